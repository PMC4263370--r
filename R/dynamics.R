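# Assembly and integration of the coupled rate equations.

#' Describe a perturbation action
#'
#' @param target id of the perturbed entity: a source's target metabolite for
#'   `influx_fold`; an enzyme, protein or switch id for `degradation_fold` /
#'   `knockout`; any state id (typically a switch active pool) for
#'   `constant_activation`; a metabolite with a sink for `sink_fold`.
#' @param kind one of `influx_fold`, `degradation_fold`, `knockout`,
#'   `constant_activation`, `sink_fold`.
#' @param magnitude positive fold-change (for `constant_activation`, the level
#'   the state is held at). `knockout` defaults to 1000.
#' @param start_time time at which the action switches on.
#' @return a one-row `nss_perturbation` data.frame; combine with [rbind()].
#' @export
perturbation <- function(target, kind = c("influx_fold", "degradation_fold",
                                          "knockout", "constant_activation",
                                          "sink_fold"),
                         magnitude = if (kind == "knockout") 1000 else 1,
                         start_time = 0) {
  kind <- match.arg(kind)
  if (magnitude <= 0) nss_error("perturbation magnitude must be > 0")
  if (kind == "knockout" && magnitude < 1000) magnitude <- 1000
  structure(data.frame(target = target, kind = kind, magnitude = magnitude,
                       start_time = start_time, stringsAsFactors = FALSE),
            class = c("nss_perturbation", "data.frame"))
}

#' Combine perturbation actions
#' @param ... `nss_perturbation` objects (or NULL).
#' @return a combined `nss_perturbation`.
#' @export
perturbations <- function(...) {
  ps <- Filter(Negate(is.null), list(...))
  if (!length(ps)) return(NULL)
  structure(do.call(rbind, ps), class = c("nss_perturbation", "data.frame"))
}

baseline_parms <- function(network) {
  rt <- network$rt
  list(src_mult = rep(1, length(rt$src_met)),
       sink_mult = rep(1, length(rt$sink_met)),
       enz_deg_mult = rep(1, length(rt$i_enz)),
       prot_deg_mult = rep(1, length(rt$i_prot)),
       sw_deg_mult = rep(1, rt$n_s),
       clamp_idx = integer(), clamp_val = numeric())
}

# resolve a perturbation table into per-leg solver parameters
perturbation_legs <- function(network, spec, t_end) {
  rt <- network$rt
  if (is.null(spec) || nrow(spec) == 0L)
    return(list(list(t0 = 0, t1 = t_end, parms = baseline_parms(network))))
  ev <- sort(unique(c(0, spec$start_time[spec$start_time > 0 & spec$start_time < t_end])))
  bounds <- c(ev, t_end)
  lapply(seq_along(ev), function(j) {
    t0 <- ev[j]
    act <- spec[spec$start_time <= t0, , drop = FALSE]
    p <- baseline_parms(network)
    for (i in seq_len(nrow(act))) {
      tg <- act$target[i]; mag <- act$magnitude[i]
      switch(act$kind[i],
        influx_fold = {
          j2 <- which(network$metab$id[rt$src_met] == tg)
          if (!length(j2)) nss_error("influx_fold target '%s' has no source", tg)
          p$src_mult[j2] <- p$src_mult[j2] * mag
        },
        sink_fold = {
          j2 <- which(network$metab$id[rt$sink_met] == tg)
          if (!length(j2)) nss_error("sink_fold target '%s' has no sink", tg)
          p$sink_mult[j2] <- p$sink_mult[j2] * mag
        },
        degradation_fold = ,
        knockout = {
          hit <- FALSE
          j2 <- which(rt$enz_ids == tg)
          if (length(j2)) { p$enz_deg_mult[j2] <- p$enz_deg_mult[j2] * mag; hit <- TRUE }
          j2 <- which(rt$prot_ids == tg)
          if (length(j2)) { p$prot_deg_mult[j2] <- p$prot_deg_mult[j2] * mag; hit <- TRUE }
          j2 <- which(rt$sw_ids == tg)
          if (length(j2)) { p$sw_deg_mult[j2] <- p$sw_deg_mult[j2] * mag; hit <- TRUE }
          if (!hit) nss_error("degradation target '%s' is not an enzyme, protein or switch", tg)
        },
        constant_activation = {
          ix <- rt$idx[[tg]]
          if (is.null(ix)) nss_error("constant_activation target '%s' is not a state", tg)
          p$clamp_idx <- c(p$clamp_idx, ix)
          p$clamp_val <- c(p$clamp_val, mag)
        })
    }
    list(t0 = t0, t1 = bounds[j + 1], parms = p)
  })
}

#' Assemble the derivative function of a network
#'
#' Returns a deterministic, side-effect-free function
#' `f(t, state, parms)` computing the time derivative of the full state
#' vector (metabolites, free enzymes, enzyme-substrate complexes, mRNAs,
#' regulatory proteins, switch pools) under the perturbation multipliers in
#' `parms` (default: baseline). Evaluation order is fixed by the state
#' indexing, independent of entity insertion order.
#'
#' @param network an `nss_network`.
#' @return function(t, state, parms) -> list(derivative vector).
#' @export
assemble_rhs <- function(network) {
  rt <- network$rt
  n <- rt$n_states
  # flattened consumption/production edges
  flat <- function(idx_list, nu_list) {
    k <- rep(seq_along(idx_list), lengths(idx_list))
    list(rxn = k, state = unlist(idx_list, use.names = FALSE) %||% integer(),
         nu = unlist(nu_list, use.names = FALSE) %||% numeric())
  }
  es <- flat(rt$er_sub, rt$er_sub_nu); ep <- flat(rt$er_prod, rt$er_prod_nu)
  ts <- flat(rt$tr_sub, rt$tr_sub_nu); tp <- flat(rt$tr_prod, rt$tr_prod_nu)
  n_er <- length(rt$er); n_tr <- length(rt$tr)
  # per-reaction state products (substrate / product side)
  sprod <- function(edges, nr, yc) {
    if (!nr) return(numeric(0))
    out <- rep(1, nr)
    v <- yc[edges$state]
    for (j in seq_along(edges$rxn)) out[edges$rxn[j]] <- out[edges$rxn[j]] * v[j]
    out
  }
  acc <- function(dy, idx, vals) {
    if (!length(idx)) return(dy)
    s <- rowsum(vals, idx)
    ii <- as.integer(rownames(s))
    dy[ii] <- dy[ii] + s[, 1]
    dy
  }
  gene_has_edges <- which(!vapply(rt$gene_edges, is.null, logical(1)))

  function(t, state, parms = NULL) {
    if (length(state) != n) nss_error("state vector length %d, expected %d", length(state), n)
    p <- parms %||% baseline_parms(network)
    yc <- pmax(state, 0)
    dy <- numeric(n)
    if (n_er) {
      E <- yc[rt$er_enz]; C <- yc[rt$er_cplx]
      nb <- rt$kC * sprod(es, n_er, yc) * E - rt$kCR * C
      ncat <- rt$kP * C - rt$kPR * sprod(ep, n_er, yc) * E
      dy <- acc(dy, es$state, -es$nu * nb[es$rxn])
      dy <- acc(dy, ep$state, ep$nu * ncat[ep$rxn])
      dy[rt$er_cplx] <- dy[rt$er_cplx] + nb - ncat
      dy <- acc(dy, rt$er_enz, ncat - nb)
    }
    if (n_tr) {
      v <- rt$kT * sprod(ts, n_tr, yc) - rt$kTR * sprod(tp, n_tr, yc)
      dy <- acc(dy, ts$state, -ts$nu * v[ts$rxn])
      dy <- acc(dy, tp$state, tp$nu * v[tp$rxn])
    }
    if (length(rt$src_met))
      dy[rt$src_met] <- dy[rt$src_met] + rt$src_phi * p$src_mult
    if (length(rt$sink_met))
      dy[rt$sink_met] <- dy[rt$sink_met] - rt$sink_k * p$sink_mult * yc[rt$sink_met]
    if (length(rt$i_enz)) {
      mr <- rep(1, length(rt$i_enz))
      hg <- !is.na(rt$enz_gene_mrna)
      mr[hg] <- yc[rt$enz_gene_mrna[hg]]
      dy[rt$i_enz] <- dy[rt$i_enz] + rt$enz_kdeg * mr -
        rt$enz_kdeg * p$enz_deg_mult * yc[rt$i_enz]
    }
    if (length(rt$i_mrna)) {
      fac <- rep(1, length(rt$i_mrna))
      for (g in gene_has_edges) {
        e <- rt$gene_edges[[g]]
        f <- 1
        for (j in seq_along(e$reg))
          f <- f * regulation_factor(yc[e$reg[j]], e$sign[j], e$Q_max[j], e$Q_hat[j],
                                     e$hill[j], e$basal[j])
        fac[g] <- min(f, e$cap)
      }
      dy[rt$i_mrna] <- dy[rt$i_mrna] + rt$gene_kd * fac - rt$gene_kd * yc[rt$i_mrna]
    }
    if (length(rt$i_prot))
      dy[rt$i_prot] <- dy[rt$i_prot] + rt$prot_kd * yc[rt$prot_mrna] -
        rt$prot_kd * p$prot_deg_mult * yc[rt$i_prot]
    if (rt$n_s) {
      for (s in seq_len(rt$n_s)) {
        qa <- if (length(rt$sw_act[[s]])) mean(yc[rt$sw_act[[s]]]) else 1
        qi <- if (length(rt$sw_inh[[s]])) mean(yc[rt$sw_inh[[s]]]) else 1
        Qa <- yc[rt$i_sw_a[s]]; Qi <- yc[rt$i_sw_i[s]]
        act <- rt$sw_ka[s] * qa * Qi
        inact <- rt$sw_ki[s] * qi * Qa
        kd <- rt$sw_kd[s] * p$sw_deg_mult[s]
        dy[rt$i_sw_a[s]] <- dy[rt$i_sw_a[s]] + act - inact - kd * Qa
        dy[rt$i_sw_i[s]] <- dy[rt$i_sw_i[s]] + 2 * rt$sw_kd[s] - act + inact - kd * Qi
      }
    }
    if (length(p$clamp_idx))
      dy[p$clamp_idx] <- 1.0 * (p$clamp_val - state[p$clamp_idx])
    list(dy)
  }
}

#' Maximum-norm derivative residual at a state
#'
#' @param network an `nss_network`.
#' @param state state vector (default: the initialized baseline).
#' @return max |dx/dt| over all states.
#' @export
network_residual <- function(network, state = initialize_state(network)) {
  f <- assemble_rhs(network)
  max(abs(f(0, state)[[1]]))
}

#' Integrate a network, applying perturbations at their start times
#'
#' Integration restarts at every perturbation start time so discontinuities
#' are handled exactly. The stiff BDF-capable `deSolve::lsoda` solver is used
#' with a default relative tolerance of 1e-9. Solver failure or a divergence
#' guard (any state above 1e6 or below -1e-9) is returned as a flagged
#' trajectory, not raised.
#'
#' @param network an `nss_network`.
#' @param perturbation an `nss_perturbation` or NULL.
#' @param t_end end time (arbitrary time units).
#' @param rtol,atol solver tolerances.
#' @param init initial state (default: the network baseline).
#' @param n_out output points per integration leg (geometric spacing).
#' @return an `nss_trajectory`: times, state matrix, event markers, the
#'   final-leg multipliers and failure diagnostics.
#' @export
integrate_network <- function(network, perturbation = NULL, t_end = 1e6,
                              rtol = 1e-9, atol = 1e-12, init = NULL,
                              n_out = 40) {
  legs <- perturbation_legs(network, perturbation, t_end)
  f <- assemble_rhs(network)
  y <- init %||% initialize_state(network)
  times_all <- numeric(0); states_all <- NULL
  failed <- FALSE; fail_time <- NA_real_; fail_mode <- "none"
  for (leg in legs) {
    span <- leg$t1 - leg$t0
    tt <- unique(leg$t0 + span * c(0, 10^seq(-6, 0, length.out = n_out)))
    sol <- try(suppressWarnings(
      deSolve::lsoda(y, tt, f, leg$parms, rtol = rtol, atol = atol,
                     maxsteps = 100000)), silent = TRUE)
    if (inherits(sol, "try-error")) {
      failed <- TRUE; fail_time <- leg$t0; fail_mode <- "non-convergence"
      break
    }
    sol <- as.matrix(sol)
    ok <- stats::complete.cases(sol) & apply(is.finite(sol), 1, all)
    sol <- sol[ok, , drop = FALSE]
    if (nrow(sol) < length(tt)) {
      failed <- TRUE
      fail_time <- if (nrow(sol)) sol[nrow(sol), 1] else leg$t0
      fail_mode <- "non-convergence"
    }
    if (nrow(sol)) {
      st <- sol[, -1, drop = FALSE]
      times_all <- c(times_all, sol[, 1])
      states_all <- rbind(states_all, st)
      y <- st[nrow(st), ]
      if (max(abs(y)) > 1e6) { failed <- TRUE; fail_time <- sol[nrow(sol), 1]; fail_mode <- "divergence" }
      if (min(y) < -1e-9)    { failed <- TRUE; fail_time <- sol[nrow(sol), 1]; fail_mode <- "negativity" }
    }
    if (failed) break
  }
  if (is.null(states_all)) {
    states_all <- matrix(y, nrow = 1)
    times_all <- legs[[1]]$t0
  }
  colnames(states_all) <- network$rt$labels
  structure(list(times = times_all, states = states_all,
                 labels = network$rt$labels,
                 events = vapply(legs[-1], function(l) l$t0, numeric(1)),
                 network = network,
                 final_parms = legs[[length(legs)]]$parms,
                 failed = failed, fail_time = fail_time, fail_mode = fail_mode),
            class = "nss_trajectory")
}

#' @export
print.nss_trajectory <- function(x, ...) {
  cat(sprintf("<nss_trajectory> %d states, %d time points, t in [%g, %g]%s\n",
              ncol(x$states), length(x$times), min(x$times), max(x$times),
              if (x$failed) sprintf(" [FAILED: %s at t=%g]", x$fail_mode, x$fail_time) else ""))
  invisible(x)
}

#' Detect a steady state at the end of a trajectory
#'
#' Converged iff the assembled derivative at the final state has max-norm
#' below `eps_ss` and the maximum relative state change over the trailing
#' `window` fraction of elapsed time is below `eps_ss`. Non-convergence is a
#' result, not an error.
#'
#' @param trajectory an `nss_trajectory`.
#' @param eps_ss steady-state tolerance on the normalized scale.
#' @param window trailing fraction of elapsed time checked for settledness.
#' @return an `nss_steady_state` with `converged`, `state`, `t_reached`,
#'   `residual`, `fold_changes` (ratio to the network baseline) and `mode`
#'   (`none`, `divergence`, `negativity` or `non-convergence`).
#' @export
detect_steady_state <- function(trajectory, eps_ss = 1e-7, window = 0.1) {
  tr <- trajectory
  net <- tr$network
  base <- initialize_state(net)
  n_t <- length(tr$times)
  if (!n_t) nss_error("empty trajectory")
  y <- tr$states[n_t, ]
  res <- structure(list(converged = FALSE, state = y,
                        t_reached = tr$times[n_t],
                        residual = NA_real_,
                        fold_changes = y / base,
                        mode = tr$fail_mode, baseline = base,
                        final_parms = tr$final_parms), class = "nss_steady_state")
  if (tr$failed) return(res)
  if (max(abs(y)) > 1e6) { res$mode <- "divergence"; return(res) }
  if (min(y) < -1e-9)    { res$mode <- "negativity"; return(res) }
  f <- assemble_rhs(net)
  resid <- max(abs(f(tr$times[n_t], y, tr$final_parms)[[1]]))
  res$residual <- resid
  tw <- tr$times[n_t] - window * max(tr$times[n_t], 1)
  sel <- which(tr$times >= tw)
  relch <- if (length(sel) > 1L)
    max(abs(sweep(tr$states[sel, , drop = FALSE], 2, y)) / pmax(abs(y), 1e-6))
  else 0
  if (resid < eps_ss && relch < eps_ss) {
    res$converged <- TRUE; res$mode <- "none"
  } else {
    res$mode <- "non-convergence"
  }
  res
}

#' @export
print.nss_steady_state <- function(x, ...) {
  if (x$converged)
    cat(sprintf("<nss_steady_state> converged at t=%g (residual %.3g)\n",
                x$t_reached, x$residual))
  else
    cat(sprintf("<nss_steady_state> NOT converged (mode: %s, t=%g)\n", x$mode, x$t_reached))
  invisible(x)
}

#' Integrate to a (post-perturbation) steady state
#'
#' @inheritParams integrate_network
#' @inheritParams detect_steady_state
#' @return an `nss_steady_state`.
#' @export
steady_state <- function(network, perturbation = NULL, t_end = 1e6,
                         eps_ss = 1e-7, window = 0.1, rtol = 1e-9,
                         atol = 1e-12, init = NULL) {
  tr <- integrate_network(network, perturbation, t_end = t_end,
                          rtol = rtol, atol = atol, init = init)
  detect_steady_state(tr, eps_ss = eps_ss, window = window)
}

#' Closed-form steady state of a single perturbed reaction
#'
#' For one enzymatic reaction parameterized at the normalized baseline
#' (branch fraction `f` of a unit source, reversibility `r`, enzyme ratio
#' `w`, first-order alternative-branch and product demand), the new steady
#' state after scaling the substrate influx by `influx_fold` (u) and the
#' product demand by `efflux_demand` (d) is, with
#' \eqn{A = 1 - r^2 + r^2/d} and \eqn{J = u f / (f + (1-f)A)} the new
#' reaction flux:
#' \deqn{S^* = uA/(f+(1-f)A),\; E^* = 1,\; C^* = w (J/f)((1-r)+r/d),\;
#'       P^* = J/(fd),\; f^* = f/(f+(1-f)A).}
#' The relative concentrations depend on `f`, `r`, `w` and the demand but not
#' on the absolute total flux: scaling influx and demand jointly leaves
#' `S*, E*, C*/w, f*` invariant up to the common factor in the carried flux.
#'
#' @param r reversibility in \[0,1).
#' @param f branch fraction of the source flux routed into the reaction.
#' @param w bound/free enzyme ratio.
#' @param influx_fold fold change u of the substrate influx.
#' @param efflux_demand fold change d of the product demand rate.
#' @return list with `S`, `E`, `C`, `P`, `f_star`, `flux`.
#' @export
predict_single_reaction_steady_state <- function(r, f, w, influx_fold = 1,
                                                 efflux_demand = 1) {
  if (r < 0 || r >= 1) nss_error("r must lie in [0,1)")
  if (f <= 0 || f > 1) nss_error("f must lie in (0,1]")
  if (w <= 0) nss_error("w must be > 0")
  u <- influx_fold; d <- efflux_demand
  if (u <= 0 || d <= 0) nss_error("influx_fold and efflux_demand must be > 0")
  A <- 1 - r^2 + r^2 / d
  den <- f + (1 - f) * A
  if (den <= 0) return(list(S = NA, E = NA, C = NA, P = NA, f_star = NA,
                            flux = NA, feasible = FALSE))
  J <- u * f / den
  list(S = u * A / den, E = 1,
       C = w * (J / f) * ((1 - r) + r / d),
       P = J / (f * d),
       f_star = f / den, flux = J, feasible = TRUE)
}

#' Realized flux fractions at a branch point
#'
#' Computes each branch child's net flux at the given state (net complex
#' formation for enzymatic children, net carrier flux for transport children,
#' first-order export for the `sink` child) and returns the realized
#' fractions f* = child flux / total declared efflux.
#'
#' @param network an `nss_network`.
#' @param state a state vector (typically a converged steady state).
#' @param parent branch parent metabolite id.
#' @param parms solver multipliers in effect (default baseline).
#' @return data.frame with columns child, f (declared), flux, f_star.
#' @export
realized_flux_fractions <- function(network, state, parent, parms = NULL) {
  rt <- network$rt
  p <- parms %||% baseline_parms(network)
  br <- network$definition$branches
  rows <- br[br$parent == parent, , drop = FALSE]
  if (!nrow(rows)) {
    k <- which(vapply(network$subs, function(s) s$id[1], character(1)) == parent)
    if (!length(k)) nss_error("'%s' has no branch and no primary consumer", parent)
    rows <- data.frame(parent = parent, child = network$reactions$id[k],
                       f = network$reactions$f[k], stringsAsFactors = FALSE)
  }
  yc <- pmax(state, 0)
  flux <- vapply(seq_len(nrow(rows)), function(i) {
    ch <- rows$child[i]
    if (ch == "sink") {
      m <- rt$idx[[parent]]
      j <- which(rt$sink_met == m)
      return(rt$sink_k[j] * p$sink_mult[j] * yc[m])
    }
    k <- which(network$reactions$id == ch)
    nu1 <- network$subs[[k]]$nu[1]
    if (network$reactions$enzymatic[k]) {
      j <- which(rt$er == k)
      sp <- prod(yc[rt$er_sub[[j]]])
      nu1 * (rt$kC[j] * sp * yc[rt$er_enz[j]] - rt$kCR[j] * yc[rt$er_cplx[j]])
    } else {
      j <- which(rt$tr == k)
      sp <- prod(yc[rt$tr_sub[[j]]]); pp <- prod(yc[rt$tr_prod[[j]]])
      nu1 * (rt$kT[j] * sp - rt$kTR[j] * pp)
    }
  }, numeric(1))
  tot <- sum(flux)
  if (abs(tot) < 1e-300)
    return(data.frame(rows[, c("child", "f")], flux = flux, f_star = NA_real_))
  data.frame(rows[, c("child", "f")], flux = flux, f_star = flux / tot,
             stringsAsFactors = FALSE)
}
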