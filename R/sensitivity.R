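# Metabolic control analysis over branch-point flux distributions.

#' Concentration control coefficient of a branch fraction
#'
#' Perturbs the flux fraction of one branch child by the relative amount
#' `delta` (siblings renormalized proportionally), re-derives the network
#' parameters, integrates both the reference and the perturbed network to
#' steady state under the same `background` perturbation, and returns the
#' dimensionless concentration control coefficient
#' \deqn{C^{TG}_f = \frac{TG^* - TG}{f^* - f}\cdot\frac{f}{TG}}
#' where `TG` and `TG*` are the target's steady-state concentrations and
#' `f*` is the realized post-perturbation fraction of the child (when the
#' realized fraction equals `f` to machine precision, the imposed fraction is
#' used instead and flagged).
#'
#' @param network an `nss_network`.
#' @param parent branch parent metabolite id.
#' @param child branch child id (reaction or `"sink"`).
#' @param target response state id (e.g. hepatic triglycerides).
#' @param delta relative change of the child fraction (default 0.1, the
#'   standard 10% scan interval).
#' @param background an `nss_perturbation` applied to both evaluations (e.g.
#'   a high-calorie diet), or NULL.
#' @param ref optional precomputed reference `nss_steady_state` under
#'   `background` (avoids recomputation during scans).
#' @param ... passed to [steady_state()].
#' @return a one-row data.frame (`nss_sensitivity_record`): parent, child, f,
#'   f_perturbed, f_star, target, TG, TG_star, coefficient, impact, stable,
#'   mode, denom.
#' @export
concentration_control_coefficient <- function(network, parent, child, target,
                                              delta = 0.1, background = NULL,
                                              ref = NULL, ...) {
  br <- network$definition$branches
  i <- which(br$parent == parent & br$child == child)
  if (!length(i)) nss_error("no branch row for parent '%s' child '%s'", parent, child)
  f0 <- br$f[i]
  f1 <- f0 * (1 + delta)
  if (f1 <= 0 || f1 > 1)
    nss_error("perturbed fraction %.4g outside (0, 1]", f1)
  if (is.null(network$rt$idx[[target]]))
    nss_error("unknown target state '%s'", target)
  rec <- data.frame(parent = parent, child = child, f = f0, f_perturbed = f1,
                    f_star = NA_real_, target = target, TG = NA_real_,
                    TG_star = NA_real_, coefficient = NA_real_,
                    impact = "unclassified", stable = FALSE, mode = "none",
                    denom = "realized", stringsAsFactors = FALSE)
  ss0 <- ref %||% steady_state(network, background, ...)
  net1 <- tryCatch(set_branch_fraction(network, parent, child, f1),
                   nss_error = function(e) NULL)
  if (is.null(net1)) {
    rec$mode <- "infeasible"
    class(rec) <- c("nss_sensitivity_record", "data.frame")
    return(rec)
  }
  ss1 <- steady_state(net1, background, ...)
  rec$TG <- unname(ss0$state[target])
  rec$TG_star <- unname(ss1$state[target])
  rec$stable <- ss0$converged && ss1$converged
  rec$mode <- if (!ss1$converged) ss1$mode else if (!ss0$converged) ss0$mode else "none"
  if (rec$stable) {
    fr <- realized_flux_fractions(net1, ss1$state, parent, ss1$final_parms)
    fs <- fr$f_star[fr$child == child]
    rec$f_star <- fs
    dfrac <- fs - f0
    if (!is.finite(dfrac) || abs(dfrac) < 1e-12) {
      dfrac <- f1 - f0
      rec$denom <- "imposed"
    }
    rec$coefficient <- (rec$TG_star - rec$TG) / dfrac * (f0 / rec$TG)
    rec$impact <- classify_impact(rec$coefficient)
  }
  class(rec) <- c("nss_sensitivity_record", "data.frame")
  rec
}

#' Classify a control coefficient's impact
#'
#' Absolute-value classification: `|c| > 1` high, `0.1 <= |c| <= 0.99`
#' moderate, `|c| < 0.1` low. Values in the printed-bound gap (0.99, 1\]
#' classify as high (the conservative screening call); the sign is reported
#' separately by the caller.
#'
#' @param coefficient numeric vector.
#' @return character vector in {"high", "moderate", "low", "unclassified"}.
#' @export
classify_impact <- function(coefficient) {
  a <- abs(coefficient)
  out <- rep("unclassified", length(a))
  fin <- is.finite(a)
  out[fin & a > 0.99] <- "high"
  out[fin & a >= 0.1 & a <= 0.99] <- "moderate"
  out[fin & a < 0.1] <- "low"
  out
}

#' Scan all branch points for flux-distribution sensitivity
#'
#' One record per (branch child, grid point), ordered by parent, child, then
#' grid point. Non-convergence at a grid point is flagged per record
#' (`stable = FALSE`), never aborts the scan.
#'
#' @param network an `nss_network`.
#' @param target response state id.
#' @param delta_grid relative changes to apply (default +/-10%).
#' @param background shared background perturbation.
#' @param include_sink also scan `sink` children (default TRUE).
#' @param ... passed to [steady_state()].
#' @return data.frame of sensitivity records with a `delta` column.
#' @export
scan_branches <- function(network, target, delta_grid = c(-0.1, 0.1),
                          background = NULL, include_sink = TRUE, ...) {
  br <- network$definition$branches
  if (!nrow(br)) return(NULL)
  br <- br[order(br$parent, br$child), , drop = FALSE]
  if (!include_sink) br <- br[br$child != "sink", , drop = FALSE]
  ref <- steady_state(network, background, ...)
  out <- list()
  for (i in seq_len(nrow(br))) {
    for (d in delta_grid) {
      rec <- tryCatch(
        concentration_control_coefficient(network, br$parent[i], br$child[i],
                                          target, delta = d,
                                          background = background, ref = ref, ...),
        nss_error = function(e) NULL)
      if (is.null(rec)) {
        rec <- data.frame(parent = br$parent[i], child = br$child[i], f = br$f[i],
                          f_perturbed = br$f[i] * (1 + d), f_star = NA_real_,
                          target = target, TG = NA_real_, TG_star = NA_real_,
                          coefficient = NA_real_, impact = "unclassified",
                          stable = FALSE, mode = "infeasible", denom = "realized",
                          stringsAsFactors = FALSE)
      }
      rec$delta <- d
      out[[length(out) + 1L]] <- rec
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Flux-range tolerance of a branch child
#'
#' Steps the child's fraction over a grid of resolution `resolution` in
#' (0, 1), integrating to steady state under `background` at each value, and
#' returns the maximal contiguous stable interval containing the baseline
#' fraction together with the instability mode at each boundary
#' (`divergence`, `non-convergence`, `negativity`, `infeasible`, or `none`
#' when stable through the grid end).
#'
#' @param network an `nss_network`.
#' @param parent,child the branch child scanned.
#' @param target response state id (recorded, not used for stability).
#' @param background shared background perturbation.
#' @param resolution grid step (default 0.1, the standard 10% interval).
#' @param ... passed to [steady_state()].
#' @return an `nss_tolerance_range` list: parent, child, f, f_lo, f_hi,
#'   mode_lo, mode_hi, grid (data.frame f/stable/mode).
#' @export
tolerance_range <- function(network, parent, child, target = NULL,
                            background = NULL, resolution = 0.1, ...) {
  br <- network$definition$branches
  i <- which(br$parent == parent & br$child == child)
  if (!length(i)) nss_error("no branch row for parent '%s' child '%s'", parent, child)
  f0 <- br$f[i]
  grid <- sort(unique(c(seq(resolution, 1 - resolution / 2, by = resolution), f0)))
  stable <- logical(length(grid)); mode <- character(length(grid))
  for (j in seq_along(grid)) {
    netj <- tryCatch(set_branch_fraction(network, parent, child, grid[j]),
                     nss_error = function(e) NULL)
    if (is.null(netj)) { stable[j] <- FALSE; mode[j] <- "infeasible"; next }
    ss <- steady_state(netj, background, ...)
    stable[j] <- ss$converged
    mode[j] <- ss$mode
  }
  j0 <- which.min(abs(grid - f0))
  if (!stable[j0])
    nss_error("baseline fraction %.3g is itself unstable (%s): model misconfigured",
              f0, mode[j0])
  lo <- j0; while (lo > 1 && stable[lo - 1]) lo <- lo - 1
  hi <- j0; while (hi < length(grid) && stable[hi + 1]) hi <- hi + 1
  structure(list(parent = parent, child = child, f = f0,
                 f_lo = grid[lo], f_hi = grid[hi],
                 mode_lo = if (lo > 1) mode[lo - 1] else "none",
                 mode_hi = if (hi < length(grid)) mode[hi + 1] else "none",
                 grid = data.frame(f = grid, stable = stable, mode = mode)),
            class = "nss_tolerance_range")
}

#' @export
print.nss_tolerance_range <- function(x, ...) {
  cat(sprintf("<nss_tolerance_range> %s -> %s: stable f in [%.3g, %.3g] (baseline %.3g); modes [%s | %s]\n",
              x$parent, x$child, x$f_lo, x$f_hi, x$f, x$mode_lo, x$mode_hi))
  invisible(x)
}

#' Control coefficients of a branch with respect to regulatory proteins
#'
#' Applies the same control-coefficient formula with each regulator's
#' steady-state concentration as the response variable.
#'
#' @param network an `nss_network`.
#' @param parent,child the branch child perturbed.
#' @param regulators character vector of regulatory state ids (proteins,
#'   switch pools, mRNAs).
#' @param delta relative fraction change.
#' @param background shared background perturbation.
#' @param ... passed to [steady_state()].
#' @return data.frame: one row per regulator with coefficient and class.
#' @export
regulator_sensitivity <- function(network, parent, child, regulators,
                                  delta = 0.1, background = NULL, ...) {
  ref <- steady_state(network, background, ...)
  out <- lapply(regulators, function(rg)
    concentration_control_coefficient(network, parent, child, rg,
                                      delta = delta, background = background,
                                      ref = ref, ...))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
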