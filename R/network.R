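#' Derive rate constants for a reaction at the normalized steady state
#'
#' Implements the normalized-steady-state parameterization of the reversible
#' two-step mechanism S + E <-> C <-> E + P. Given the reversibility ratio
#' `r` (reverse/forward flux ratio at baseline on each elementary step), the
#' bound/free enzyme ratio `w` and the baseline throughput `throughput`
#' (net flux through the reaction, i.e. the branch fraction f times the
#' parent's total steady-state efflux), the four rate constants are uniquely
#' determined so that the normalized state S_N = E_N = P_N = 1, C_N = w is an
#' exact equilibrium and each elementary step realizes reverse/forward = r:
#' \deqn{k_C = \Phi/(1-r),\quad k_{CR} = r\Phi/((1-r)w),\quad
#'       k_P = \Phi/((1-r)w),\quad k_{PR} = r\Phi/(1-r).}
#'
#' @param r reversibility ratio in \[0, 1); 0 for irreversible reactions,
#'   0.5 by convention for reversible reactions of unknown ratio.
#' @param w bound/free enzyme ratio, > 0.
#' @param throughput baseline net flux through the reaction, > 0.
#' @return named list with `k_C`, `k_P`, `k_CR`, `k_PR`.
#' @export
derive_rate_constants <- function(r, w, throughput) {
  if (r < 0 || r >= 1) nss_error("infeasible reversibility: r must lie in [0, 1), got %g", r)
  if (w <= 0) nss_error("domain error: w must be > 0, got %g", w)
  if (throughput <= 0) nss_error("throughput must be > 0, got %g", throughput)
  list(k_C  = throughput / (1 - r),
       k_CR = r * throughput / ((1 - r) * w),
       k_P  = throughput / ((1 - r) * w),
       k_PR = r * throughput / (1 - r))
}

#' Build a simulatable network from a model definition
#'
#' Resolves all references, validates branch-point fractions, solves the
#' baseline flux-balance linear system for every reaction's throughput,
#' derives all dependent rate constants so that the all-ones normalized state
#' is an exact fixed point, and precomputes the index structures used by the
#' assembled derivative function.
#'
#' Flux bookkeeping: each reaction's throughput is pinned to its first-listed
#' (primary) substrate through that metabolite's branch fraction; draws on
#' further (secondary) substrates are accounted against those metabolites'
#' balances. Branch fractions split the parent's efflux remaining after
#' secondary draws, and may include a reserved `sink` child (first-order
#' export). Metabolites without consumers receive an automatic first-order
#' sink, closing the network so that mass balances exactly at baseline.
#'
#' @param definition an `nss_definition`.
#' @param quiet suppress warnings about unreferenced entities.
#' @return an object of class `nss_network`.
#' @export
build_network <- function(definition, quiet = FALSE) {
  def <- definition
  validate_definition(def)
  met <- def$metabolites; rx <- def$reactions; enz <- def$enzymes
  n_m <- nrow(met); n_r <- nrow(rx)
  if (n_m == 0L) nss_error("network has no metabolites")

  mi <- stats::setNames(seq_len(n_m), met$id)
  subs <- lapply(rx$substrates, parse_species)
  prods <- lapply(rx$products, parse_species)
  for (k in seq_len(n_r)) {
    bad <- setdiff(c(subs[[k]]$id, prods[[k]]$id), met$id)
    if (length(bad))
      nss_error("reaction '%s': dangling metabolite reference '%s'", rx$id[k], bad[1])
  }
  if (n_r) {
    bad <- setdiff(rx$enzyme[!is.na(rx$enzyme)], enz$id)
    if (length(bad)) nss_error("dangling enzyme reference '%s'", bad[1])
  }

  # ---- branch validation -------------------------------------------------
  br <- def$branches
  prim_of <- vapply(subs, function(s) s$id[1], character(1))  # primary substrate per rxn
  prim_nu <- vapply(subs, function(s) s$nu[1], numeric(1))
  if (nrow(br)) {
    bad <- setdiff(br$parent, met$id)
    if (length(bad)) nss_error("branch parent '%s' is not a metabolite", bad[1])
    for (p in unique(br$parent)) {
      b <- br[br$parent == p, , drop = FALSE]
      tot <- sum(b$f)
      if (abs(tot - 1) > 1e-12)
        nss_error("branch fractions at '%s' sum to %.12g (residual %.3g)", p, tot, 1 - tot)
      if (any(b$f <= 0 | b$f > 1))
        nss_error("branch fractions at '%s' must lie in (0, 1]", p)
      kids <- setdiff(b$child, "sink")
      bad <- setdiff(kids, rx$id)
      if (length(bad)) nss_error("branch child '%s' is not a reaction", bad[1])
      notprim <- kids[prim_of[match(kids, rx$id)] != p]
      if (length(notprim))
        nss_error("branch child '%s' does not consume parent '%s' as primary substrate",
                  notprim[1], p)
    }
  }
  # implicit f for reactions: from branch rows, else sole-primary-consumer = 1
  f_r <- rep(NA_real_, n_r)
  if (nrow(br)) {
    m <- match(rx$id, br$child)
    f_r[!is.na(m)] <- br$f[m[!is.na(m)]]
  }
  for (k in seq_len(n_r)) {
    if (is.na(f_r[k])) {
      siblings <- which(prim_of == prim_of[k])
      if (length(siblings) > 1L)
        nss_error("metabolite '%s' has several primary consumers but no branch declaration",
                  prim_of[k])
      f_r[k] <- 1
    }
  }

  # ---- baseline flux balance --------------------------------------------
  src_vec <- numeric(n_m)
  if (nrow(def$sources)) {
    bad <- setdiff(def$sources$target, met$id)
    if (length(bad)) nss_error("source target '%s' is not a metabolite", bad[1])
    src_vec[mi[def$sources$target]] <- src_vec[mi[def$sources$target]] + def$sources$phi
  }
  P <- matrix(0, n_m, max(n_r, 1))   # production multipliers
  Csec <- matrix(0, n_m, max(n_r, 1))  # secondary-substrate draws
  for (k in seq_len(n_r)) {
    pr <- prods[[k]]
    P[mi[pr$id], k] <- P[mi[pr$id], k] + pr$nu
    ss <- subs[[k]]
    if (nrow(ss) > 1L)
      Csec[mi[ss$id[-1]], k] <- Csec[mi[ss$id[-1]], k] + ss$nu[-1]
  }
  phi_r <- numeric(0)
  if (n_r) {
    A <- matrix(0, n_r, n_r); b <- numeric(n_r)
    for (k in seq_len(n_r)) {
      m <- mi[[prim_of[k]]]
      A[k, ] <- -f_r[k] * (P[m, ] - Csec[m, ])
      A[k, k] <- A[k, k] + prim_nu[k]
      b[k] <- f_r[k] * src_vec[m]
    }
    phi_r <- tryCatch(solve(A, b), error = function(e)
      nss_error("flux-balance system is singular: %s", conditionMessage(e)))
    if (any(!is.finite(phi_r)) || any(phi_r <= 1e-12))
      nss_error("flux balance yields non-positive throughput for reaction '%s'",
                rx$id[which(phi_r <= 1e-12)[1]])
  }

  influx <- src_vec + if (n_r) as.vector(P %*% phi_r) else 0
  secdraw <- if (n_r) as.vector(Csec %*% phi_r) else numeric(n_m)
  avail <- influx - secdraw
  if (any(avail < -1e-9)) {
    m <- which(avail < -1e-9)[1]
    nss_error("metabolite '%s' is overdrawn at baseline (influx %.4g < secondary draws %.4g)",
              met$id[m], influx[m], secdraw[m])
  }
  primdraw <- numeric(n_m)
  for (k in seq_len(n_r)) {
    m <- mi[[prim_of[k]]]
    primdraw[m] <- primdraw[m] + prim_nu[k] * phi_r[k]
  }
  sink_k <- pmax(avail - primdraw, 0)
  sink_k[abs(sink_k) < 1e-12] <- 0
  # metabolites that are consumed only partially or not at all get a sink;
  # those fully covered by branches (sum f over reactions = 1, no sink child) get none
  orphan <- influx <= 1e-12 & primdraw <= 1e-12 & secdraw <= 1e-12
  if (any(orphan) && !quiet)
    warning(sprintf("unreferenced metabolite(s) with zero baseline flux: %s",
                    paste(met$id[orphan], collapse = ", ")), call. = FALSE)
  used_enz <- unique(rx$enzyme[!is.na(rx$enzyme)])
  if (nrow(enz) && !quiet) {
    un <- setdiff(enz$id, used_enz)
    if (length(un))
      warning(sprintf("unreferenced enzyme(s): %s", paste(un, collapse = ", ")), call. = FALSE)
  }

  # ---- rate constants ----------------------------------------------------
  enzymatic <- if (n_r) !is.na(rx$enzyme) else logical(0)
  kC <- kP <- kCR <- kPR <- rep(NA_real_, n_r)
  for (k in which(enzymatic)) {
    ks <- derive_rate_constants(rx$r[k], rx$w[k], phi_r[k])
    kC[k] <- ks$k_C; kP[k] <- ks$k_P; kCR[k] <- ks$k_CR; kPR[k] <- ks$k_PR
  }
  # carrier-free transport: first-order forward/backward, net = throughput
  kT <- kTR <- rep(NA_real_, n_r)
  for (k in which(!enzymatic)) {
    r <- rx$r[k]
    kT[k] <- phi_r[k] / (1 - r)
    kTR[k] <- r * phi_r[k] / (1 - r)
  }

  net <- structure(list(
    definition = def,
    metab = data.frame(id = met$id, compartment = met$compartment,
                       source = src_vec, sink_k = sink_k,
                       influx = influx, avail = avail, stringsAsFactors = FALSE),
    reactions = data.frame(id = if (n_r) rx$id else character(),
                           enzyme = if (n_r) rx$enzyme else character(),
                           enzymatic = enzymatic,
                           r = if (n_r) rx$r else numeric(), w = if (n_r) rx$w else numeric(),
                           f = f_r, throughput = phi_r,
                           k_C = kC, k_P = kP, k_CR = kCR, k_PR = kPR,
                           k_T = kT, k_TR = kTR, stringsAsFactors = FALSE),
    subs = subs, prods = prods
  ), class = "nss_network")
  net <- index_states(net)
  net
}

# assign state-vector indices and precompute runtime structures
index_states <- function(net) {
  def <- net$definition
  rx <- net$reactions
  n_m <- nrow(net$metab)
  enz_ids <- unique(rx$enzyme[rx$enzymatic])
  n_e <- length(enz_ids)
  er <- which(rx$enzymatic); tr <- which(!rx$enzymatic)
  n_g <- nrow(def$genes)
  prot_g <- which(def$genes$target_type == "protein")
  prot_ids <- def$genes$target[prot_g]
  n_p <- length(prot_ids)
  n_s <- nrow(def$switches)

  labels <- c(net$metab$id, enz_ids, if (length(er)) paste0("C:", rx$id[er]),
              def$genes$id, prot_ids,
              if (n_s) as.vector(rbind(paste0(def$switches$id, "_a"),
                                       paste0(def$switches$id, "_i"))))
  idx <- stats::setNames(seq_along(labels), labels)

  emeta <- def$enzymes[match(enz_ids, def$enzymes$id), , drop = FALSE]
  gene_of_enz <- match(emeta$gene, def$genes$id)        # NA if constitutive
  if (any(!is.na(emeta$gene) & is.na(gene_of_enz)))
    nss_error("enzyme '%s' references unknown gene '%s'",
              emeta$id[which(!is.na(emeta$gene) & is.na(gene_of_enz))[1]],
              emeta$gene[which(!is.na(emeta$gene) & is.na(gene_of_enz))[1]])
  # gene targets resolve
  if (n_g) {
    tg_e <- def$genes$target_type == "enzyme"
    bad <- setdiff(def$genes$target[tg_e], def$enzymes$id)
    if (length(bad)) nss_error("gene targets unknown enzyme '%s'", bad[1])
    back <- match(def$genes$id[tg_e], emeta$gene)
    if (anyNA(back))
      nss_error("gene '%s' targets an enzyme that does not declare it via gene=",
                def$genes$id[tg_e][which(is.na(back))[1]])
  }
  resolve_states <- function(ids, what) {
    out <- idx[ids]
    if (anyNA(out)) nss_error("%s references unknown state '%s'", what, ids[is.na(out)][1])
    unname(out)
  }

  rt <- list(
    n_states = length(labels), labels = labels, idx = idx,
    i_met = seq_len(n_m),
    i_enz = if (n_e) n_m + seq_len(n_e) else integer(),
    enz_ids = enz_ids,
    enz_kdeg = emeta$k_deg %||% numeric(),
    enz_gene_mrna = if (n_e) ifelse(is.na(gene_of_enz), NA_integer_,
                                    n_m + n_e + length(er) + gene_of_enz) else integer(),
    er = er, tr = tr,
    er_enz = if (length(er)) n_m + match(rx$enzyme[er], enz_ids) else integer(),
    er_cplx = if (length(er)) n_m + n_e + seq_along(er) else integer(),
    er_sub = lapply(net$subs[er], function(s) unname(idx[s$id])),
    er_sub_nu = lapply(net$subs[er], function(s) s$nu),
    er_prod = lapply(net$prods[er], function(s) unname(idx[s$id])),
    er_prod_nu = lapply(net$prods[er], function(s) s$nu),
    tr_sub = lapply(net$subs[tr], function(s) unname(idx[s$id])),
    tr_sub_nu = lapply(net$subs[tr], function(s) s$nu),
    tr_prod = lapply(net$prods[tr], function(s) unname(idx[s$id])),
    tr_prod_nu = lapply(net$prods[tr], function(s) s$nu),
    kC = rx$k_C[er], kCR = rx$k_CR[er], kP = rx$k_P[er], kPR = rx$k_PR[er],
    kT = rx$k_T[tr], kTR = rx$k_TR[tr],
    src_met = which(net$metab$source > 0),
    src_phi = net$metab$source[net$metab$source > 0],
    sink_met = which(net$metab$sink_k > 0),
    sink_k = net$metab$sink_k[net$metab$sink_k > 0],
    i_mrna = if (n_g) n_m + n_e + length(er) + seq_len(n_g) else integer(),
    gene_kd = def$genes$k_d,
    i_prot = if (n_p) n_m + n_e + length(er) + n_g + seq_len(n_p) else integer(),
    prot_ids = prot_ids,
    prot_mrna = if (n_p) n_m + n_e + length(er) + prot_g else integer(),
    prot_kd = def$genes$k_dp[prot_g],
    n_s = n_s,
    sw_ids = def$switches$id,
    i_sw_a = if (n_s) n_m + n_e + length(er) + n_g + n_p + 2 * seq_len(n_s) - 1L else integer(),
    i_sw_i = if (n_s) n_m + n_e + length(er) + n_g + n_p + 2 * seq_len(n_s) else integer(),
    sw_ka = def$switches$k_a,
    sw_ki = def$switches$k_a - def$switches$k_d,
    sw_kd = def$switches$k_d,
    sw_act = lapply(def$switches$activator, function(a)
      if (is.na(a)) integer() else resolve_states(trimws(strsplit(a, ",")[[1]]), "switch activator")),
    sw_inh = lapply(def$switches$inhibitor, function(a)
      if (is.na(a)) integer() else resolve_states(trimws(strsplit(a, ",")[[1]]), "switch inhibitor"))
  )
  # transcription edges grouped per gene
  te <- def$tf_edges
  rt$gene_edges <- lapply(seq_len(n_g), function(g) {
    e <- te[te$gene == def$genes$id[g], , drop = FALSE]
    if (!nrow(e)) return(NULL)
    list(reg = resolve_states(e$regulator, "tf edge"),
         sign = e$sign, Q_max = e$Q_max, Q_hat = e$Q_hat, hill = e$hill,
         basal = e$basal, cap = max(e$Q_max))
  })
  if (n_g) {
    bad <- setdiff(te$gene, def$genes$id)
    if (length(bad)) nss_error("tf edge references unknown gene '%s'", bad[1])
  } else if (nrow(te)) {
    nss_error("tf edges declared but no genes")
  }
  net$rt <- rt
  net
}

#' Initial (baseline) state vector of a network
#'
#' Every metabolite, enzyme, mRNA and protein state is 1; each
#' enzyme-substrate complex equals its reaction's `w`; switch pools sit at
#' their baseline partition (1, 1). By construction of the derived rate
#' constants this vector is an exact fixed point of the assembled system.
#'
#' @param network an `nss_network`.
#' @return named numeric state vector.
#' @export
initialize_state <- function(network) {
  rt <- network$rt
  y <- rep(1, rt$n_states)
  names(y) <- rt$labels
  if (length(rt$er)) y[rt$er_cplx] <- network$reactions$w[rt$er]
  y
}

#' Structural and parameter-count statistics of a network
#'
#' Counts entities and classifies parameters into the independent categories
#' (flux distribution, reaction reversibility, free-bound enzyme ratio, gene
#' expression control, stoichiometric multipliers) and the dependent
#' set-at-initialization constants.
#'
#' @param network an `nss_network`.
#' @return an object of class `nss_structure_stats` (a list of counts).
#' @export
structure_stats <- function(network) {
  def <- network$definition
  rx <- network$reactions
  n_r <- nrow(rx)
  n_er <- sum(rx$enzymatic)
  n_stoich <- sum(vapply(network$subs, nrow, integer(1)),
                  vapply(network$prods, nrow, integer(1)))
  gene_pars <- nrow(def$genes) * 2 +            # k_d, k_t(=k_dp)
    nrow(def$tf_edges) * 3 +                    # Q_max, Q_hat, hill
    nrow(def$switches) * 2                      # k_a, k_d
  dependent <- 4 * n_er + 2 * (n_r - n_er) +    # rate constants
    length(network$rt$sink_k) +                 # auto-sink rates
    nrow(def$switches) * 2                      # derived k_i, synthesis flux
  out <- list(
    n_reactions = n_r,
    n_metabolites = nrow(network$metab),
    n_enzymes = length(network$rt$enz_ids),
    n_regulatory_proteins = length(network$rt$prot_ids) + network$rt$n_s,
    n_genes = nrow(def$genes),
    n_states = network$rt$n_states,
    n_parameters_by_category = c(
      flux_distribution = nrow(def$branches),
      reaction_reversibility = n_r,
      free_bound_enzyme_ratio = n_er,
      gene_expression_control = gene_pars,
      stoichiometric = n_stoich,
      set_at_initialization = dependent)
  )
  structure(out, class = "nss_structure_stats")
}

#' @export
print.nss_structure_stats <- function(x, ...) {
  cat(sprintf("%d reactions, %d metabolites, %d enzymes, %d regulatory proteins; %d states\n",
              x$n_reactions, x$n_metabolites, x$n_enzymes,
              x$n_regulatory_proteins, x$n_states))
  cat("parameters:\n")
  p <- x$n_parameters_by_category
  for (nm in names(p)) cat(sprintf("  %-26s %d\n", nm, p[[nm]]))
  invisible(x)
}

#' @export
print.nss_network <- function(x, ...) {
  cat("<nss_network> ")
  print(structure_stats(x))
  invisible(x)
}

#' Change a branch-point flux fraction (with sibling renormalization)
#'
#' Sets child `child` of the branch at `parent` to fraction `f_new` and
#' rescales all siblings by a common factor so the fractions still sum to 1
#' exactly. Only the rate constants of the reactions at this branch (and the
#' parent's export rate, if the branch has a `sink` child) are re-derived
#' from the new fractions; every other parameter keeps the value it received
#' at baseline initialization. The all-ones state is therefore no longer an
#' equilibrium of the modified network — the change in flux distribution is
#' the disturbance whose propagated steady-state response the sensitivity
#' analysis measures.
#'
#' @param network an `nss_network`.
#' @param parent branch parent metabolite id.
#' @param child branch child (reaction id or `"sink"`).
#' @param f_new new fraction in (0, 1).
#' @return the modified `nss_network`.
#' @export
set_branch_fraction <- function(network, parent, child, f_new) {
  net <- network
  def <- net$definition
  br <- def$branches
  i <- which(br$parent == parent & br$child == child)
  if (!length(i)) nss_error("no branch row for parent '%s' child '%s'", parent, child)
  sib <- which(br$parent == parent & br$child != child)
  f_old <- br$f[i]
  if (f_new <= 0 || (f_new >= 1 && length(sib)))
    nss_error("f_new must lie in (0, 1) when siblings exist, got %g", f_new)
  br$f[i] <- f_new
  if (length(sib)) br$f[sib] <- br$f[sib] * (1 - f_new) / (1 - f_old)
  rows <- which(br$parent == parent)
  br$f[rows] <- br$f[rows] / sum(br$f[rows])
  def$branches <- br
  net$definition <- def

  m <- match(parent, net$metab$id)
  avail <- net$metab$avail[m]
  for (j in rows) {
    ch <- br$child[j]
    if (ch == "sink") {
      net$metab$sink_k[m] <- br$f[j] * avail
      next
    }
    k <- match(ch, net$reactions$id)
    nu1 <- net$subs[[k]]$nu[1]
    phi <- br$f[j] * avail / nu1
    net$reactions$f[k] <- br$f[j]
    net$reactions$throughput[k] <- phi
    if (net$reactions$enzymatic[k]) {
      ks <- derive_rate_constants(net$reactions$r[k], net$reactions$w[k], phi)
      net$reactions$k_C[k] <- ks$k_C; net$reactions$k_P[k] <- ks$k_P
      net$reactions$k_CR[k] <- ks$k_CR; net$reactions$k_PR[k] <- ks$k_PR
    } else {
      r <- net$reactions$r[k]
      net$reactions$k_T[k] <- phi / (1 - r)
      net$reactions$k_TR[k] <- r * phi / (1 - r)
    }
  }
  index_states(net)
}
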