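# Pure-function rate laws for the gene-expression and post-translational
# regulatory layer. Every law is normalized so that with all drivers at 1 the
# net rate is exactly 0, preserving the global all-ones fixed point when
# regulation is wired into a metabolic network.

# per-regulator production factor, equal to 1 at the baseline level Q_C = 1.
# negative control: bounded decreasing sigmoid Q_max/(1 + (Q_max-1) Q_C^h),
#   upper asymptote Q_max as Q_C -> 0, lower asymptote 0 as Q_C -> Inf.
# positive control: clamped Hill sigmoid with a basal floor,
#   p(q) = basal + (Q_max - basal) * min(H(q), H(Q_hat)) / H(Q_hat),
#   H(q) = q^h/(q^h + K) with K fixed by the baseline condition p(1) = 1.
#   It rises from the basal level, passes 1 at the baseline regulator level,
#   reaches Q_max exactly at the saturating level Q_hat and is clamped there
#   beyond. Feasibility requires (1-basal)/(Q_max-basal) > Q_hat^-hill (a
#   Hill curve of steepness h cannot span the required rise over [1, Q_hat]
#   otherwise).
regulation_factor <- function(q, sign, Q_max, Q_hat = 10, hill = 2, basal = 0.05) {
  q <- pmax(q, 0)
  if (sign < 0) {
    Q_max / (1 + (Q_max - 1) * q^hill)
  } else {
    rho <- (1 - basal) / (Q_max - basal)
    Qh <- Q_hat^hill
    if (rho * Qh <= 1)
      nss_error("positive control with Q_max=%g, Q_hat=%g, hill=%g, basal=%g has no dynamic range",
                Q_max, Q_hat, hill, basal)
    K <- Qh * (1 - rho) / (rho * Qh - 1)
    H <- function(x) x^hill / (x^hill + K)
    basal + (Q_max - basal) * pmin(H(q), H(Q_hat)) / H(Q_hat)
  }
}

#' Transcription rate of a gene-expression node
#'
#' Production is a bounded sigmoid of each regulator level — monotone
#' decreasing for negative control, increasing for positive control and
#' saturating exactly at `Q_max` when a positive regulator reaches its level
#' of maximal effect `Q_hat` — minus first-order mRNA degradation. With every
#' regulator at its baseline level 1 and `Q_mRNA = 1` the net rate is exactly
#' zero. Factors from several independent regulators multiply, capped at the
#' largest `Q_max` so the steady-state mRNA stays within \[0, Q_max].
#'
#' @param node list with `Q_max` (> 1), `k_d` (mRNA degradation rate),
#'   `sign` (vector, +1/-1 per regulator), and optionally `Q_hat`, `hill`
#'   (recycled over regulators).
#' @param regulator_levels numeric vector of current regulator levels (>= 0).
#' @param Q_mRNA current mRNA level.
#' @return dQ_mRNA/dt.
#' @export
transcription_rate <- function(node, regulator_levels, Q_mRNA = 1) {
  if (any(regulator_levels < 0)) nss_error("regulator levels must be >= 0")
  if (any(node$Q_max <= 1)) nss_error("Q_max must exceed 1 (no dynamic range)")
  n <- length(regulator_levels)
  Q_max <- rep_len(node$Q_max, n)
  Q_hat <- rep_len(node$Q_hat %||% 10, n)
  hill <- rep_len(node$hill %||% 2, n)
  basal <- rep_len(node$basal %||% 0.05, n)
  sgn <- rep_len(node$sign, n)
  fac <- 1
  for (j in seq_len(n))
    fac <- fac * regulation_factor(regulator_levels[j], sgn[j], Q_max[j], Q_hat[j],
                                   hill[j], basal[j])
  fac <- min(fac, max(Q_max))
  node$k_d * fac - node$k_d * Q_mRNA
}

#' Translation rate of a protein node
#'
#' Linear synthesis from mRNA minus first-order degradation:
#' `k_t * Q_mRNA - k_d * Q_P`; zero at the all-ones baseline when
#' `k_t = k_d`.
#'
#' @param node list with `k_t` and `k_d`.
#' @param Q_mRNA mRNA level (>= 0).
#' @param Q_P protein level.
#' @return dQ_P/dt.
#' @export
translation_rate <- function(node, Q_mRNA, Q_P = 1) {
  node$k_t * Q_mRNA - node$k_d * Q_P
}

#' Rates of a post-translational activation/inactivation switch
#'
#' Activation transfers mass from the inactive to the active pool at rate
#' `k_a * Q_M_act * Q_CI`; inactivation transfers it back at
#' `k_i * Q_M_inh * Q_CA`. Both pools degrade at `k_d` and the inactive pool
#' receives the constant synthesis flux `2 * k_d`. Total protein is therefore
#' governed only by synthesis and degradation, never by switching. With the
#' baseline partition (both pools 1) and drivers at 1, and the derived
#' `k_i = k_a - k_d`, both rates are exactly zero.
#'
#' @param switch list with `k_a`, `k_d` (and optionally `k_i`, otherwise
#'   derived as `k_a - k_d`).
#' @param Q_M driver level(s): scalar applied to activation, or a list with
#'   components `act` and `inh`.
#' @param Q_CA,Q_CI current active and inactive pools.
#' @return list with `dQ_CA`, `dQ_CI`.
#' @export
switch_rates <- function(switch, Q_M, Q_CA = 1, Q_CI = 1) {
  if (Q_CA < 0 || Q_CI < 0) nss_error("switch pools must be >= 0")
  k_i <- switch$k_i %||% (switch$k_a - switch$k_d)
  qa <- if (is.list(Q_M)) Q_M$act %||% 1 else Q_M
  qi <- if (is.list(Q_M)) Q_M$inh %||% 1 else 1
  act <- switch$k_a * qa * Q_CI
  inact <- k_i * qi * Q_CA
  syn <- 2 * switch$k_d
  list(dQ_CA = act - inact - switch$k_d * Q_CA,
       dQ_CI = syn - act + inact - switch$k_d * Q_CI)
}
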