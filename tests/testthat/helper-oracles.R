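# Independent oracles used by the tests. These deliberately avoid the
# package's assembled-derivative code path: the single-reaction mechanism is
# written out explicitly and integrated with deSolve directly.

# Reversible two-step mechanism S + E <-> C <-> E + P with constant enzyme
# turnover, a unit source split f/(1-f) between the reaction and a
# first-order alternative route, and first-order product demand. Rate
# constants are rebuilt here from first principles (not via
# derive_rate_constants).
brute_force_single_reaction <- function(r, f, w, influx_fold = 1,
                                        efflux_demand = 1, k_dE = 0.01,
                                        t_end = 2e5) {
  phi <- f                       # baseline throughput of the reaction
  kC <- phi / (1 - r)
  kCR <- r * phi / ((1 - r) * w)
  kP <- phi / ((1 - r) * w)
  kPR <- r * phi / (1 - r)
  k_alt <- 1 - f                 # alternative-branch demand on S
  k_out <- f * efflux_demand     # product demand
  rhs <- function(t, y, p) {
    S <- y[1]; E <- y[2]; C <- y[3]; P <- y[4]
    vb <- kC * S * E - kCR * C
    vc <- kP * C - kPR * P * E
    list(c(influx_fold - k_alt * S - vb,
           k_dE - k_dE * E - vb + vc,
           vb - vc,
           vc - k_out * P))
  }
  y0 <- c(S = 1, E = 1, C = w, P = 1)
  out <- deSolve::lsoda(y0, c(0, t_end), rhs, NULL, rtol = 1e-11, atol = 1e-13)
  y <- out[nrow(out), -1]
  resid <- max(abs(unlist(rhs(0, y, NULL))))
  stopifnot(resid < 1e-9)
  y
}

# independent finite-difference control coefficient: two steady-state runs
# and the relative-sensitivity formula, written out in place
fd_coefficient <- function(net, parent, child, target, delta, background = NULL,
                           t_end = 1e5) {
  br <- net$definition$branches
  f0 <- br$f[br$parent == parent & br$child == child]
  ss0 <- steady_state(net, background, t_end = t_end)
  net1 <- set_branch_fraction(net, parent, child, f0 * (1 + delta))
  ss1 <- steady_state(net1, background, t_end = t_end)
  stopifnot(ss0$converged, ss1$converged)
  fr <- realized_flux_fractions(net1, ss1$state, parent, ss1$final_parms)
  fstar <- fr$f_star[fr$child == child]
  tg0 <- unname(ss0$state[target]); tg1 <- unname(ss1$state[target])
  den <- fstar - f0
  if (abs(den) < 1e-12) den <- f0 * delta
  (tg1 - tg0) / den * (f0 / tg0)
}

# a nonlinear toy: two-branch split where child 1's enzyme is repressed by
# its own product (negative feedback makes the response to f genuinely
# nonlinear)
make_regulated_branch_toy <- function() {
  def <- model_definition(
    compartments = "liver",
    metabolites = data.frame(id = c("M", "P1", "P2"), compartment = "liver"),
    enzymes = data.frame(id = c("E1", "E2"), compartment = "liver",
                         gene = c("e1_g", NA)),
    reactions = data.frame(id = c("c1", "c2"), substrates = "M",
                           products = c("P1", "P2"),
                           enzyme = c("E1", "E2"), r = 0, w = 1),
    branches = data.frame(parent = "M", child = c("c1", "c2"), f = c(0.6, 0.4)),
    sources = data.frame(target = "M", phi = 1),
    genes = data.frame(id = "e1_g", target_type = "enzyme", target = "E1"),
    tf_edges = data.frame(gene = "e1_g", regulator = "P1", sign = -1,
                          Q_max = 10, Q_hat = 10, hill = 2))
  build_network(def)
}

# definition of a minimal single-reaction network with a branch fraction f
# routed into the reaction and (1-f) into an export sink
single_reaction_network <- function(r = 0, f = 0.6, w = 1) {
  def <- model_definition(
    compartments = "liver",
    metabolites = data.frame(id = c("S", "P"), compartment = "liver"),
    enzymes = data.frame(id = "E", compartment = "liver"),
    reactions = data.frame(id = "rx", substrates = "S", products = "P",
                           enzyme = "E", r = r, w = w),
    branches = data.frame(parent = "S", child = c("rx", "sink"), f = c(f, 1 - f)),
    sources = data.frame(target = "S", phi = 1))
  build_network(def)
}
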