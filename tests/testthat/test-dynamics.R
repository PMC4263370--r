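test_that("the assembled derivative vanishes at baseline and has correct signs", {
  net <- single_reaction_network(r = 0.2, f = 0.6, w = 0.5)
  f <- assemble_rhs(net)
  y0 <- initialize_state(net)
  expect_lt(max(abs(f(0, y0)[[1]])), 1e-12)

  # substrate doubled by hand: S is consumed faster, complex builds up
  y <- y0; y["S"] <- 2
  dy <- stats::setNames(f(0, y)[[1]], names(y0))
  expect_lt(dy[["S"]], 0)
  expect_gt(dy[["C:rx"]], 0)

  # influx fold x10: substrate derivative positive at t = 0+
  legs <- nssnet:::perturbation_legs(net, perturbation("S", "influx_fold", 10), 1)
  dy10 <- stats::setNames(f(0, y0, legs[[1]]$parms)[[1]], names(y0))
  expect_gt(dy10[["S"]], 0)

  expect_error(f(0, c(1, 2, 3)), "length")
})

test_that("unperturbed trajectories stay at baseline", {
  net <- make_toy_networks()$chain
  tr <- integrate_network(net, t_end = 1e4)
  expect_false(tr$failed)
  expect_lt(max(abs(sweep(tr$states, 2, initialize_state(net)))), 1e-8)
  ss <- detect_steady_state(tr)
  expect_true(ss$converged)
  expect_equal(unname(ss$fold_changes), rep(1, length(ss$fold_changes)))
})

test_that("integrated steady states match the closed form (oracle equivalence)", {
  for (u in c(0.1, 0.5, 2, 10)) {
    for (r in c(0, 0.5)) {
      net <- single_reaction_network(r = r, f = 0.6, w = 1)
      ss <- steady_state(net, perturbation("S", "influx_fold", u), t_end = 3e5)
      expect_true(ss$converged)
      pred <- predict_single_reaction_steady_state(r, 0.6, 1, u, 1)
      expect_equal(ss$state[["S"]], pred$S, tolerance = 1e-6)
      expect_equal(ss$state[["E"]], pred$E, tolerance = 1e-6)
      expect_equal(ss$state[["C:rx"]], pred$C, tolerance = 1e-6)
      expect_equal(ss$state[["P"]], pred$P, tolerance = 1e-6)
    }
  }
})

test_that("the closed form agrees with an independent mechanistic integration", {
  cases <- list(c(r = 0, w = 1, f = 1, u = 2, d = 1),
                c(r = 0, w = 1, f = 0.6, u = 2, d = 3),
                c(r = 0.5, w = 0.4, f = 0.3, u = 0.2, d = 0.5),
                c(r = 0.8, w = 5, f = 0.7, u = 4, d = 2))
  for (cs in cases) {
    cs <- as.list(cs)
    y <- brute_force_single_reaction(cs$r, cs$f, cs$w, cs$u, cs$d)
    pred <- predict_single_reaction_steady_state(cs$r, cs$f, cs$w, cs$u, cs$d)
    expect_equal(unname(y["S"]), pred$S, tolerance = 1e-6)
    expect_equal(unname(y["E"]), pred$E, tolerance = 1e-6)
    expect_equal(unname(y["C"]), pred$C, tolerance = 1e-6)
    expect_equal(unname(y["P"]), pred$P, tolerance = 1e-6)
  }
})

test_that("relative steady state does not depend on the absolute flux scale", {
  base <- predict_single_reaction_steady_state(0.5, 0.4, 2, 1, 1)
  expect_equal(base[c("S", "E", "P")], list(S = 1, E = 1, P = 1))
  expect_equal(base$C, 2)
  expect_equal(base$f_star, 0.4)
  # at fixed demand, scaling the influx scales every concentration by the
  # same factor: ratios and the realized fraction are flux-scale free
  for (d in c(0.5, 1, 3)) {
    a <- predict_single_reaction_steady_state(0.5, 0.4, 2, 2, d)
    b <- predict_single_reaction_steady_state(0.5, 0.4, 2, 6, d)
    expect_equal(b$S / a$S, 3, tolerance = 1e-12)
    expect_equal(b$P / a$P, 3, tolerance = 1e-12)
    expect_equal(a$f_star, b$f_star, tolerance = 1e-12)
    expect_equal(a$S / a$P, b$S / b$P, tolerance = 1e-12)
  }
})

test_that("re-integrating from a converged state is idempotent", {
  net <- make_toy_networks()$chain
  p <- perturbation("S", "influx_fold", 2)
  ss <- steady_state(net, p, t_end = 1e5)
  tr2 <- integrate_network(net, p, t_end = 1e4, init = ss$state)
  expect_lt(max(abs(sweep(tr2$states, 2, ss$state))), 1e-6)
})

test_that("perturbation events are handled exactly (split vs delayed run)", {
  net <- make_toy_networks()$chain
  t0 <- 500
  tr <- integrate_network(net, perturbation("S", "influx_fold", 3, start_time = t0),
                          t_end = 2e3)
  expect_equal(tr$events, t0)
  # manual split: baseline to t0, then perturbed from the reached state
  tr1 <- integrate_network(net, t_end = t0)
  y_mid <- tr1$states[nrow(tr1$states), ]
  tr2 <- integrate_network(net, perturbation("S", "influx_fold", 3),
                           t_end = 2e3 - t0, init = y_mid)
  end_split <- tr2$states[nrow(tr2$states), ]
  end_event <- tr$states[nrow(tr$states), ]
  expect_equal(unname(end_event), unname(end_split), tolerance = 1e-7)
})

test_that("knockout drives the enzyme toward zero", {
  net <- make_toy_networks()$chain
  ss <- steady_state(net, perturbation("E2", "knockout"), t_end = 3e5)
  expect_lt(ss$state[["E2"]], 2e-3)
})

test_that("monotone response: larger influx never lowers downstream products", {
  net <- make_toy_networks()$chain
  folds <- c(1, 2, 5)
  p_ss <- vapply(folds, function(u)
    steady_state(net, perturbation("S", "influx_fold", u), t_end = 1e5)$state[["P"]],
    numeric(1))
  expect_true(all(diff(p_ss) > 0))
})

test_that("overloading a capacity-limited route is flagged, not raised", {
  net <- make_toy_networks()$branch_sat
  # demand f*u on the secondary substrate X exceeds its fixed supply
  ss <- steady_state(net, perturbation("M", "influx_fold", 3), t_end = 1e5)
  expect_false(ss$converged)
  expect_true(ss$mode %in% c("non-convergence", "divergence"))
})

test_that("realized flux fractions recover declared fractions at baseline", {
  net <- make_toy_networks()$branch2
  y0 <- initialize_state(net)
  fr <- realized_flux_fractions(net, y0, "M")
  expect_equal(fr$f_star, fr$f, tolerance = 1e-12)
  expect_equal(sum(fr$f_star), 1, tolerance = 1e-12)

  # knocking out child 1's enzyme reroutes all flux to child 2
  ss <- steady_state(net, perturbation("E1", "knockout"), t_end = 3e5)
  fr2 <- realized_flux_fractions(net, ss$state, "M", ss$final_parms)
  expect_lt(fr2$f_star[fr2$child == "c1"], 0.01)
  expect_gt(fr2$f_star[fr2$child == "c2"], 0.99)
  expect_equal(sum(fr2$f_star), 1, tolerance = 1e-9)
})

test_that("time rescaling preserves steady states, w only transients", {
  toys <- make_toy_networks()
  p <- perturbation("S", "influx_fold", 2)
  ref <- steady_state(toys$chain, p, t_end = 1e5)

  fast <- build_network(rescale_time(toys$chain$definition, 5))
  ss_fast <- steady_state(fast, p, t_end = 1e5)
  expect_equal(unname(ss_fast$state), unname(ref$state), tolerance = 1e-8)

  for (w in c(0.3, 5)) {
    def_w <- toys$chain$definition
    def_w$reactions$w <- w
    net_w <- build_network(def_w)
    ss_w <- steady_state(net_w, p, t_end = 3e5)
    keep <- setdiff(names(ss_w$state), grep("^C:", names(ss_w$state), value = TRUE))
    expect_equal(ss_w$state[keep], ref$state[keep], tolerance = 1e-8)
  }
})
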