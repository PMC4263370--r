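test_that("control coefficients on the linear two-branch toy are analytic", {
  net <- make_toy_networks()$branch2
  # P1 is proportional to f1, so C^{P1}_{f1} = 1 exactly;
  # P2 is proportional to (1 - f1), so C^{P2}_{f1} = -f1/(1 - f1)
  r1 <- concentration_control_coefficient(net, "M", "c1", "P1", delta = 0.1,
                                          t_end = 5e4)
  expect_true(r1$stable)
  expect_equal(r1$coefficient, 1, tolerance = 1e-6)
  expect_equal(r1$f_star, 0.77, tolerance = 1e-9)
  r2 <- concentration_control_coefficient(net, "M", "c1", "P2", delta = 0.1,
                                          t_end = 5e4)
  expect_equal(r2$coefficient, -0.7 / 0.3, tolerance = 1e-6)
  expect_equal(classify_impact(r2$coefficient), "high")
})

test_that("a target decoupled from the branch has zero coefficient", {
  # two identical downstream chains fed by an independent source
  def <- model_definition("liver",
    data.frame(id = c("M", "P1", "P2", "Z", "ZP"), compartment = "liver"),
    data.frame(id = c("c1", "c2", "z1"), substrates = c("M", "M", "Z"),
               products = c("P1", "P2", "ZP"), enzyme = NA, r = 0, w = 1),
    branches = data.frame(parent = "M", child = c("c1", "c2"), f = c(0.5, 0.5)),
    sources = data.frame(target = c("M", "Z"), phi = 1))
  net <- build_network(def)
  rec <- concentration_control_coefficient(net, "M", "c1", "ZP", delta = 0.1,
                                           t_end = 5e4)
  expect_equal(rec$coefficient, 0, tolerance = 1e-9)
  expect_equal(classify_impact(rec$coefficient), "low")
})

test_that("coefficients match an independent finite-difference recomputation", {
  net <- make_regulated_branch_toy()
  for (target in c("P1", "P2", "E1")) {
    rec <- concentration_control_coefficient(net, "M", "c1", target,
                                             delta = 0.1, t_end = 1e5)
    ora <- fd_coefficient(net, "M", "c1", target, delta = 0.1, t_end = 1e5)
    expect_true(rec$stable)
    expect_equal(rec$coefficient, ora, tolerance = 1e-7)  # 6+ significant figures
  }
})

test_that("halving delta moves smooth-toy coefficients by less than 20%", {
  net <- make_regulated_branch_toy()
  c10 <- concentration_control_coefficient(net, "M", "c1", "P1", delta = 0.1,
                                           t_end = 1e5)$coefficient
  c05 <- concentration_control_coefficient(net, "M", "c1", "P1", delta = 0.05,
                                           t_end = 1e5)$coefficient
  expect_lt(abs(c10 - c05) / abs(c05), 0.2)
})

test_that("impact classification follows the printed bounds", {
  expect_equal(classify_impact(2.781), "high")
  expect_equal(classify_impact(2.098), "high")
  expect_equal(classify_impact(0.5), "moderate")
  expect_equal(classify_impact(-0.05), "low")
  # closed boundaries and the gap between 0.99 and 1
  expect_equal(classify_impact(1.0), "high")
  expect_equal(classify_impact(0.995), "high")
  expect_equal(classify_impact(0.99), "moderate")
  expect_equal(classify_impact(0.1), "moderate")
  expect_equal(classify_impact(-0.1), "moderate")
  expect_equal(classify_impact(NaN), "unclassified")
  # every finite value maps to exactly one class
  grid <- c(-3, -1, -0.5, -0.09, 0, 0.09, 0.1, 0.5, 0.99, 0.995, 1, 4)
  expect_true(all(classify_impact(grid) %in% c("high", "moderate", "low")))
})

test_that("branch scans are complete, ordered and robust to instability", {
  net <- make_toy_networks()$branch2
  sc <- scan_branches(net, "P1", delta_grid = c(-0.1, 0.1), t_end = 5e4)
  expect_equal(nrow(sc), 4)   # 2 children x 2 grid points
  expect_equal(sc$child, c("c1", "c1", "c2", "c2"))
  expect_true(all(sc$stable))
  # each record agrees with one-at-a-time recomputation
  for (i in seq_len(nrow(sc))) {
    one <- concentration_control_coefficient(net, sc$parent[i], sc$child[i],
                                             "P1", delta = sc$delta[i],
                                             t_end = 5e4)
    expect_equal(sc$coefficient[i], one$coefficient, tolerance = 1e-9)
  }

  # a scan across a capacity-limited branch flags the unstable points and
  # still completes
  sat <- make_toy_networks()$branch_sat
  bg <- perturbation("M", "influx_fold", 1.5)
  sc2 <- scan_branches(sat, "Q", delta_grid = c(-0.1, 2), background = bg,
                       t_end = 1e5)
  expect_equal(nrow(sc2), 4)
  expect_true(any(!sc2$stable))
  # shrinking c1 keeps the co-substrate demand under its supply cap
  expect_true(all(sc2$stable[sc2$child == "c1" & sc2$delta == -0.1]))
  # growing c1 far past the cap is flagged unstable
  expect_false(any(sc2$stable[sc2$child == "c1" & sc2$delta == 2]))
})

test_that("tolerance ranges find the stable interval around the baseline", {
  sat <- make_toy_networks()$branch_sat
  bg <- perturbation("M", "influx_fold", 1.5)
  tr <- tolerance_range(sat, "M", "c1", "Q", background = bg,
                        resolution = 0.05, t_end = 1e5)
  expect_equal(tr$f_lo, 0.05)
  # X supplies 0.3 while demand is f * 1.5: capacity is exhausted at f = 0.2
  # (a marginal, algebraically slow point), so the last stable grid value is
  # one resolution step below
  expect_equal(tr$f_hi, 0.15)
  expect_true(tr$mode_hi %in% c("non-convergence", "divergence"))
  expect_equal(tr$mode_lo, "none")
  expect_true(all(tr$grid$stable[tr$grid$f <= tr$f_hi]))

  # a globally stable branch spans the whole grid
  net <- make_toy_networks()$branch2
  tr2 <- tolerance_range(net, "M", "c1", "P1", resolution = 0.25, t_end = 5e4)
  expect_equal(tr2$mode_hi, "none")
  expect_equal(tr2$mode_lo, "none")
})

test_that("regulator sensitivity reuses the same formula per regulator", {
  net <- make_regulated_branch_toy()
  tab <- regulator_sensitivity(net, "M", "c1", c("e1_g", "E1"), delta = 0.1,
                               t_end = 1e5)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$target, c("e1_g", "E1"))
  for (i in 1:2)
    expect_equal(tab$coefficient[i],
                 fd_coefficient(net, "M", "c1", tab$target[i], 0.1, t_end = 1e5),
                 tolerance = 1e-7)
})
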