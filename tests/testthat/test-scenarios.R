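test_that("toy fixtures match their manifests and oracles", {
  toys <- make_toy_networks()
  for (nm in names(toys)) {
    man <- attr(toys[[nm]], "manifest")
    st <- structure_stats(toys[[nm]])
    for (k in names(man)) expect_equal(st[[k]], man[[k]], info = paste(nm, k))
    expect_lt(network_residual(toys[[nm]]), 1e-10)
  }
  # chain under influx x2: every step matches the closed form (u-scaling)
  ss <- steady_state(toys$chain, perturbation("S", "influx_fold", 2), t_end = 1e5)
  pred <- predict_single_reaction_steady_state(0, 1, 1, 2, 1)
  for (v in c("S", "A", "B", "P")) expect_equal(ss$state[[v]], pred$S, tolerance = 1e-6)
  # branch2 baseline child fluxes are 0.7 / 0.3
  expect_equal(toys$branch2$reactions$throughput, c(0.7, 0.3))
  # negative feedback: response to influx x2 is sub-linear
  fb <- steady_state(toys$feedback_loop, perturbation("S", "influx_fold", 2),
                     t_end = 3e5)
  expect_true(fb$converged)
  expect_lt(fb$state[["P"]], 2)
  expect_gt(fb$state[["P"]], 1)
})

test_that("direction verdicts follow the margin semantics", {
  folds <- c(a = 1.0, b = 0.2, c = 1.04, d = 1.2)
  exps <- data.frame(variable = c("a", "b", "c", "d", "missing"),
                     direction = c("unchanged", "down", "unchanged", "up", "up"))
  v <- check_directions(folds, exps, margin = 0.05)
  expect_equal(v$verdict, c("unchanged", "down", "unchanged", "up", "uncovered"))
  expect_equal(v$pass, c(TRUE, TRUE, TRUE, TRUE, NA))
  expect_error(check_directions(folds, exps, margin = 0.6), "margin")
})

test_that("scenario specs validate their phases", {
  expect_error(scenario("x", list(list(perturbation = NULL, t_end = -1)),
                        data.frame(variable = "a", direction = "up")),
               "durations")
  expect_error(perturbation("x", "influx_fold", -2), "magnitude")
})

test_that("phase chaining equals separate runs from saved states", {
  net <- make_toy_networks()$chain
  sc <- scenario("two_step",
                 phases = list(
                   list(perturbation = perturbation("S", "influx_fold", 2),
                        t_end = 1e5),
                   list(perturbation = perturbation("S", "influx_fold", 0.5),
                        t_end = 1e5)),
                 expectations = data.frame(variable = "P", direction = "down",
                                           phase = 2))
  rep <- run_scenario(net, sc)
  expect_true(rep$pass)
  # manual chaining
  s1 <- steady_state(net, perturbation("S", "influx_fold", 2), t_end = 1e5)
  s2 <- steady_state(net, perturbation("S", "influx_fold", 0.5), t_end = 1e5,
                     init = s1$state)
  expect_equal(unname(rep$phases[[2]]$state), unname(s2$state), tolerance = 1e-8)
})

test_that("uncovered expectation rows are listed, not silently dropped", {
  net <- make_toy_networks()$chain
  sc <- scenario("cover",
                 phases = list(list(perturbation = perturbation("S", "influx_fold", 2),
                                    t_end = 5e4)),
                 expectations = data.frame(variable = c("P", "urea"),
                                           direction = "up", phase = 1))
  rep <- run_scenario(net, sc)
  expect_equal(rep$uncovered, "urea")
  expect_equal(rep$n_covered, 1)
  expect_true(rep$pass)
})

test_that("the four validation scenarios are well formed", {
  scs <- validation_scenarios()
  expect_named(scs, c("fasting", "scd_knockout", "adiponectin", "ppara_agonist"))
  n_rows <- sum(vapply(scs, function(s) nrow(s$expectations), integer(1)))
  expect_gte(n_rows, 20)
  for (s in scs) {
    expect_true(all(s$expectations$direction %in% c("up", "down", "unchanged")))
    expect_true(all(s$expectations$phase <= length(s$phases)))
  }
  # the knockout scenario carries its diet-matched control protocol
  expect_length(scs$scd_knockout$control_phases, 2)
})
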