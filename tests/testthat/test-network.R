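test_that("derived rate constants realize throughput and reversibility exactly", {
  cases <- expand.grid(r = c(0, 0.3, 0.5, 0.8), w = c(0.1, 1, 7),
                       phi = c(0.2, 1, 3))
  for (i in seq_len(nrow(cases))) {
    r <- cases$r[i]; w <- cases$w[i]; phi <- cases$phi[i]
    k <- derive_rate_constants(r, w, phi)
    # net flux through each elementary step at the normalized state
    expect_equal(k$k_C * 1 - k$k_CR * w, phi, tolerance = 1e-12)
    expect_equal(k$k_P * w - k$k_PR * 1, phi, tolerance = 1e-12)
    if (r == 0) {
      expect_identical(k$k_CR, 0)
      expect_identical(k$k_PR, 0)
    } else {
      # realized reverse/forward flux ratio equals r on each step
      expect_equal(k$k_CR * w / k$k_C, r, tolerance = 1e-12)
      expect_equal(k$k_PR / (k$k_P * w), r, tolerance = 1e-12)
    }
  }
  expect_error(derive_rate_constants(1, 1, 1), "infeasible reversibility")
  expect_error(derive_rate_constants(0.5, 0, 1), "domain error")
  expect_error(derive_rate_constants(0.5, 1, 0), "throughput")
})

test_that("a minimal network builds with the expected states", {
  net <- single_reaction_network()
  expect_equal(net$rt$n_states, 4)        # S, P, E, complex
  st <- structure_stats(net)
  expect_equal(st$n_reactions, 1)
  expect_equal(st$n_metabolites, 2)
  expect_equal(st$n_enzymes, 1)
  expect_equal(st$n_regulatory_proteins, 0)
  expect_lt(network_residual(net), 1e-10)
})

test_that("structural errors name the offending entity", {
  met <- data.frame(id = c("a", "b"), compartment = "liver")
  bad_enzyme <- model_definition("liver", met,
    data.frame(id = "r1", substrates = "a", products = "b", enzyme = "EX",
               r = 0, w = 1),
    sources = data.frame(target = "a", phi = 1))
  expect_error(build_network(bad_enzyme), "dangling enzyme reference 'EX'")

  bad_met <- model_definition("liver", met,
    data.frame(id = "r1", substrates = "a", products = "zz", enzyme = NA,
               r = 0, w = 1),
    sources = data.frame(target = "a", phi = 1))
  expect_error(build_network(bad_met), "dangling metabolite reference 'zz'")
})

test_that("branch fractions must sum to one and the residual is reported", {
  def <- model_definition("liver",
    data.frame(id = c("m", "p1", "p2"), compartment = "liver"),
    data.frame(id = c("c1", "c2"), substrates = "m", products = c("p1", "p2"),
               enzyme = NA, r = 0, w = 1),
    branches = data.frame(parent = "m", child = c("c1", "c2"), f = c(0.6, 0.3)),
    sources = data.frame(target = "m", phi = 1))
  err <- tryCatch(build_network(def), error = identity)
  expect_match(conditionMessage(err), "sum to 0.9")
  expect_match(conditionMessage(err), "residual 0.1")
})

test_that("overdrawn secondary substrates are a build error", {
  def <- model_definition("liver",
    data.frame(id = c("a", "x", "q"), compartment = "liver"),
    data.frame(id = "rx", substrates = "a + x", products = "q", enzyme = NA,
               r = 0, w = 1),
    sources = data.frame(target = c("a", "x"), phi = c(1, 0.5)))
  expect_error(build_network(def), "overdrawn")
})

test_that("initialized state is all ones with complexes at w", {
  net <- single_reaction_network(r = 0.4, w = 0.3)
  y <- initialize_state(net)
  expect_equal(unname(y[c("S", "P", "E")]), c(1, 1, 1))
  expect_equal(unname(y["C:rx"]), 0.3)
  expect_lt(network_residual(net), 1e-10)
})

test_that("the mini fixture matches its hand-counted manifest", {
  net <- make_mini_steatonet()
  man <- mini_steatonet_manifest()
  st <- structure_stats(net)
  expect_equal(st$n_reactions, man$n_reactions)
  expect_equal(st$n_metabolites, man$n_metabolites)
  expect_equal(st$n_enzymes, man$n_enzymes)
  expect_equal(st$n_genes, man$n_genes)
  expect_equal(st$n_regulatory_proteins, man$n_regulatory_proteins)
  expect_equal(st$n_states, man$n_states)
  expect_equal(st$n_parameters_by_category[["flux_distribution"]], man$n_branch_rows)

  # independent walk of the definition file itself
  lines <- readLines(system.file("extdata", "mini_steatonet.nss", package = "nssnet"))
  lines <- trimws(sub("#.*", "", lines)); lines <- lines[nzchar(lines)]
  section <- cumsum(startsWith(lines, "@"))
  names(section) <- sub("^@", "", lines[startsWith(lines, "@")])[section]
  in_sec <- function(s) sum(names(section) == s & !startsWith(lines, "@"))
  expect_equal(in_sec("metabolites"), man$n_metabolites)
  expect_equal(in_sec("enzymes"), man$n_enzymes)
  expect_equal(in_sec("reactions"), man$n_reactions)
  expect_equal(in_sec("genes"), man$n_genes)
  expect_equal(in_sec("sources"), man$n_sources)
})

test_that("unreferenced entities are reported as warnings, not errors", {
  def <- model_definition("liver",
    data.frame(id = c("a", "b", "lonely"), compartment = "liver"),
    data.frame(id = "r1", substrates = "a", products = "b", enzyme = NA,
               r = 0, w = 1),
    enzymes = data.frame(id = "unused", compartment = "liver"),
    sources = data.frame(target = "a", phi = 1))
  expect_warning(expect_warning(build_network(def), "lonely"), "unused")
})

test_that("sibling renormalization keeps fractions summing to one exactly", {
  net <- make_toy_networks()$branch2
  net2 <- set_branch_fraction(net, "M", "c1", 0.9)
  br <- net2$definition$branches
  expect_identical(sum(br$f[br$parent == "M"]), 1)
  expect_equal(br$f[br$child == "c2"], 0.1)
})
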