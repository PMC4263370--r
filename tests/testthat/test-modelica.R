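modelica_fixture <- c(
  "model MiniPathway",
  "  // one enzymatic reaction fed by a source",
  "  SysBio.Source src(phi = 1);",
  "  SysBio.Metabolite glc;",
  "  SysBio.Metabolite g6p;",
  "  SysBio.Enzyme hk(k_dE = 0.01);",
  "  SysBio.Reaction rx(r = 0.5, w = 2, f = 1);",
  "equation",
  "  connect(src.O, glc.I);",
  "  connect(glc.O, rx.S);",
  "  connect(rx.P, g6p.I);",
  "  connect(hk.E, rx.E);",
  "end MiniPathway;")

test_that("a handcrafted component/connect fixture imports to one reaction", {
  imp <- import_modelica_subset(modelica_fixture)
  def <- imp$definition
  expect_equal(nrow(def$reactions), 1)
  expect_equal(def$reactions$substrates, "glc")
  expect_equal(def$reactions$products, "g6p")
  expect_equal(def$reactions$enzyme, "hk")
  expect_equal(def$reactions$r, 0.5)
  expect_equal(def$reactions$w, 2)
  expect_equal(def$sources$target, "glc")
  expect_equal(imp$report$n_connects, 4)
  # the imported definition builds and holds the fixed point
  net <- build_network(def, quiet = TRUE)
  expect_lt(network_residual(net), 1e-10)
})

test_that("an empty model yields an empty definition and report", {
  imp <- import_modelica_subset(c("model Empty", "end Empty;"))
  expect_equal(nrow(imp$definition$reactions), 0)
  expect_equal(imp$report$n_recognized, 0)
  expect_equal(imp$report$n_unrecognized, 0)
})

test_that("unrecognized constructs are reported with line numbers, never dropped", {
  txt <- c(modelica_fixture[1:7],
           "  Weird.FluxCapacitor fc(power = 1.21);",
           modelica_fixture[8:13])
  imp <- import_modelica_subset(txt)
  expect_equal(imp$report$n_unrecognized, 1)
  expect_match(imp$report$unrecognized$text, "FluxCapacitor")
  expect_equal(imp$report$unrecognized$line, 8)
  # conservatism: recognized + unrecognized = all instantiated objects
  expect_equal(imp$report$n_recognized + imp$report$n_unrecognized, 6)
  expect_equal(nrow(imp$definition$reactions), 1)
})

test_that("gene expression objects map to genes and transcription edges", {
  txt <- c(
    "model Regulated",
    "  SysBio.Source src(phi = 1);",
    "  SysBio.Metabolite glc;",
    "  SysBio.Metabolite g6p;",
    "  SysBio.Enzyme hk;",
    "  SysBio.Reaction rx(r = 0, w = 1);",
    "  SysBio.mRNA hk_m(k_d = 0.02);",
    "  SysBio.Translation hk_t;",
    "  SysBio.TranscriptionalInhibition rep(Q_max = 5);",
    "equation",
    "  connect(src.O, glc.I);",
    "  connect(glc.O, rx.S);",
    "  connect(rx.P, g6p.I);",
    "  connect(hk.E, rx.E);",
    "  connect(hk_m.O, hk_t.I);",
    "  connect(hk_t.O, hk.I);",
    "  connect(g6p.O, rep.C);",
    "  connect(rep.O, hk_m.I);",
    "end Regulated;")
  imp <- import_modelica_subset(txt)
  expect_equal(nrow(imp$definition$genes), 1)
  expect_equal(imp$definition$genes$target, "hk")
  expect_equal(imp$definition$genes$k_d, 0.02)
  expect_equal(nrow(imp$definition$tf_edges), 1)
  expect_equal(imp$definition$tf_edges$sign, -1)
  expect_equal(imp$definition$tf_edges$regulator, "g6p")
  expect_equal(imp$definition$tf_edges$Q_max, 5)
  net <- build_network(imp$definition, quiet = TRUE)
  expect_lt(network_residual(net), 1e-10)
})

test_that("library class names are learned by their base-class keyword", {
  lib <- c("package SysBio", "model MetaboliteNode", "end MetaboliteNode;",
           "model EnzymeNode", "end EnzymeNode;", "end SysBio;")
  txt <- c("model M", "  SysBio.MetaboliteNode glc;", "  SysBio.EnzymeNode hk;",
           "end M;")
  imp <- import_modelica_subset(txt, lib)
  expect_equal(imp$report$n_recognized, 2)
  expect_setequal(imp$report$mapping$class, c("metabolite", "enzyme"))
})
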