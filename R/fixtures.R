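# Toy fixture networks with analytic oracles, and a seeded generator of
# random valid networks for property-style testing.

#' Toy fixture networks
#'
#' * `chain`: S -> A -> B -> P, three enzymatic steps, unit source on S.
#'   Under an influx fold u every steady-state concentration scales by u
#'   (first-order demand), matching the closed-form single-reaction relations
#'   step by step.
#' * `branch2`: one parent M split 0.7/0.3 into two enzymatic children.
#' * `feedback_loop`: S -> P whose enzyme's gene is repressed by P, with an
#'   alternative export route competing for S; product steady states under
#'   influx folds are sub-linear (the repressed enzyme loses flux share).
#' * `branch_sat`: a two-route split where child `c1` feeds a reaction that
#'   also draws a second substrate X supplied at a fixed capped rate; pushing
#'   the `c1` fraction (or the influx) past the X supply makes the
#'   intermediate P1 grow without bound — a low-tolerance branch.
#'
#' @param w bound/free enzyme ratio used for the enzymatic steps.
#' @param r reversibility used for the chain steps.
#' @return named list of `nss_network` objects with a `manifest` attribute
#'   per network (entity counts).
#' @export
make_toy_networks <- function(w = 1, r = 0) {
  chain_def <- model_definition(
    compartments = "liver",
    metabolites = data.frame(id = c("S", "A", "B", "P"), compartment = "liver"),
    enzymes = data.frame(id = c("E1", "E2", "E3"), compartment = "liver"),
    reactions = data.frame(id = c("r1", "r2", "r3"),
                           substrates = c("S", "A", "B"),
                           products = c("A", "B", "P"),
                           enzyme = c("E1", "E2", "E3"), r = r, w = w),
    sources = data.frame(target = "S", phi = 1))
  branch2_def <- model_definition(
    compartments = "liver",
    metabolites = data.frame(id = c("M", "P1", "P2"), compartment = "liver"),
    enzymes = data.frame(id = c("E1", "E2"), compartment = "liver"),
    reactions = data.frame(id = c("c1", "c2"), substrates = "M",
                           products = c("P1", "P2"),
                           enzyme = c("E1", "E2"), r = 0, w = w),
    branches = data.frame(parent = "M", child = c("c1", "c2"), f = c(0.7, 0.3)),
    sources = data.frame(target = "M", phi = 1))
  fb_def <- model_definition(
    compartments = "liver",
    metabolites = data.frame(id = c("S", "P"), compartment = "liver"),
    enzymes = data.frame(id = "E", compartment = "liver", gene = "e_g"),
    reactions = data.frame(id = "rx", substrates = "S", products = "P",
                           enzyme = "E", r = 0, w = w),
    branches = data.frame(parent = "S", child = c("rx", "sink"), f = c(0.5, 0.5)),
    sources = data.frame(target = "S", phi = 1),
    genes = data.frame(id = "e_g", target_type = "enzyme", target = "E"),
    tf_edges = data.frame(gene = "e_g", regulator = "P", sign = -1,
                          Q_max = 10, Q_hat = 10, hill = 2))
  sat_def <- model_definition(
    compartments = "liver",
    metabolites = data.frame(id = c("M", "P1", "P2", "X", "Q"), compartment = "liver"),
    enzymes = data.frame(id = "E3", compartment = "liver"),
    reactions = data.frame(id = c("c1", "c2", "d1"),
                           substrates = c("M", "M", "P1 + X"),
                           products = c("P1", "P2", "Q"),
                           enzyme = c(NA, NA, "E3"), r = 0, w = w),
    branches = data.frame(parent = "M", child = c("c1", "c2"), f = c(0.15, 0.85)),
    sources = data.frame(target = c("M", "X"), phi = c(1, 0.3)))
  nets <- list(chain = build_network(chain_def),
               branch2 = build_network(branch2_def),
               feedback_loop = build_network(fb_def),
               branch_sat = build_network(sat_def))
  manifests <- list(
    chain = list(n_reactions = 3, n_metabolites = 4, n_enzymes = 3,
                 n_regulatory_proteins = 0, n_states = 10),
    branch2 = list(n_reactions = 2, n_metabolites = 3, n_enzymes = 2,
                   n_regulatory_proteins = 0, n_states = 7),
    feedback_loop = list(n_reactions = 1, n_metabolites = 2, n_enzymes = 1,
                         n_regulatory_proteins = 0, n_states = 5),
    branch_sat = list(n_reactions = 3, n_metabolites = 5, n_enzymes = 1,
                      n_regulatory_proteins = 0, n_states = 7))
  for (nm in names(nets)) attr(nets[[nm]], "manifest") <- manifests[[nm]]
  nets
}

#' Generate a random valid network
#'
#' Draws a branching tree of reactions from a unit source: at each frontier
#' metabolite, 1-3 consuming children (enzymatic with probability 0.7,
#' carrier-free transport otherwise) with simplex-drawn flux fractions
#' (optionally including an export `sink` share), reversibilities
#' r ~ U\[0, 0.9], enzyme ratios w ~ U\[0.1, 10], and (with probability
#' `p_gene`) gene-expression control of an enzyme by a random upstream
#' metabolite. Every generated network is validated by construction: its
#' all-ones state is an exact fixed point.
#'
#' @param seed integer RNG seed (local to this call).
#' @param max_depth maximum pathway depth.
#' @param p_gene probability that an enzyme is expression-regulated.
#' @return an `nss_network`.
#' @export
random_network <- function(seed = 1, max_depth = 4, p_gene = 0.3) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)

  mets <- data.frame(id = "M1", compartment = "liver", stringsAsFactors = FALSE)
  enz <- rx <- br <- gn <- tf <- NULL
  frontier <- data.frame(id = "M1", depth = 0, stringsAsFactors = FALSE)
  n_m <- 1L; n_e <- 0L; n_r <- 0L; n_g <- 0L
  while (nrow(frontier)) {
    m <- frontier$id[1]; d <- frontier$depth[1]
    frontier <- frontier[-1, , drop = FALSE]
    if (d >= max_depth) next                      # terminal: auto-sink
    k <- sample(1:3, 1)
    add_sink <- stats::runif(1) < 0.3
    fr <- stats::rgamma(k + add_sink, shape = 1.5)
    fr <- fr / sum(fr)
    fr <- pmax(fr, 0.02); fr <- fr / sum(fr)      # keep fractions away from 0
    kids <- character(k)
    for (j in seq_len(k)) {
      n_m <- n_m + 1L; newm <- paste0("M", n_m)
      mets <- rbind(mets, data.frame(id = newm, compartment = "liver"))
      n_r <- n_r + 1L; rid <- paste0("R", n_r)
      enzymatic <- stats::runif(1) < 0.7
      eid <- NA_character_
      if (enzymatic) {
        n_e <- n_e + 1L; eid <- paste0("E", n_e)
        gene <- NA_character_
        if (stats::runif(1) < p_gene) {
          n_g <- n_g + 1L; gene <- paste0("G", n_g)
          gn <- rbind(gn, data.frame(id = gene, target_type = "enzyme",
                                     target = eid, k_d = 0.01, k_dp = 0.01))
          tf <- rbind(tf, data.frame(gene = gene,
                                     regulator = sample(mets$id[seq_len(n_m - 1L)], 1),
                                     sign = sample(c(-1, 1), 1),
                                     Q_max = stats::runif(1, 2, 10),
                                     Q_hat = 10, hill = 2))
        }
        enz <- rbind(enz, data.frame(id = eid, compartment = "liver",
                                     gene = gene, k_deg = 0.01))
      }
      rx <- rbind(rx, data.frame(id = rid, substrates = m, products = newm,
                                 enzyme = eid,
                                 r = stats::runif(1, 0, 0.9),
                                 w = stats::runif(1, 0.1, 10)))
      kids[j] <- rid
      if (stats::runif(1) < 0.6)
        frontier <- rbind(frontier, data.frame(id = newm, depth = d + 1))
    }
    if (k + add_sink > 1)
      br <- rbind(br, data.frame(parent = m,
                                 child = c(kids, if (add_sink) "sink"),
                                 f = fr))
  }
  def <- model_definition(
    compartments = "liver", metabolites = mets, enzymes = enz,
    reactions = rx, branches = br,
    sources = data.frame(target = "M1", phi = stats::runif(1, 0.5, 2)),
    genes = gn, tf_edges = tf)
  build_network(def, quiet = TRUE)
}

#' Rescale the time unit of a model definition
#'
#' Multiplies every rate parameter (source influxes — hence all derived rate
#' constants —, enzyme turnovers, mRNA/protein degradation rates, switch
#' factors) by a common positive factor. Steady states are invariant under
#' this rescaling; only transients compress.
#'
#' @param definition an `nss_definition`.
#' @param factor positive scale factor.
#' @return a rescaled `nss_definition`.
#' @export
rescale_time <- function(definition, factor) {
  if (factor <= 0) nss_error("rescaling factor must be > 0")
  def <- definition
  if (nrow(def$sources)) def$sources$phi <- def$sources$phi * factor
  if (nrow(def$enzymes)) def$enzymes$k_deg <- def$enzymes$k_deg * factor
  if (nrow(def$genes)) { def$genes$k_d <- def$genes$k_d * factor
                         def$genes$k_dp <- def$genes$k_dp * factor }
  if (nrow(def$switches)) { def$switches$k_a <- def$switches$k_a * factor
                            def$switches$k_d <- def$switches$k_d * factor }
  def
}
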