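COMPARTMENTS <- c("liver", "adipose", "blood", "pancreas", "peripheral", "macrophage")

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || (length(a) == 1L && is.na(a))) b else a

nss_error <- function(fmt, ..., class = "nss_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "nss_error")))
}

#' Create a network model definition
#'
#' A model definition is the declarative description of a multi-compartment
#' metabolic-regulatory network: metabolites, enzymes, reactions, branch-point
#' flux fractions, flux sources, gene-expression nodes, transcription-factor
#' edges and post-translational switches. Definitions are built either
#' programmatically with this constructor or parsed from the line-oriented
#' text format by [read_model_definition()]. [build_network()] turns a
#' definition into a simulatable network.
#'
#' @param compartments character vector of compartment names; must be a subset
#'   of `liver, adipose, blood, pancreas, peripheral, macrophage`.
#' @param metabolites data.frame with columns `id`, `compartment`.
#' @param enzymes data.frame with columns `id`, `compartment`, and optionally
#'   `gene` (id of the gene-expression node whose mRNA drives synthesis; NA
#'   for constitutive enzymes) and `k_deg` (degradation rate constant, per
#'   time unit; default 0.01).
#' @param reactions data.frame with columns `id`, `substrates`, `products`
#'   (species strings like `"fa + glyc3p"` or `"2*acoa"`), and optionally
#'   `enzyme` (NA for carrier-free transport steps), `r` (reversibility ratio
#'   in \[0,1)), `w` (bound/free enzyme ratio > 0).
#' @param branches long-format data.frame with columns `parent`, `child`, `f`.
#'   `child` is a reaction id that consumes `parent` as its first-listed
#'   substrate, or the reserved word `"sink"` for a first-order export route.
#'   Fractions at each parent must sum to 1.
#' @param sources data.frame with columns `target` (metabolite id), `phi`
#'   (normalized baseline influx > 0).
#' @param genes data.frame with columns `id`, `target_type` (`"enzyme"` or
#'   `"protein"`), `target` (enzyme id, or the protein state id created),
#'   and optionally `k_d` (mRNA degradation rate, default 0.01) and `k_dp`
#'   (protein degradation rate for protein targets, default 0.01).
#' @param tf_edges data.frame with columns `gene`, `regulator` (any state id),
#'   `sign` (+1 or -1), and optionally `Q_max` (> 1, default 10), `Q_hat`
#'   (regulator level of maximal effect for positive control, default 10),
#'   `hill` (default 2).
#' @param switches data.frame with columns `id` and optionally `activator`,
#'   `inhibitor` (comma-separated state ids driving activation/inactivation;
#'   NA means a constant drive), `k_a` (activation factor, default 0.02) and
#'   `k_d` (degradation rate, default 0.01). The inactivation factor
#'   `k_i = k_a - k_d` and the synthesis flux `2*k_d` are derived so that the
#'   declared baseline partition (both pools at 1) is an exact fixed point.
#' @return an object of class `nss_definition`.
#' @export
model_definition <- function(compartments,
                             metabolites,
                             reactions,
                             enzymes = NULL,
                             branches = NULL,
                             sources = NULL,
                             genes = NULL,
                             tf_edges = NULL,
                             switches = NULL) {
  chr <- NA_character_
  def <- structure(list(
    compartments = as.character(compartments),
    metabolites  = fill_defaults(metabolites, list(id = chr, compartment = chr)),
    enzymes      = fill_defaults(enzymes, list(id = chr, compartment = chr,
                                               gene = chr, k_deg = 0.01)),
    reactions    = fill_defaults(reactions, list(id = chr, substrates = chr,
                                                 products = chr, enzyme = chr,
                                                 r = 0, w = 1)),
    branches     = fill_defaults(branches, list(parent = chr, child = chr, f = NA_real_)),
    sources      = fill_defaults(sources, list(target = chr, phi = 1)),
    genes        = fill_defaults(genes, list(id = chr, target_type = chr, target = chr,
                                             k_d = 0.01, k_dp = 0.01)),
    tf_edges     = fill_defaults(tf_edges, list(gene = chr, regulator = chr, sign = 1,
                                                Q_max = 10, Q_hat = 10, hill = 2,
                                                basal = 0.05)),
    switches     = fill_defaults(switches, list(id = chr, activator = chr, inhibitor = chr,
                                                k_a = 0.02, k_d = 0.01)),
    provenance   = NULL
  ), class = "nss_definition")
  validate_definition(def)
  def
}

fill_defaults <- function(df, spec) {
  spec <- as.list(spec)
  cols <- names(spec)
  if (is.null(df) || nrow(as.data.frame(df, stringsAsFactors = FALSE)) == 0L) {
    out <- as.data.frame(lapply(spec, function(x) x[0]), stringsAsFactors = FALSE)
    names(out) <- cols
    return(out)
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (cl in cols) {
    if (!cl %in% names(df)) df[[cl]] <- spec[[cl]]
    miss <- is.na(df[[cl]])
    if (any(miss) && !is.na(spec[[cl]])) df[[cl]][miss] <- spec[[cl]]
    df[[cl]] <- if (is.numeric(spec[[cl]])) as.numeric(df[[cl]]) else as.character(df[[cl]])
  }
  df[, cols, drop = FALSE]
}

validate_definition <- function(def) {
  bad <- setdiff(def$compartments, COMPARTMENTS)
  if (length(bad))
    nss_error("unknown compartment(s): %s", paste(bad, collapse = ", "))
  bad <- setdiff(def$metabolites$compartment, def$compartments)
  if (length(bad))
    nss_error("metabolite compartment(s) not declared: %s", paste(bad, collapse = ", "))
  dup_in <- function(x, what) {
    d <- unique(x[duplicated(x)])
    if (length(d)) nss_error("duplicate %s id(s): %s", what, paste(d, collapse = ", "))
  }
  dup_in(def$metabolites$id, "metabolite")
  dup_in(def$enzymes$id, "enzyme")
  dup_in(def$reactions$id, "reaction")
  dup_in(def$genes$id, "gene")
  dup_in(def$switches$id, "switch")
  # global state-label uniqueness
  labels <- c(def$metabolites$id, def$enzymes$id, def$genes$id,
              def$genes$target[def$genes$target_type == "protein"],
              paste0(def$switches$id, "_a"), paste0(def$switches$id, "_i"))
  dup_in(labels, "state label")
  if (nrow(def$reactions)) {
    if (any(def$reactions$r < 0 | def$reactions$r >= 1))
      nss_error("reversibility r must lie in [0, 1)")
    if (any(def$reactions$w <= 0))
      nss_error("bound/free enzyme ratio w must be > 0")
  }
  if (nrow(def$sources) && any(def$sources$phi <= 0))
    nss_error("source influx phi must be > 0")
  if (nrow(def$tf_edges) && any(!def$tf_edges$sign %in% c(-1, 1)))
    nss_error("tf edge sign must be +1 or -1")
  if (nrow(def$tf_edges) && any(def$tf_edges$Q_max <= 1))
    nss_error("Q_max must exceed 1 (no dynamic range otherwise)")
  if (nrow(def$switches) && any(def$switches$k_a < def$switches$k_d))
    nss_error("switch activation factor k_a must be >= its degradation rate k_d")
  invisible(def)
}

# parse "2*fa + glyc3p" into data.frame(id, nu)
parse_species <- function(txt) {
  txt <- trimws(txt)
  if (!nzchar(txt)) nss_error("empty species list")
  parts <- trimws(strsplit(txt, "+", fixed = TRUE)[[1]])
  nu <- rep(1, length(parts))
  id <- parts
  hasmult <- grepl("*", parts, fixed = TRUE)
  if (any(hasmult)) {
    sp <- strsplit(parts[hasmult], "*", fixed = TRUE)
    nu[hasmult] <- suppressWarnings(
      vapply(sp, function(x) as.numeric(trimws(x[1])), numeric(1)))
    id[hasmult] <- vapply(sp, function(x) trimws(x[2]), character(1))
  }
  if (anyNA(nu) || any(nu <= 0)) nss_error("malformed stoichiometric multiplier in '%s'", txt)
  data.frame(id = id, nu = nu, stringsAsFactors = FALSE)
}

format_species <- function(df) {
  paste(ifelse(df$nu == 1, df$id, paste0(df$nu, "*", df$id)), collapse = " + ")
}

#' @export
print.nss_definition <- function(x, ...) {
  cat("<nss_definition>\n")
  cat(sprintf("  compartments: %s\n", paste(x$compartments, collapse = ", ")))
  cat(sprintf("  %d metabolites, %d enzymes, %d reactions, %d branch rows\n",
              nrow(x$metabolites), nrow(x$enzymes), nrow(x$reactions), nrow(x$branches)))
  cat(sprintf("  %d sources, %d genes, %d tf edges, %d switches\n",
              nrow(x$sources), nrow(x$genes), nrow(x$tf_edges), nrow(x$switches)))
  invisible(x)
}
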