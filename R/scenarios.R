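# Validation scenarios: named perturbation protocols with
# direction-of-change expectations, and the reduced liver-adipose-blood
# fixture network they run on.

#' Load the reduced liver-adipose-blood fixture network
#'
#' A ~27-metabolite, 3-switch rendition of a whole-body hepatic-metabolism
#' network: glucose influx, glycolysis, glycogen turnover, gluconeogenesis
#' (PEPCK), de novo lipogenesis (ACC1, FAS, SCD1, GPAT), beta-oxidation
#' (CPT1), ketogenesis, cholesterol synthesis and lipoprotein cycling
#' (VLDL/LDL/HDL), adipose storage/lipolysis, and regulation by
#' insulin, glucagon, PPARalpha, SREBP-1c, adiponectin and TNFalpha.
#' Shipped as a plain-text definition in `inst/extdata/mini_steatonet.nss`.
#'
#' @return an `nss_network`.
#' @export
make_mini_steatonet <- function() {
  path <- system.file("extdata", "mini_steatonet.nss", package = "nssnet")
  if (!nzchar(path)) nss_error("mini_steatonet.nss fixture not found")
  build_network(read_model_definition(path))
}

#' Hand-counted manifest of the mini fixture
#'
#' Entity counts enumerated independently from the definition file; used to
#' cross-check [structure_stats()].
#' @return named list of counts.
#' @export
mini_steatonet_manifest <- function() {
  list(n_reactions = 40, n_metabolites = 27, n_enzymes = 28,
       n_genes = 17, n_regulatory_proteins = 6, n_branch_rows = 35,
       n_sources = 4, n_states = 110)
}

#' Define a simulation scenario
#'
#' @param name scenario name.
#' @param phases list of phases, each a list with `perturbation` (an
#'   `nss_perturbation`; multipliers are absolute with respect to baseline
#'   and apply for the whole phase) and optionally `t_end`.
#' @param control_phases optional matched control protocol (same structure as
#'   `phases`); expectations with `relative_to = "control"` compare each
#'   phase's steady state against the corresponding control phase (e.g. a
#'   knockout against the diet-matched wild type).
#' @param expectations data.frame with columns `variable`, `direction`
#'   (`up`, `down`, `unchanged`), and optionally `phase` (default: last) and
#'   `relative_to` (`baseline` or `previous`, default baseline).
#' @return an `nss_scenario`.
#' @export
scenario <- function(name, phases, expectations, control_phases = NULL) {
  expectations <- fill_defaults(expectations,
                                list(variable = NA_character_, direction = NA_character_,
                                     phase = as.numeric(length(phases)),
                                     relative_to = "baseline"))
  for (ph in phases)
    if (!is.null(ph$t_end) && ph$t_end <= 0) nss_error("phase durations must be > 0")
  structure(list(name = name, phases = phases, expectations = expectations,
                 control_phases = control_phases),
            class = "nss_scenario")
}

#' @export
print.nss_scenario <- function(x, ...) {
  cat(sprintf("<nss_scenario> %s: %d phase(s), %d expectation rows\n",
              x$name, length(x$phases), nrow(x$expectations)))
  invisible(x)
}

#' Published validation scenarios
#'
#' The four qualitative validation conditions with their expected
#' direction-of-change rows, encoded machine-readably:
#' * `scenario_fasting()` — glucose influx reduced 10-fold.
#' * `scenario_scd_knockout()` — SCD1 degradation increased 1000-fold, on a
#'   lipogenic diet (glucose x10) then a high-fat diet (triglycerides x5,
#'   cholesterol x4, glucose /2.5).
#' * `scenario_adiponectin()` — adiponectin degradation reduced 10-fold
#'   under fasting.
#' * `scenario_ppara_agonist()` — high-fat diet from t = 0, then constant
#'   activation of the PPARalpha switch.
#'
#' Expectation rows involving variables absent from the fixture (e.g. urea
#' cycle enzymes in fasting) are retained and reported as uncovered.
#' @return an `nss_scenario`.
#' @name validation_scenarios
NULL

exp_rows <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(variable = r[[1]], direction = r[[2]],
               phase = if (length(r) > 2) as.integer(r[[3]]) else NA_integer_,
               relative_to = if (length(r) > 3) r[[4]] else "baseline",
               stringsAsFactors = FALSE)))
}

#' @rdname validation_scenarios
#' @export
scenario_fasting <- function() {
  scenario("fasting",
    phases = list(list(perturbation = perturbation("glc_B", "influx_fold", 0.1))),
    expectations = exp_rows(
      list("ins_a", "down", 1), list("glc_B", "down", 1),
      list("glycogen_L", "down", 1), list("ACC1", "down", 1),
      list("FAS", "down", 1), list("SREBP1c", "down", 1),
      list("gcg_a", "up", 1), list("fa_B", "up", 1),
      list("PEPCK", "up", 1), list("CPT1", "up", 1),
      list("urea_cycle_enzymes", "up", 1)))
}

#' @rdname validation_scenarios
#' @export
scenario_scd_knockout <- function() {
  ko <- perturbation("SCD1", "knockout")
  lipogenic <- perturbations(ko, perturbation("glc_B", "influx_fold", 10))
  highfat <- perturbations(ko,
                           perturbation("tg_B", "influx_fold", 5),
                           perturbation("chol_L", "influx_fold", 4),
                           perturbation("glc_B", "influx_fold", 1 / 2.5))
  scenario("scd_knockout",
    phases = list(list(perturbation = lipogenic), list(perturbation = highfat)),
    control_phases = list(
      list(perturbation = perturbation("glc_B", "influx_fold", 10)),
      list(perturbation = perturbations(
        perturbation("tg_B", "influx_fold", 5),
        perturbation("chol_L", "influx_fold", 4),
        perturbation("glc_B", "influx_fold", 1 / 2.5)))),
    expectations = exp_rows(
      list("tg_L", "down", 1), list("CPT1", "up", 1),
      list("kb_B", "up", 1),
      list("GPAT", "up", 1), list("SREBP1c", "up", 1),
      list("tg_L", "down", 2, "control"), list("CPT1", "up", 2, "control"),
      list("kb_B", "up", 2),
      list("GPAT", "down", 2, "previous"),
      list("SREBP1c", "down", 2, "previous")))
}

#' @rdname validation_scenarios
#' @export
scenario_adiponectin <- function() {
  scenario("adiponectin_overexpression",
    phases = list(list(perturbation = perturbations(
      perturbation("adipo", "degradation_fold", 0.1),
      perturbation("glc_B", "influx_fold", 0.1)))),
    expectations = exp_rows(
      list("fa_B", "down", 1), list("tg_L", "down", 1),
      list("TNFA", "down", 1), list("ceramide_L", "down", 1),
      list("SREBP1c", "down", 1), list("GPAT", "down", 1),
      list("SCD1", "down", 1), list("CPT1A", "up", 1),
      list("kb_B", "unchanged", 1)))
}

#' @rdname validation_scenarios
#' @export
scenario_ppara_agonist <- function() {
  highfat <- perturbations(perturbation("tg_B", "influx_fold", 5),
                           perturbation("chol_L", "influx_fold", 4),
                           perturbation("glc_B", "influx_fold", 1 / 2.5))
  agonist <- perturbations(highfat, perturbation("ppara_a", "constant_activation", 2))
  scenario("ppara_agonist",
    phases = list(list(perturbation = highfat), list(perturbation = agonist)),
    expectations = exp_rows(
      list("tg_L", "up", 1), list("fa_B", "up", 1),
      list("vldl_B", "up", 1), list("chol_L", "up", 1), list("ldl_B", "up", 1),
      list("tg_L", "down", 2, "previous"), list("CPT1", "up", 2, "previous"),
      list("fa_B", "down", 2, "previous"), list("vldl_B", "down", 2, "previous"),
      list("chol_L", "down", 2, "previous"), list("ldl_B", "down", 2, "previous"),
      list("hdl_B", "unchanged", 2, "previous")))
}

#' All four validation scenarios
#' @return named list of `nss_scenario` objects.
#' @export
validation_scenarios <- function() {
  list(fasting = scenario_fasting(),
       scd_knockout = scenario_scd_knockout(),
       adiponectin = scenario_adiponectin(),
       ppara_agonist = scenario_ppara_agonist())
}

#' Run a scenario on a network
#'
#' Phases run sequentially, each starting from the previous phase's end
#' state; each phase's perturbation multipliers are absolute with respect to
#' baseline and active for the whole phase. Fold changes are reported both
#' against the initial baseline (all states 1) and against the previous
#' phase's steady state. Non-convergence in a phase is flagged in the
#' report, not raised.
#'
#' @param network an `nss_network`.
#' @param spec an `nss_scenario`.
#' @param margin direction margin: a fold outside `[1-margin, 1+margin]`
#'   counts as changed.
#' @param t_end default integration horizon per phase.
#' @param ... passed to [steady_state()].
#' @return an `nss_scenario_report`: per-phase steady states, the verdict
#'   table, uncovered rows, and an overall pass flag.
#' @export
run_scenario <- function(network, spec, margin = 0.05, t_end = 1e6, ...) {
  stopifnot(inherits(spec, "nss_scenario"))
  init <- NULL
  phases <- list()
  folds_base <- list(); folds_prev <- list()
  prev_state <- initialize_state(network)
  for (k in seq_along(spec$phases)) {
    ph <- spec$phases[[k]]
    ss <- steady_state(network, ph$perturbation,
                       t_end = ph$t_end %||% t_end, init = init, ...)
    phases[[k]] <- ss
    folds_base[[k]] <- ss$fold_changes
    folds_prev[[k]] <- ss$state / prev_state
    prev_state <- ss$state
    init <- ss$state
  }
  folds_ctrl <- NULL
  if (!is.null(spec$control_phases) &&
      any(spec$expectations$relative_to == "control")) {
    cinit <- NULL; folds_ctrl <- list()
    for (k in seq_along(spec$control_phases)) {
      cph <- spec$control_phases[[k]]
      css <- steady_state(network, cph$perturbation,
                          t_end = cph$t_end %||% t_end, init = cinit, ...)
      folds_ctrl[[k]] <- phases[[min(k, length(phases))]]$state / css$state
      cinit <- css$state
    }
  }
  verdicts <- check_directions(list(base = folds_base, prev = folds_prev,
                                    ctrl = folds_ctrl),
                               spec$expectations, margin = margin)
  converged <- all(vapply(phases, function(s) s$converged, logical(1)))
  covered <- verdicts[verdicts$verdict != "uncovered", , drop = FALSE]
  structure(list(scenario = spec$name, phases = phases, verdicts = verdicts,
                 uncovered = verdicts$variable[verdicts$verdict == "uncovered"],
                 n_covered = nrow(covered),
                 pass = converged && all(covered$pass),
                 converged = converged, margin = margin),
            class = "nss_scenario_report")
}

#' Check direction expectations against computed fold changes
#'
#' @param folds either the list produced inside [run_scenario()] (components
#'   `base` and `prev`, each a list of per-phase fold vectors) or a single
#'   named fold vector (then `phase`/`relative_to` are ignored).
#' @param expectations expectation data.frame (see [scenario()]).
#' @param margin direction margin in (0, 0.5).
#' @return data.frame: variable, direction, phase, relative_to, fold,
#'   verdict, pass.
#' @export
check_directions <- function(folds, expectations, margin = 0.05) {
  if (margin <= 0 || margin >= 0.5) nss_error("margin must lie in (0, 0.5)")
  exps <- fill_defaults(expectations, list(variable = NA_character_,
                                           direction = NA_character_,
                                           phase = 1, relative_to = "baseline"))
  single <- is.numeric(folds)
  out <- exps
  out$fold <- NA_real_; out$verdict <- "uncovered"; out$pass <- NA
  for (i in seq_len(nrow(exps))) {
    v <- exps$variable[i]
    fv <- if (single) folds else {
      set <- switch(exps$relative_to[i], previous = folds$prev,
                    control = folds$ctrl, folds$base)
      if (is.null(set)) next
      set[[min(exps$phase[i], length(set))]]
    }
    if (!v %in% names(fv)) next
    fold <- unname(fv[v])
    out$fold[i] <- fold
    verdict <- if (fold > 1 + margin) "up" else if (fold < 1 - margin) "down" else "unchanged"
    out$verdict[i] <- verdict
    out$pass[i] <- verdict == exps$direction[i]
  }
  out
}

#' @export
print.nss_scenario_report <- function(x, ...) {
  cat(sprintf("<nss_scenario_report> %s: %s (%d/%d covered rows pass%s)\n",
              x$scenario, if (x$pass) "PASS" else "FAIL",
              sum(x$verdicts$pass, na.rm = TRUE), x$n_covered,
              if (length(x$uncovered))
                sprintf("; uncovered: %s", paste(x$uncovered, collapse = ", "))
              else ""))
  v <- x$verdicts
  for (i in seq_len(nrow(v)))
    cat(sprintf("  %-18s phase %s vs %-8s expect %-9s fold %-8s %s\n",
                v$variable[i], v$phase[i], v$relative_to[i], v$direction[i],
                ifelse(is.na(v$fold[i]), "-", sprintf("%.3g", v$fold[i])),
                ifelse(is.na(v$pass[i]), "UNCOVERED", ifelse(v$pass[i], "ok", "MISMATCH"))))
  invisible(x)
}
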