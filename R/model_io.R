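#' Read a model definition from the line-oriented text format
#'
#' The format is UTF-8, line-oriented, with `#` comments and `@section`
#' headers. Sections: `@compartments`, `@metabolites`, `@enzymes`,
#' `@reactions`, `@branches`, `@sources`, `@genes`, `@tf`, `@switches`.
#' See the packaged grammar in `inst/extdata/model-format.md` and the
#' shipped `mini_steatonet.nss` fixture for a complete example.
#'
#' @param text character: either a path to a file or a character vector of
#'   lines (a single string with newlines is split).
#' @return an `nss_definition` with per-entity source-line provenance.
#' @export
read_model_definition <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    text <- readLines(text, encoding = "UTF-8", warn = FALSE)
  if (length(text) == 1L) text <- strsplit(text, "\n", fixed = TRUE)[[1]]

  raw <- sub("#.*$", "", text)
  raw <- trimws(raw)
  keep <- nzchar(raw)
  lines <- raw[keep]
  lineno <- which(keep)

  section <- NA_character_
  acc <- list(compartments = character(), metabolites = list(), enzymes = list(),
              reactions = list(), branches = list(), sources = list(),
              genes = list(), tf = list(), switches = list())
  prov <- list()

  parse_kv <- function(tokens) {
    kv <- tokens[grepl("=", tokens, fixed = TRUE)]
    out <- list()
    for (t in kv) {
      p <- strsplit(t, "=", fixed = TRUE)[[1]]
      out[[trimws(p[1])]] <- trimws(paste(p[-1], collapse = "="))
    }
    out
  }
  num_or <- function(x, default) if (is.null(x)) default else as.numeric(x)

  for (i in seq_along(lines)) {
    ln <- lines[i]; n <- lineno[i]
    if (startsWith(ln, "@")) {
      section <- sub("^@", "", strsplit(ln, "[[:space:]]+")[[1]][1])
      next
    }
    if (is.na(section))
      nss_error("line %d: content before any @section header", n)
    tok <- strsplit(ln, "[[:space:]]+")[[1]]
    switch(section,
      compartments = {
        acc$compartments <- c(acc$compartments, tok)
      },
      metabolites = {
        acc$metabolites[[length(acc$metabolites) + 1L]] <-
          list(id = tok[1], compartment = tok[2], line = n)
      },
      enzymes = {
        kv <- parse_kv(tok[-(1:2)])
        acc$enzymes[[length(acc$enzymes) + 1L]] <-
          list(id = tok[1], compartment = tok[2],
               gene = kv$gene %||% NA_character_,
               k_deg = num_or(kv$kdeg, 0.01), line = n)
      },
      reactions = {
        # id: subs -> prods | enzyme=E r=0.5 w=1
        m <- regmatches(ln, regexec("^([^:]+):([^|]+)(\\|(.*))?$", ln))[[1]]
        if (length(m) < 3) nss_error("line %d: malformed reaction '%s'", n, ln)
        id <- trimws(m[2])
        eq <- strsplit(m[3], "->", fixed = TRUE)[[1]]
        if (length(eq) != 2) nss_error("line %d: reaction needs 'subs -> prods'", n)
        kv <- parse_kv(strsplit(trimws(m[5] %||% ""), "[[:space:]]+")[[1]])
        acc$reactions[[length(acc$reactions) + 1L]] <-
          list(id = id, substrates = trimws(eq[1]), products = trimws(eq[2]),
               enzyme = kv$enzyme %||% NA_character_,
               r = num_or(kv$r, 0), w = num_or(kv$w, 1), line = n)
      },
      branches = {
        # parent: child=f child=f ...
        m <- strsplit(ln, ":", fixed = TRUE)[[1]]
        if (length(m) != 2) nss_error("line %d: malformed branch '%s'", n, ln)
        parent <- trimws(m[1])
        kv <- parse_kv(strsplit(trimws(m[2]), "[[:space:]]+")[[1]])
        if (!length(kv)) nss_error("line %d: branch lists no children", n)
        fs <- suppressWarnings(as.numeric(unlist(kv)))
        if (anyNA(fs)) nss_error("line %d: malformed fraction", n)
        for (j in seq_along(kv))
          acc$branches[[length(acc$branches) + 1L]] <-
            list(parent = parent, child = names(kv)[j], f = fs[j], line = n)
      },
      sources = {
        phi <- if (length(tok) > 1) as.numeric(tok[2]) else 1
        if (is.na(phi)) nss_error("line %d: malformed source influx", n)
        acc$sources[[length(acc$sources) + 1L]] <-
          list(target = tok[1], phi = phi, line = n)
      },
      genes = {
        kv <- parse_kv(tok[-1])
        tt <- if (!is.null(kv$enzyme)) "enzyme" else if (!is.null(kv$protein)) "protein" else
          nss_error("line %d: gene needs enzyme= or protein= target", n)
        acc$genes[[length(acc$genes) + 1L]] <-
          list(id = tok[1], target_type = tt,
               target = kv$enzyme %||% kv$protein,
               k_d = num_or(kv$kd, 0.01), k_dp = num_or(kv$kdp, 0.01), line = n)
      },
      tf = {
        # regulator -> gene + key=val | regulator -> gene -
        m <- strsplit(ln, "->", fixed = TRUE)[[1]]
        if (length(m) != 2) nss_error("line %d: malformed tf edge '%s'", n, ln)
        rest <- strsplit(trimws(m[2]), "[[:space:]]+")[[1]]
        sgn <- if (length(rest) >= 2 && rest[2] %in% c("+", "-")) ifelse(rest[2] == "+", 1, -1) else 1
        kv <- parse_kv(rest)
        acc$tf[[length(acc$tf) + 1L]] <-
          list(gene = rest[1], regulator = trimws(m[1]), sign = sgn,
               Q_max = num_or(kv$Qmax, 10), Q_hat = num_or(kv$Qhat, 10),
               hill = num_or(kv$hill, 2), basal = num_or(kv$basal, 0.05), line = n)
      },
      switches = {
        m <- strsplit(ln, ":", fixed = TRUE)[[1]]
        kv <- parse_kv(strsplit(trimws(m[2] %||% ""), "[[:space:]]+")[[1]])
        acc$switches[[length(acc$switches) + 1L]] <-
          list(id = trimws(m[1]),
               activator = kv$act %||% NA_character_,
               inhibitor = kv$inh %||% NA_character_,
               k_a = num_or(kv$ka, 0.02), k_d = num_or(kv$kd, 0.01), line = n)
      },
      nss_error("line %d: unknown section '@%s'", n, section)
    )
  }

  bind <- function(lst) {
    if (!length(lst)) return(NULL)
    do.call(rbind, lapply(lst, function(x) as.data.frame(x, stringsAsFactors = FALSE)))
  }
  met <- bind(acc$metabolites)
  if (!is.null(met)) {
    d <- met$id[duplicated(met$id)]
    if (length(d)) {
      both <- met$line[met$id %in% d]
      nss_error("duplicate metabolite id '%s' (lines %s)", d[1], paste(both, collapse = ", "))
    }
  }
  strip <- function(df) { if (!is.null(df)) df$line <- NULL; df }
  def <- model_definition(
    compartments = unique(acc$compartments),
    metabolites = strip(met),
    enzymes = strip(bind(acc$enzymes)),
    reactions = strip(bind(acc$reactions)),
    branches = strip(bind(acc$branches)),
    sources = strip(bind(acc$sources)),
    genes = strip(bind(acc$genes)),
    tf_edges = strip(bind(acc$tf)),
    switches = strip(bind(acc$switches))
  )
  def$provenance <- list(metabolites = met$line %||% integer(),
                         n_lines = length(text))
  def
}

#' Write a model definition in the text format
#'
#' Round-trip stable: `read_model_definition(write_model_definition(def))`
#' yields an identical definition.
#'
#' @param def an `nss_definition`.
#' @param path optional output file; when NULL the lines are returned.
#' @return character vector of lines, invisibly when `path` is given.
#' @export
write_model_definition <- function(def, path = NULL) {
  num <- function(x) trimws(formatC(x, format = "g", digits = 15))
  out <- c("# nssnet model definition v1",
           "@compartments", paste(def$compartments, collapse = " "))
  out <- c(out, "", "@metabolites",
           sprintf("%s %s", def$metabolites$id, def$metabolites$compartment))
  if (nrow(def$enzymes)) {
    ln <- sprintf("%s %s", def$enzymes$id, def$enzymes$compartment)
    has_g <- !is.na(def$enzymes$gene)
    ln[has_g] <- paste0(ln[has_g], " gene=", def$enzymes$gene[has_g])
    ln <- paste0(ln, " kdeg=", num(def$enzymes$k_deg))
    out <- c(out, "", "@enzymes", ln)
  }
  if (nrow(def$reactions)) {
    rx <- def$reactions
    opts <- paste0(ifelse(is.na(rx$enzyme), "", paste0("enzyme=", rx$enzyme, " ")),
                   "r=", num(rx$r), " w=", num(rx$w))
    out <- c(out, "", "@reactions",
             sprintf("%s: %s -> %s | %s", rx$id, rx$substrates, rx$products, opts))
  }
  if (nrow(def$branches)) {
    sp <- split(def$branches, factor(def$branches$parent,
                                     levels = unique(def$branches$parent)))
    out <- c(out, "", "@branches",
             vapply(sp, function(b) sprintf("%s: %s", b$parent[1],
                      paste0(b$child, "=", num(b$f), collapse = " ")), character(1)))
  }
  if (nrow(def$sources))
    out <- c(out, "", "@sources",
             sprintf("%s %s", def$sources$target, num(def$sources$phi)))
  if (nrow(def$genes)) {
    g <- def$genes
    out <- c(out, "", "@genes",
             sprintf("%s %s=%s kd=%s kdp=%s", g$id, g$target_type, g$target,
                     num(g$k_d), num(g$k_dp)))
  }
  if (nrow(def$tf_edges)) {
    e <- def$tf_edges
    out <- c(out, "", "@tf",
             sprintf("%s -> %s %s Qmax=%s Qhat=%s hill=%s basal=%s", e$regulator, e$gene,
                     ifelse(e$sign > 0, "+", "-"), num(e$Q_max), num(e$Q_hat),
                     num(e$hill), num(e$basal)))
  }
  if (nrow(def$switches)) {
    s <- def$switches
    ln <- sprintf("%s:", s$id)
    ln <- paste0(ln, ifelse(is.na(s$activator), "", paste0(" act=", s$activator)))
    ln <- paste0(ln, ifelse(is.na(s$inhibitor), "", paste0(" inh=", s$inhibitor)))
    ln <- paste0(ln, " ka=", num(s$k_a), " kd=", num(s$k_d))
    out <- c(out, "", "@switches", ln)
  }
  if (!is.null(path)) {
    writeLines(out, path, useBytes = TRUE)
    return(invisible(out))
  }
  out
}

#' Write result tables as tidy TSV files
#'
#' @param tables a named list of data.frames (or a single data.frame, in
#'   which case `path` is the file name).
#' @param path output directory (or file for a single data.frame).
#' @return invisibly, the paths written.
#' @export
write_results <- function(tables, path) {
  write_one <- function(df, file) {
    num <- vapply(df, is.double, logical(1))
    df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
    utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
    file
  }
  if (is.data.frame(tables)) return(invisible(write_one(tables, path)))
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  files <- vapply(names(tables), function(nm)
    write_one(tables[[nm]], file.path(path, paste0(nm, ".tsv"))), character(1))
  invisible(files)
}

#' Export a trajectory as a tidy table
#'
#' @param traj an `nss_trajectory` from [integrate_network()].
#' @return data.frame with columns time, variable, value.
#' @export
trajectory_table <- function(traj) {
  st <- traj$states
  data.frame(time = rep(traj$times, ncol(st)),
             variable = rep(colnames(st), each = nrow(st)),
             value = as.vector(st), stringsAsFactors = FALSE)
}

#' Summarize steady-state fold changes as a table
#'
#' @param ss an `nss_steady_state`.
#' @return data.frame with columns variable, baseline, new, fold, direction.
#' @export
fold_change_table <- function(ss) {
  fc <- ss$fold_changes
  dirn <- ifelse(fc > 1, "up", ifelse(fc < 1, "down", "unchanged"))
  data.frame(variable = names(fc), baseline = ss$baseline, new = ss$state,
             fold = unname(fc), direction = unname(dirn), stringsAsFactors = FALSE)
}
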