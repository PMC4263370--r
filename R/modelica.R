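# Restricted importer for Modelica models built from a systems-biology
# object library. Only component declarations (with parameter modifiers) of
# the library's class vocabulary and connect statements are interpreted;
# anything else is reported, never executed.

MODELICA_CLASSES <- c(
  source = "source", metabolite = "metabolite", enzyme = "enzyme",
  regulatoryprotein = "regulatory_protein", protein = "regulatory_protein",
  mrna = "mrna", translation = "translation", reaction = "reaction",
  activation = "activation", inhibition = "inhibition",
  transcriptionalactivation = "transcriptional_activation",
  transcriptionalinhibition = "transcriptional_inhibition")

strip_modelica_comments <- function(text) {
  text <- gsub("/\\*.*?\\*/", " ", paste(text, collapse = "\n"))
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  sub("//.*$", "", lines)
}

parse_modifiers <- function(txt) {
  if (is.na(txt) || !nzchar(trimws(txt))) return(list())
  parts <- strsplit(txt, ",")[[1]]
  out <- list()
  for (p in parts) {
    kv <- strsplit(p, "=", fixed = TRUE)[[1]]
    if (length(kv) == 2) {
      val <- suppressWarnings(as.numeric(trimws(kv[2])))
      out[[trimws(kv[1])]] <- val
    }
  }
  out
}

#' Import a restricted Modelica model into a model definition
#'
#' Parses component declarations (`ClassName instName(mod = value, ...);`)
#' whose classes belong to the systems-biology object vocabulary
#' (metabolite, enzyme, regulatory protein, mRNA, translation, reaction,
#' source, post-translational activation/inhibition, transcriptional
#' activation/inhibition), plus `connect(a.port, b.port)` statements whose
#' ports follow the library conventions (S substrate, P product, E enzyme,
#' C transcriptional-regulator, A active, I inactive/input, O output).
#' Everything outside this subset is listed in the import report with its
#' line number; nothing is dropped silently.
#'
#' @param model_text Modelica model source (path, single string or lines).
#' @param library_text optional library source; only used to learn extra
#'   class names (classes defined in the library map by their base class
#'   keyword in their name).
#' @return list with `definition` (an `nss_definition`) and `report`
#'   (an `nss_import_report`).
#' @export
import_modelica_subset <- function(model_text, library_text = NULL) {
  read_lines <- function(x) {
    if (length(x) == 1L && !grepl("\n", x) && file.exists(x))
      return(readLines(x, warn = FALSE))
    if (length(x) == 1L) strsplit(x, "\n", fixed = TRUE)[[1]] else x
  }
  lines <- strip_modelica_comments(read_lines(model_text))
  classmap <- MODELICA_CLASSES
  if (!is.null(library_text)) {
    lib <- strip_modelica_comments(read_lines(library_text))
    defs <- regmatches(lib, regexec("^\\s*(?:model|class|block)\\s+([A-Za-z_][A-Za-z0-9_]*)", lib))
    for (d in defs) {
      if (length(d) < 2) next
      key <- tolower(d[2])
      hit <- names(classmap)[vapply(names(classmap), function(k) grepl(k, key, fixed = TRUE),
                                    logical(1))]
      hit <- hit[order(-nchar(hit))]
      if (length(hit)) classmap[key] <- classmap[[hit[1]]]
    }
  }

  # join statements split over lines, keep line provenance of first line
  stmts <- list(); cur <- ""; cur_line <- NA_integer_
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    # section headers carry no semicolon; never glue them onto the next
    # declaration
    if (!nzchar(cur) && !grepl(";", ln, fixed = TRUE) &&
        grepl("^(model|class|block|package|equation|algorithm|protected|public|within)\\b", ln))
      next
    if (!nzchar(cur)) cur_line <- i
    cur <- paste(cur, ln)
    while (grepl(";", cur, fixed = TRUE)) {
      sp <- regmatches(cur, regexpr("^[^;]*;", cur))
      stmts[[length(stmts) + 1L]] <- list(text = trimws(sub(";$", "", sp)), line = cur_line)
      cur <- sub("^[^;]*;", "", cur)
      cur_line <- i
    }
  }

  comp <- list(); conn <- list(); unrec <- list()
  skip_re <- "^(model|end|annotation|equation|extends|within|package|parameter|Real|input|output)\\b"
  comp_re <- "^([A-Za-z_][A-Za-z0-9_.]*)\\s+([A-Za-z_][A-Za-z0-9_]*)\\s*(\\((.*)\\))?$"
  conn_re <- "^connect\\s*\\(\\s*([A-Za-z_][A-Za-z0-9_]*)\\.([A-Za-z_][A-Za-z0-9_]*)\\s*,\\s*([A-Za-z_][A-Za-z0-9_]*)\\.([A-Za-z_][A-Za-z0-9_]*)\\s*\\)$"
  for (st in stmts) {
    tx <- st$text
    if (grepl("^connect", tx)) {
      m <- regmatches(tx, regexec(conn_re, tx))[[1]]
      if (length(m)) {
        conn[[length(conn) + 1L]] <- list(a = m[2], ap = toupper(m[3]),
                                          b = m[4], bp = toupper(m[5]), line = st$line)
      } else unrec[[length(unrec) + 1L]] <- st
      next
    }
    if (grepl(skip_re, tx)) next
    m <- regmatches(tx, regexec(comp_re, tx))[[1]]
    if (length(m)) {
      cls <- tolower(sub(".*\\.", "", m[2]))
      hit <- names(classmap)[vapply(names(classmap), function(k) grepl(k, cls, fixed = TRUE),
                                    logical(1))]
      hit <- hit[order(-nchar(hit))]
      if (length(hit)) {
        comp[[length(comp) + 1L]] <- list(class = classmap[[hit[1]]], name = m[3],
                                          mods = parse_modifiers(m[5]), line = st$line)
        next
      }
    }
    unrec[[length(unrec) + 1L]] <- st
  }

  cls_of <- stats::setNames(vapply(comp, `[[`, character(1), "class"),
                            vapply(comp, `[[`, character(1), "name"))
  mods_of <- stats::setNames(lapply(comp, `[[`, "mods"), names(cls_of))
  ends_at <- function(inst, port, want) {
    hits <- character(0)
    for (cn in conn) {
      if (cn$a == inst && cn$ap == port && cls_of[cn$b] %in% want) hits <- c(hits, cn$b)
      if (cn$b == inst && cn$bp == port && cls_of[cn$a] %in% want) hits <- c(hits, cn$a)
    }
    unique(hits)
  }
  num_mod <- function(inst, keys, default) {
    for (k in keys) if (!is.null(mods_of[[inst]][[k]])) return(mods_of[[inst]][[k]])
    default
  }

  mets <- names(cls_of)[cls_of == "metabolite"]
  enzs <- names(cls_of)[cls_of == "enzyme"]
  rxns <- names(cls_of)[cls_of == "reaction"]
  srcs <- names(cls_of)[cls_of == "source"]
  mrnas <- names(cls_of)[cls_of == "mrna"]
  transl <- names(cls_of)[cls_of == "translation"]
  prots <- names(cls_of)[cls_of == "regulatory_protein"]

  rx_rows <- lapply(rxns, function(rx) {
    subs <- ends_at(rx, "S", "metabolite")
    prods <- ends_at(rx, "P", "metabolite")
    enz <- ends_at(rx, "E", "enzyme")
    if (!length(subs) || !length(prods)) return(NULL)
    data.frame(id = rx, substrates = paste(subs, collapse = " + "),
               products = paste(prods, collapse = " + "),
               enzyme = if (length(enz)) enz[1] else NA_character_,
               r = num_mod(rx, "r", 0), w = num_mod(rx, "w", 1),
               stringsAsFactors = FALSE)
  })
  rx_df <- do.call(rbind, rx_rows)
  src_rows <- lapply(srcs, function(s) {
    tg <- ends_at(s, "O", "metabolite")
    if (!length(tg)) return(NULL)
    data.frame(target = tg[1], phi = num_mod(s, c("phi", "phi_I"), 1),
               stringsAsFactors = FALSE)
  })
  # branch fractions from reaction f modifiers
  br_rows <- NULL
  if (!is.null(rx_df)) {
    fmods <- vapply(rx_df$id, function(rx) num_mod(rx, "f", NA_real_), numeric(1))
    prim <- vapply(rx_df$substrates, function(s) parse_species(s)$id[1], character(1))
    for (p in unique(prim)) {
      ii <- which(prim == p)
      if (length(ii) < 2 && all(is.na(fmods[ii]))) next
      fs <- fmods[ii]
      if (anyNA(fs)) next
      rows <- data.frame(parent = p, child = rx_df$id[ii], f = fs,
                         stringsAsFactors = FALSE)
      if (sum(fs) < 1 - 1e-9)
        rows <- rbind(rows, data.frame(parent = p, child = "sink", f = 1 - sum(fs)))
      br_rows <- rbind(br_rows, rows)
    }
  }
  # gene expression: mRNA + translation + transcriptional control
  gene_rows <- NULL; tf_rows <- NULL; enz_gene <- stats::setNames(rep(NA_character_, length(enzs)), enzs)
  for (mr in mrnas) {
    tr_hit <- NULL
    for (tl in transl) {
      if (mr %in% ends_at(tl, "I", "mrna")) { tr_hit <- tl; break }
    }
    target <- NULL; ttype <- NULL
    if (!is.null(tr_hit)) {
      out_e <- ends_at(tr_hit, "O", "enzyme")
      out_p <- ends_at(tr_hit, "O", "regulatory_protein")
      if (length(out_e)) { target <- out_e[1]; ttype <- "enzyme"; enz_gene[out_e[1]] <- mr }
      else if (length(out_p)) { target <- out_p[1]; ttype <- "protein" }
    }
    if (is.null(target)) next
    gene_rows <- rbind(gene_rows,
      data.frame(id = mr, target_type = ttype,
                 target = if (ttype == "protein") paste0(target, "_p") else target,
                 k_d = num_mod(mr, "k_d", 0.01), k_dp = 0.01, stringsAsFactors = FALSE))
  }
  for (ta in names(cls_of)[cls_of %in% c("transcriptional_activation",
                                         "transcriptional_inhibition")]) {
    reg <- c(ends_at(ta, "C", "regulatory_protein"), ends_at(ta, "C", "metabolite"))
    gene <- ends_at(ta, "O", "mrna")
    if (!length(reg) || !length(gene) || !gene[1] %in% (gene_rows$id %||% character())) next
    tf_rows <- rbind(tf_rows,
      data.frame(gene = gene[1], regulator = reg[1],
                 sign = if (cls_of[ta] == "transcriptional_activation") 1 else -1,
                 Q_max = num_mod(ta, "Q_max", 10), Q_hat = num_mod(ta, "Q_hat", 10),
                 hill = 2, basal = 0.05, stringsAsFactors = FALSE))
  }

  met_df <- if (length(mets)) data.frame(id = mets, compartment = "liver",
                                         stringsAsFactors = FALSE) else NULL
  enz_df <- if (length(enzs)) data.frame(id = enzs, compartment = "liver",
                                         gene = unname(enz_gene),
                                         k_deg = vapply(enzs, num_mod, numeric(1),
                                                        keys = "k_dE", default = 0.01),
                                         stringsAsFactors = FALSE) else NULL
  def <- model_definition(compartments = "liver",
                          metabolites = met_df %||% data.frame(id = character(),
                                                               compartment = character()),
                          enzymes = enz_df, reactions = rx_df,
                          branches = br_rows, sources = do.call(rbind, src_rows),
                          genes = gene_rows, tf_edges = tf_rows)

  counts <- table(factor(unname(cls_of), levels = unique(unname(MODELICA_CLASSES))))
  report <- structure(list(
    recognized = as.list(counts),
    n_recognized = length(comp),
    n_unrecognized = length(unrec),
    unrecognized = data.frame(
      line = vapply(unrec, function(u) u$line, integer(1)),
      text = vapply(unrec, function(u) u$text, character(1)),
      stringsAsFactors = FALSE),
    n_connects = length(conn),
    mapping = data.frame(object = names(cls_of), class = unname(cls_of),
                         stringsAsFactors = FALSE)
  ), class = "nss_import_report")
  list(definition = def, report = report)
}

#' @export
print.nss_import_report <- function(x, ...) {
  cat(sprintf("<nss_import_report> %d components recognized, %d unrecognized, %d connects\n",
              x$n_recognized, x$n_unrecognized, x$n_connects))
  for (nm in names(x$recognized))
    if (x$recognized[[nm]] > 0) cat(sprintf("  %-28s %d\n", nm, x$recognized[[nm]]))
  if (nrow(x$unrecognized)) {
    cat("unrecognized constructs:\n")
    for (i in seq_len(min(nrow(x$unrecognized), 10)))
      cat(sprintf("  line %d: %s\n", x$unrecognized$line[i], x$unrecognized$text[i]))
  }
  invisible(x)
}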