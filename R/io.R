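# Result serialization and the command-line surface.

.render_score <- function(x) {
  ifelse(is.na(x), "", sprintf("%.4f", x))
}

#' Write scoring results
#'
#' Serializes a [score_cohort()] result with a fixed column order
#' (`protein_id`, `raw_tes`, `tes`, `class`, and `dcs` when present) and
#' scores rendered at 4 decimal places (the display precision of the score
#' tables), e.g. a normalized maximum prints as `1.0000`. Full-precision
#' values can be appended as extra columns with `full_precision = TRUE`.
#' CSV and TSV variants differ only in the delimiter; output is UTF-8 with
#' LF line endings and RFC 4180 quoting for CSV.
#'
#' @param results data.frame from [score_cohort()] (optionally with a `dcs`
#'   column).
#' @param path Output path, or `""` to write to stdout.
#' @param format `"csv"` or `"tsv"`.
#' @param full_precision Append unrounded `raw_tes_full`, `tes_full` columns.
#' @return The path, invisibly.
#' @export
write_results <- function(results, path, format = c("csv", "tsv"),
                          full_precision = FALSE) {
  format <- match.arg(format)
  cols <- intersect(c("protein_id", "raw_tes", "tes", "class", "dcs"),
                    names(results))
  out <- results[, cols, drop = FALSE]
  for (cc in intersect(c("raw_tes", "tes", "dcs"), cols)) {
    out[[cc]] <- .render_score(results[[cc]])
  }
  out$class <- as.character(results$class)
  if (full_precision) {
    out$raw_tes_full <- format(results$raw_tes, digits = 15, trim = TRUE)
    out$tes_full <- format(results$tes, digits = 15, trim = TRUE)
  }
  sep <- if (format == "csv") "," else "\t"
  con <- if (identical(path, "")) stdout() else file(path, open = "wb")
  if (!identical(path, "")) on.exit(close(con))
  utils::write.table(out, con, sep = sep, quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(path)
}

#' Read scoring results
#'
#' @param path CSV/TSV written by [write_results()].
#' @param format `"csv"` or `"tsv"` (guessed from the extension when `NULL`).
#' @return data.frame with numeric `raw_tes`, `tes` and factor `class`.
#' @export
read_results <- function(path, format = NULL) {
  if (is.null(format)) format <- if (grepl("\\.tsv$", path)) "tsv" else "csv"
  sep <- if (format == "csv") "," else "\t"
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, na.strings = "")
  for (cc in intersect(c("raw_tes", "tes", "dcs"), names(df))) {
    df[[cc]] <- as.numeric(df[[cc]])
  }
  if ("class" %in% names(df)) {
    df$class <- factor(df$class, levels = c("non_translocating",
                                            "low_confidence",
                                            "high_confidence"))
  }
  df
}

.cli_usage <- function() {
  paste(c(
    "usage: transloc <command> [options]",
    "",
    "commands:",
    "  featurize  --obo F --annotations F --edges F --out F [--seed N]",
    "  score      --features F [--out F] [--format csv|tsv] [--weights high_precision|published|F] [--raw]",
    "  classify   --scores F [--lower X] [--upper X] [--out F] [--format csv|tsv]",
    "  train      --cohort F --out F [--rounds N] [--eta X] [--seed N]",
    "  cv         --cohort F --out F [--folds N] [--repeats N] [--seed N]",
    "  thresholds --scores F --labels F --out F",
    "  dcs        --registry F --out F",
    "  validate   --registry F",
    "  simulate   --out-dir D [--seed N] [--preset paper-scale|tiny]",
    "",
    "transloc --version prints the package and packaged-model provenance."),
    collapse = "\n")
}

.cli_opts <- function(argv) {
  opts <- list(); i <- 1L
  while (i <= length(argv)) {
    a <- argv[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a, call. = FALSE)
    key <- sub("^--", "", a)
    if (i < length(argv) && !startsWith(argv[i + 1L], "--")) {
      opts[[key]] <- argv[i + 1L]; i <- i + 2L
    } else {
      opts[[key]] <- TRUE; i <- i + 1L
    }
  }
  opts
}

.cli_need <- function(opts, keys) {
  miss <- setdiff(keys, names(opts))
  if (length(miss)) {
    stop("missing required option(s): ",
         paste0("--", miss, collapse = ", "), call. = FALSE)
  }
}

.cli_weights <- function(opts) {
  w <- opts[["weights"]]
  if (is.null(w) || w %in% c("high_precision", "published")) {
    tes_weights(if (is.null(w)) "high_precision" else w)
  } else {
    tab <- utils::read.table(w, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE, na.strings = "")
    .check_weights(tab)
  }
}

#' Command-line entry point
#'
#' Thin dispatcher over the package's functions, intended to be called from
#' an `Rscript` wrapper (see `inst/exec/transloc`). Subcommands: `featurize`,
#' `score`, `classify`, `train`, `cv`, `thresholds`, `dcs`, `validate`,
#' `simulate`. Returns (invisibly) the process exit code: 0 on success, 1 on
#' a data error, 2 on a usage error. Diagnostics go to stderr.
#'
#' @param argv Character vector of command-line arguments (excluding the
#'   program name).
#' @return Integer exit code, invisibly.
#' @export
tl_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (!length(argv)) {
    message(.cli_usage())
    return(invisible(2L))
  }
  cmd <- argv[1]
  if (cmd %in% c("--version", "version")) {
    cat(sprintf("transloc %s (packaged model: 19-feature TES weight table, variants high_precision/published; thresholds %.4f/%.4f)\n",
                as.character(utils::packageVersion("transloc")),
                TES_LOWER, TES_UPPER))
    return(invisible(0L))
  }
  if (cmd %in% c("--help", "help")) {
    message(.cli_usage())
    return(invisible(0L))
  }
  known <- c("featurize", "score", "classify", "train", "cv", "thresholds",
             "dcs", "validate", "simulate")
  if (!cmd %in% known) {
    message("unknown subcommand: ", cmd, "\n", .cli_usage())
    return(invisible(2L))
  }
  opts <- tryCatch(.cli_opts(argv[-1]), error = function(e) e)
  if (inherits(opts, "error")) {
    message(conditionMessage(opts), "\n", .cli_usage())
    return(invisible(2L))
  }
  code <- tryCatch({
    switch(cmd,
      featurize = .cmd_featurize(opts),
      score = .cmd_score(opts),
      classify = .cmd_classify(opts),
      train = .cmd_train(opts),
      cv = .cmd_cv(opts),
      thresholds = .cmd_thresholds(opts),
      dcs = .cmd_dcs(opts),
      validate = .cmd_validate(opts),
      simulate = .cmd_simulate(opts))
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(as.integer(code))
}

.cmd_featurize <- function(opts) {
  .cli_need(opts, c("obo", "annotations", "edges", "out"))
  seed <- as.integer(opts[["seed"]] %||% 0L)
  dag <- read_obo(opts[["obo"]])
  ann <- annotate_proteins(read_annotations(opts[["annotations"]]), dag)
  graph <- read_edge_list(opts[["edges"]], quiet = TRUE)
  topo <- topology_table(graph, seed = seed)
  ff <- feature_frame(topo, ann)
  utils::write.table(ff, opts[["out"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  message(sprintf("featurize: %d proteins -> %s", nrow(ff), opts[["out"]]))
  0L
}

.read_feature_frame <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, na.strings = "")
  if (!"go_terms" %in% names(df)) df$go_terms <- ""
  df$go_terms[is.na(df$go_terms)] <- ""
  df
}

.cmd_score <- function(opts) {
  .cli_need(opts, "features")
  table <- .cli_weights(opts)
  feats <- features_from_frame(.read_feature_frame(opts[["features"]]))
  raw <- vapply(feats, function(f) raw_tes(binarize_features(f, table), table),
                numeric(1))
  ids <- vapply(feats, `[[`, "", "protein_id")
  if (isTRUE(opts[["raw"]])) {
    out <- data.frame(protein_id = ids, raw_tes = raw)
    con <- if (is.null(opts[["out"]])) stdout() else opts[["out"]]
    utils::write.table(
      data.frame(protein_id = ids, raw_tes = .render_score(raw)),
      con, sep = if (identical(opts[["format"]], "tsv")) "\t" else ",",
      quote = FALSE, row.names = FALSE)
    return(0L)
  }
  res <- score_cohort(feats, table)
  write_results(res, opts[["out"]] %||% "",
                format = opts[["format"]] %||% "csv")
  0L
}

.cmd_classify <- function(opts) {
  .cli_need(opts, "scores")
  res <- read_results(opts[["scores"]])
  lower <- as.numeric(opts[["lower"]] %||% TES_LOWER)
  upper <- as.numeric(opts[["upper"]] %||% TES_UPPER)
  res$class <- classify_tes(res$tes, lower, upper)
  write_results(res, opts[["out"]] %||% "",
                format = opts[["format"]] %||% "csv")
  0L
}

.cmd_train <- function(opts) {
  .cli_need(opts, c("cohort", "out"))
  cohort <- read_cohort(opts[["cohort"]])
  cfg <- training_config(seed = as.integer(opts[["seed"]] %||% 0L),
                         nrounds = as.integer(opts[["rounds"]] %||% 100L),
                         learning_rate = as.numeric(opts[["eta"]] %||% 0.3))
  ens <- fit_stump_ensemble(cohort, cfg)
  sel <- select_features(ens, cfg$importance_cutoff)
  jsonlite::write_json(
    list(importance = as.list(ens$importance),
         selected_features = sel,
         weight_table = as_weight_table(ens),
         base = ens$base, n_trees = nrow(ens$trees)),
    opts[["out"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  message(sprintf("train: %d features selected (|importance| > %g) -> %s",
                  length(sel), cfg$importance_cutoff, opts[["out"]]))
  0L
}

.cmd_cv <- function(opts) {
  .cli_need(opts, c("cohort", "out"))
  cohort <- read_cohort(opts[["cohort"]])
  cfg <- training_config(folds = as.integer(opts[["folds"]] %||% 5L),
                         repeats = as.integer(opts[["repeats"]] %||% 100L),
                         seed = as.integer(opts[["seed"]] %||% 0L))
  rep <- cross_validate(cohort, cfg)
  jsonlite::write_json(list(auc = rep$auc, summary = as.list(rep$summary)),
                       opts[["out"]], auto_unbox = TRUE, digits = NA)
  message(sprintf("cv: mean AUC %.4f over %d runs -> %s",
                  rep$summary["mean"], cfg$repeats, opts[["out"]]))
  0L
}

.cmd_thresholds <- function(opts) {
  .cli_need(opts, c("scores", "labels", "out"))
  scores <- as.numeric(readLines(opts[["scores"]]))
  labels <- as.integer(readLines(opts[["labels"]]))
  scan <- f1_threshold_scan(scores, labels)
  hi <- high_confidence_cutoff(scores[labels == 0L])
  jsonlite::write_json(list(f1_threshold = scan$threshold, f1 = scan$f1,
                            high_confidence_cutoff = hi),
                       opts[["out"]], auto_unbox = TRUE, digits = NA)
  curves_path <- sub("\\.json$", "_curves.tsv", opts[["out"]])
  utils::write.table(scan$curves, curves_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  0L
}

.cmd_dcs <- function(opts) {
  .cli_need(opts, c("registry", "out"))
  reg <- registry_dcs(read_registry(opts[["registry"]]))
  write_registry(reg, opts[["out"]])
  0L
}

.cmd_validate <- function(opts) {
  .cli_need(opts, "registry")
  v <- validate_registry(read_registry(opts[["registry"]]))
  if (nrow(v)) {
    utils::write.table(v, stdout(), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(1L)
  }
  message("registry valid")
  0L
}

.cmd_simulate <- function(opts) {
  .cli_need(opts, "out-dir")
  preset <- opts[["preset"]] %||% "paper-scale"
  seed <- as.integer(opts[["seed"]] %||% 0L)
  spec <- switch(preset,
    "paper-scale" = synthetic_spec(seed = seed),
    "tiny" = synthetic_spec(seed = seed, n_terms = 15L, n_positive = 20L,
                            n_negative = 15L, noise_go = 5L,
                            mean_degree = 5, degree_effect = 4,
                            n_entries = 12L, n_pathology_only = 3L,
                            n_bridges = 2L),
    stop("unknown preset: ", preset, call. = FALSE))
  dir.create(opts[["out-dir"]], showWarnings = FALSE, recursive = TRUE)
  dag <- make_ontology(spec)
  graph <- make_interactome(spec)
  syn <- make_cohort(spec, dag, graph)
  reg <- make_curated_registry(spec)
  p <- function(f) file.path(opts[["out-dir"]], f)
  write_obo(dag, p("ontology.obo"))
  write_annotations(syn$annotations, p("annotations.tsv"))
  write_edge_list(graph, p("edges.tsv"))
  write_cohort(syn$cohort, p("cohort.tsv"))
  write_registry(reg, p("registry.csv"))
  topo <- topology_table(graph, seed = spec$seed)
  ff <- feature_frame(topo, annotate_proteins(syn$annotations, dag))
  utils::write.table(ff, p("features.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  message(sprintf("simulate: preset '%s', seed %d -> %s", preset, seed,
                  opts[["out-dir"]]))
  0L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
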