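# Translocation Evidence Score (TES): binary featurization against a weighted
# indicator model, raw weighted sum, min-max normalization to [0,1], and
# three-class classification with calibrated cutoffs.

# Default classifier boundaries: the lower one maximizes F1 on the training
# cohort, the upper one is the largest normalized score attained by any
# negative-set protein.
TES_LOWER <- 0.4487
TES_UPPER <- 0.6167

#' The packaged translocation model
#'
#' Returns the final 19-feature weight table of the translocation evidence
#' model: 15 GO-term indicators, two degree indicators (`degree < 14.5`,
#' `degree < 62.5`) and two bridgeness indicators (`bridgeness < 2.5e-06`,
#' `bridgeness < 0.000292`), each carrying a signed importance weight
#' obtained as the summed leaf scores of a boosted one-depth-tree model.
#'
#' Two variants ship. `"high_precision"` (the default) uses three-decimal
#' weights for the three coefficients published at that precision
#' (-0.497 for `degree < 62.5`, 2.675 for GO:0009887, 1.353 for GO:0005737)
#' and two-decimal weights elsewhere; `"published"` rounds all weights to two
#' decimals. The bridgeness cutoffs are on the scale of the module-overlap
#' tool used to build the model; they are meaningful for externally supplied
#' bridgeness columns on that scale, while bridgeness computed by
#' [bridgeness()] requires recalibrated cutoffs (pass a custom table).
#'
#' @param variant `"high_precision"` or `"published"`.
#' @return A `tes_weights` data.frame with columns `feature_id`, `kind`
#'   (`go_term`, `degree_below`, `bridgeness_below`), `term` (GO id or `NA`),
#'   `threshold` (numeric or `NA`), `weight`, `description`.
#' @examples
#' w <- tes_weights()
#' nrow(w)   # 19
#' sum(w$weight[w$weight > 0])
#' @export
tes_weights <- function(variant = c("high_precision", "published")) {
  variant <- match.arg(variant)
  tab <- data.frame(
    feature_id = c(
      "GO:0009887", "GO:0006109", "GO:0005737", "GO:0044428", "GO:0048523",
      "GO:0044459", "GO:0005576", "GO:0005829", "GO:0005681",
      "bridgeness_below_0.000292", "degree_below_62.5", "degree_below_14.5",
      "GO:1902532", "GO:0030099", "GO:0031224", "GO:0003008", "GO:0016337",
      "bridgeness_below_2.5e-06", "GO:0043234"),
    kind = c(rep("go_term", 9),
             "bridgeness_below", "degree_below", "degree_below",
             rep("go_term", 5), "bridgeness_below", "go_term"),
    term = c("GO:0009887", "GO:0006109", "GO:0005737", "GO:0044428",
             "GO:0048523", "GO:0044459", "GO:0005576", "GO:0005829",
             "GO:0005681", NA, NA, NA,
             "GO:1902532", "GO:0030099", "GO:0031224", "GO:0003008",
             "GO:0016337", NA, "GO:0043234"),
    threshold = c(rep(NA_real_, 9), 0.000292, 62.5, 14.5,
                  rep(NA_real_, 5), 2.5e-06, NA_real_),
    weight = c(2.68, 1.53, 1.35, 1.12, 1.12, 0.70, 0.65, 0.57, 0.23,
               -0.36, -0.50, -0.54, -0.61, -0.74, -0.82, -0.91, -1.06,
               -1.10, -1.24),
    description = c(
      "animal organ morphogenesis", "regulation of carbohydrate metabolic process",
      "cytoplasm", "nuclear part", "negative regulation of cellular process",
      "plasma membrane part", "extracellular region", "cytosol",
      "spliceosomal complex", "bridgeness lower than 0.000292",
      "degree lower than 62.5", "degree lower than 14.5",
      "negative regulation of intracellular signal transduction",
      "myeloid cell differentiation", "intrinsic component of membrane",
      "system process", "single organismal cell-cell adhesion",
      "bridgeness lower than 2.5e-06", "protein complex"),
    stringsAsFactors = FALSE)
  if (variant == "high_precision") {
    tab$weight[tab$feature_id == "GO:0009887"] <- 2.675
    tab$weight[tab$feature_id == "GO:0005737"] <- 1.353
    tab$weight[tab$feature_id == "degree_below_62.5"] <- -0.497
  }
  attr(tab, "variant") <- variant
  class(tab) <- c("tes_weights", "data.frame")
  tab
}

.check_weights <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("feature_id", "kind", "weight") %in% names(table)))
  if (anyDuplicated(table$feature_id)) {
    stop("duplicate feature_id in weight table", call. = FALSE)
  }
  bad <- setdiff(unique(table$kind),
                 c("go_term", "degree_below", "bridgeness_below"))
  if (length(bad)) {
    stop("unknown feature kind(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(table)
}

#' Assemble a protein feature record
#'
#' @param protein_id Protein identifier.
#' @param go_terms Character vector of (ideally ancestor-closed) GO term ids.
#' @param degree Integer degree, or `NA` if unknown.
#' @param bridgeness Numeric bridgeness, or `NA` if unknown (e.g. the protein
#'   lies outside the interactome giant component).
#' @return A `protein_features` list.
#' @export
protein_features <- function(protein_id, go_terms = character(0),
                             degree = NA, bridgeness = NA) {
  structure(list(protein_id = as.character(protein_id),
                 go_terms = unique(as.character(go_terms)),
                 degree = if (is.na(degree)) NA_real_ else as.numeric(degree),
                 bridgeness = as.numeric(bridgeness)),
            class = "protein_features")
}

#' Binarize a protein against a weight table
#'
#' Produces the indicator vector `x` of the scoring model: a `go_term`
#' feature is true iff the term is in the protein's GO set; `degree_below(t)`
#' is true iff the degree is known and `< t`; `bridgeness_below(t)` is true
#' iff bridgeness is known and `< t`. An unknown underlying value always
#' yields false — a protein with no interactome record activates none of the
#' topology indicators.
#'
#' @param features A [protein_features()] record.
#' @param table A weight table from [tes_weights()] (or custom, same columns).
#' @return Integer 0/1 vector named by `feature_id`, aligned to the table.
#' @export
binarize_features <- function(features, table = tes_weights()) {
  .check_weights(table)
  x <- integer(nrow(table))
  for (i in seq_len(nrow(table))) {
    x[i] <- switch(table$kind[i],
      go_term = as.integer(table$term[i] %in% features$go_terms),
      degree_below = as.integer(!is.na(features$degree) &&
                                  features$degree < table$threshold[i]),
      bridgeness_below = as.integer(!is.na(features$bridgeness) &&
                                      features$bridgeness < table$threshold[i]))
  }
  stats::setNames(x, table$feature_id)
}

#' Raw translocation evidence score
#'
#' The weighted sum over model indicators,
#' \deqn{TES_{raw} = \sum_{i=1}^{n} w_i x_i,}
#' where `w_i` is the signed importance weight of feature `i` and `x_i` its
#' 0/1 indicator.
#'
#' @param x Indicator vector from [binarize_features()].
#' @param table The matching weight table.
#' @return The raw (pre-normalization) score.
#' @examples
#' w <- tes_weights()
#' p <- protein_features("A", go_terms = c("GO:0009887", "GO:0005737"),
#'                       degree = 20)
#' raw_tes(binarize_features(p, w), w)   # 3.531
#' @export
raw_tes <- function(x, table = tes_weights()) {
  .check_weights(table)
  if (length(x) != nrow(table)) {
    stop(sprintf("indicator vector length %d does not match table length %d",
                 length(x), nrow(table)), call. = FALSE)
  }
  if (!all(x %in% c(0L, 1L))) stop("indicators must be 0/1", call. = FALSE)
  sum(table$weight * as.numeric(x))
}

#' Min-max normalization of raw scores
#'
#' Rescales a cohort of raw scores to `[0, 1]`:
#' \deqn{x' = (x - x_{min}) / (x_{max} - x_{min}).}
#' The cohort maximum maps to 1 and the minimum to 0. A fixed reference
#' `(min, max)` pair may be supplied to score new proteins against a frozen
#' cohort; values are then clipped into `[0, 1]`.
#'
#' @param scores Numeric vector of raw scores (at least 2 distinct values
#'   unless a reference range is given).
#' @param reference Optional `c(min, max)` reference range.
#' @return Numeric vector of normalized scores in `[0, 1]`.
#' @export
normalize_tes <- function(scores, reference = NULL) {
  if (is.null(reference)) {
    lo <- min(scores); hi <- max(scores)
    if (!is.finite(lo) || !is.finite(hi) || hi == lo) {
      stop("degenerate cohort: all raw scores identical; min-max normalization undefined",
           call. = FALSE)
    }
  } else {
    stopifnot(length(reference) == 2L)
    lo <- reference[1]; hi <- reference[2]
    if (hi <= lo) stop("reference range must have min < max", call. = FALSE)
  }
  pmin(1, pmax(0, (scores - lo) / (hi - lo)))
}

#' Classify a normalized score
#'
#' Three-class partition of normalized scores: below `lower` is
#' non-translocating, above `upper` is high-confidence translocating, and
#' everything in between — both boundary values included — is low-confidence
#' translocating.
#'
#' @param normalized Numeric vector of normalized scores in `[0, 1]`.
#' @param lower,upper Class boundaries; defaults are the calibrated 0.4487
#'   (F1 maximum) and 0.6167 (no negative-set protein above it).
#' @return Factor with levels `non_translocating`, `low_confidence`,
#'   `high_confidence`.
#' @export
classify_tes <- function(normalized, lower = TES_LOWER, upper = TES_UPPER) {
  if (lower >= upper) stop("classification thresholds require lower < upper",
                           call. = FALSE)
  if (any(normalized < 0 | normalized > 1, na.rm = TRUE)) {
    stop("normalized scores must lie in [0, 1]", call. = FALSE)
  }
  cls <- ifelse(normalized < lower, "non_translocating",
                ifelse(normalized > upper, "high_confidence",
                       "low_confidence"))
  factor(cls, levels = c("non_translocating", "low_confidence",
                         "high_confidence"))
}

#' Score a cohort of proteins
#'
#' The full pipeline binarize -> raw score -> min-max normalize -> classify,
#' applied to a list of protein feature records. Output rows are in input
#' order.
#'
#' @param features List of [protein_features()] records, or a data.frame with
#'   columns `protein_id`, `degree`, `bridgeness`, `go_terms`
#'   (semicolon-joined).
#' @param table Weight table; see [tes_weights()].
#' @param lower,upper Classification boundaries.
#' @param reference Optional fixed normalization range, see [normalize_tes()].
#' @return A data.frame with columns `protein_id`, `raw_tes`, `tes`, `class`.
#' @export
score_cohort <- function(features, table = tes_weights(),
                         lower = TES_LOWER, upper = TES_UPPER,
                         reference = NULL) {
  if (is.data.frame(features)) features <- features_from_frame(features)
  raw <- vapply(features,
                function(f) raw_tes(binarize_features(f, table), table),
                numeric(1))
  tes <- normalize_tes(raw, reference = reference)
  data.frame(protein_id = vapply(features, `[[`, "", "protein_id"),
             raw_tes = raw,
             tes = tes,
             class = classify_tes(tes, lower, upper),
             stringsAsFactors = FALSE)
}

#' Convert a merged feature table to protein feature records
#'
#' @param df data.frame with columns `protein_id`, `degree`, `bridgeness`,
#'   `go_terms` (semicolon-joined term ids; empty for none).
#' @return List of [protein_features()] records.
#' @export
features_from_frame <- function(df) {
  stopifnot(all(c("protein_id", "degree", "bridgeness", "go_terms") %in% names(df)))
  lapply(seq_len(nrow(df)), function(i) {
    gt <- df$go_terms[i]
    gt <- if (is.na(gt) || !nzchar(gt)) character(0) else
      strsplit(gt, ";", fixed = TRUE)[[1]]
    protein_features(df$protein_id[i], go_terms = trimws(gt),
                     degree = df$degree[i], bridgeness = df$bridgeness[i])
  })
}

#' Merge topology and annotations into a feature table
#'
#' Joins a topology table with an (ancestor-closed) annotation set into the
#' merged feature table consumed by [score_cohort()] and the CLI.
#'
#' @param topology data.frame from [topology_table()].
#' @param annotations Named list protein id -> term ids (see
#'   [annotate_proteins()]); proteins absent from it get an empty GO set.
#' @return data.frame with columns `protein_id`, `degree`, `bridgeness`,
#'   `go_terms`.
#' @export
feature_frame <- function(topology, annotations) {
  gt <- vapply(topology$protein_id, function(p) {
    terms <- annotations[[p]]
    if (is.null(terms)) "" else paste(sort(terms), collapse = ";")
  }, "")
  data.frame(protein_id = topology$protein_id,
             degree = topology$degree,
             bridgeness = topology$bridgeness,
             go_terms = unname(gt),
             stringsAsFactors = FALSE)
}
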