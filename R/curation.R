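# Curated-entry registry: schema validation, training-set assembly, and the
# Data Complexity Score (DCS).

# UniProt accession pattern (6- and 10-character forms).
UNIPROT_AC_REGEX <- "^([OPQ][0-9][A-Z0-9]{3}[0-9]|[A-NR-Z][0-9]([A-Z][A-Z0-9]{2}[0-9]){1,2})$"

MAJOR_LOCALIZATIONS <- c("cytoplasm", "extracellular", "mitochondrion",
                         "nucleus", "membrane", "secretory-pathway")

NEGATIVE_CATEGORIES <- c("diffuse_multicompartmental", "single_compartment",
                         "nucleic_acid_docked", "membrane_embedded",
                         "cytoskeleton_attached")

# Registry columns, in canonical order. List-valued cells are
# semicolon-joined strings.
REGISTRY_COLUMNS <- c(
  "uniprot_ac", "gene_name", "protein_names", "pubmed_ids",
  "initial_localization", "initial_localization_minor",
  "target_localization", "target_localization_minor",
  "partners_initial", "partners_target",
  "functions_initial", "functions_target",
  "mechanism", "detection_method", "structural_info",
  "disease_group", "disease", "pathological_role", "pathways",
  "pathology_only", "negative_category")

#' Default Data Complexity Score weights
#'
#' Per-field weights for [data_complexity_score()]. Fields describing the
#' translocation event itself (mechanism, detection method, structural
#' information) carry weight 2; descriptive fields carry weight 1. The
#' weights are an editable configuration, not a fixed constant of the score.
#'
#' @return Named numeric vector of non-negative weights.
#' @export
dcs_weights <- function() {
  c(pubmed_ids = 1,
    initial_localization_minor = 1, target_localization_minor = 1,
    partners_initial = 1, partners_target = 1,
    functions_initial = 1, functions_target = 1,
    mechanism = 2, detection_method = 2, structural_info = 2,
    disease_group = 1, disease = 1, pathological_role = 1,
    pathways = 1)
}

.blank <- function(x) {
  is.null(x) || length(x) == 0L || all(is.na(x)) ||
    (is.character(x) && !any(nzchar(trimws(x))))
}

#' Validate a curated entry
#'
#' Checks one registry row against the schema invariants: UniProt accession
#' pattern; major localizations drawn from the six-value vocabulary
#' (cytoplasm, extracellular, mitochondrion, nucleus, membrane,
#' secretory-pathway); a translocating entry must change localization
#' (different major localizations, or the same major with distinct minors);
#' the negative category, when set, must be one of the five recognized
#' classes and is mutually exclusive with translocation.
#'
#' Violations are returned as data, not raised as errors.
#'
#' @param entry A named list or one-row data.frame with registry fields.
#' @return Character vector of violations (empty if the entry is valid),
#'   each formatted `"field: rule"`.
#' @export
validate_entry <- function(entry) {
  entry <- as.list(entry)
  v <- character(0)
  ac <- entry$uniprot_ac
  if (.blank(ac) || !grepl(UNIPROT_AC_REGEX, ac)) {
    v <- c(v, sprintf("uniprot_ac: '%s' does not match the UniProt accession pattern",
                      if (.blank(ac)) "" else ac))
  }
  is_negative <- !.blank(entry$negative_category)
  for (fld in c("initial_localization", "target_localization")) {
    loc <- entry[[fld]]
    if (!.blank(loc) && !loc %in% MAJOR_LOCALIZATIONS) {
      v <- c(v, sprintf("%s: '%s' is not one of the six major localizations",
                        fld, loc))
    }
  }
  if (is_negative) {
    if (!entry$negative_category %in% NEGATIVE_CATEGORIES) {
      v <- c(v, sprintf("negative_category: '%s' is not a recognized category",
                        entry$negative_category))
    }
    if (!.blank(entry$target_localization)) {
      v <- c(v, "negative_category: a non-translocating entry must not declare a target localization")
    }
  } else {
    if (.blank(entry$initial_localization) || .blank(entry$target_localization)) {
      v <- c(v, "localization: a translocating entry needs both initial and target localizations")
    } else {
      same_major <- entry$initial_localization == entry$target_localization
      same_minor <- identical(entry$initial_localization_minor,
                              entry$target_localization_minor)
      if (same_major && (same_minor ||
                         (.blank(entry$initial_localization_minor) &&
                          .blank(entry$target_localization_minor)))) {
        v <- c(v, "localization: initial and target localizations must differ (major or minor)")
      }
    }
  }
  v
}

#' Validate a whole registry
#'
#' @param registry data.frame of curated entries (see [read_registry()]).
#' @return data.frame with columns `uniprot_ac`, `violation`; zero rows if
#'   the registry is valid.
#' @export
validate_registry <- function(registry) {
  out <- lapply(seq_len(nrow(registry)), function(i) {
    v <- validate_entry(registry[i, , drop = FALSE])
    if (length(v)) data.frame(uniprot_ac = registry$uniprot_ac[i],
                              violation = v, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(uniprot_ac = character(0), violation = character(0),
                      stringsAsFactors = FALSE)
  }
  out
}

#' Assemble positive and negative training sets
#'
#' Positives are the translocating entries (no negative category) whose
#' translocation is observed under physiological conditions
#' (`pathology_only = FALSE`); entries translocating exclusively under
#' pathological conditions are excluded. Negatives are the entries carrying a
#' negative-set category. An entry that is both translocating (has a target
#' localization) and negative-flagged is inconsistent and raises an error.
#'
#' @param registry data.frame of curated entries.
#' @return List with data.frames `positives` and `negatives`.
#' @export
build_training_sets <- function(registry) {
  neg_flag <- !is.na(registry$negative_category) &
    nzchar(trimws(as.character(registry$negative_category)))
  has_target <- !is.na(registry$target_localization) &
    nzchar(trimws(as.character(registry$target_localization)))
  conflict <- neg_flag & has_target
  if (any(conflict)) {
    stop("entries both translocating and negative-flagged: ",
         paste(registry$uniprot_ac[conflict], collapse = ", "), call. = FALSE)
  }
  patho <- .as_flag(registry$pathology_only)
  list(positives = registry[!neg_flag & !patho, , drop = FALSE],
       negatives = registry[neg_flag, , drop = FALSE])
}

.as_flag <- function(x) {
  if (is.logical(x)) return(!is.na(x) & x)
  x <- tolower(trimws(as.character(x)))
  !is.na(x) & x %in% c("true", "1", "yes")
}

#' Data Complexity Score
#'
#' A normalized weighted measure in `[0, 1]` of how much curated information
#' an entry carries:
#' \deqn{DCS = \sum_f w_f \, present(f) \; / \; \sum_f w_f,}
#' over the weighted fields, where `present(f)` is 1 iff field `f` is
#' populated (a list-valued field counts iff nonempty; no partial credit by
#' list length). Translocation-mechanism fields carry higher weight than
#' descriptive ones under the default [dcs_weights()], so the score reflects
#' the relevance as well as the quantity of the curated data.
#'
#' @param entry A named list or one-row data.frame of registry fields.
#' @param weights Named non-negative weights; see [dcs_weights()].
#' @return DCS in `[0, 1]`.
#' @export
data_complexity_score <- function(entry, weights = dcs_weights()) {
  if (!length(weights) || all(weights == 0) || any(weights < 0)) {
    stop("DCS weights must be non-negative with at least one positive value",
         call. = FALSE)
  }
  entry <- as.list(entry)
  present <- vapply(names(weights), function(f) !.blank(entry[[f]]), TRUE)
  sum(weights[present]) / sum(weights)
}

#' Append DCS to a registry
#'
#' @param registry data.frame of curated entries.
#' @param weights Passed to [data_complexity_score()].
#' @return The registry with a `dcs` column appended.
#' @export
registry_dcs <- function(registry, weights = dcs_weights()) {
  registry$dcs <- vapply(seq_len(nrow(registry)), function(i) {
    data_complexity_score(registry[i, , drop = FALSE], weights)
  }, numeric(1))
  registry
}

#' Read a curated registry
#'
#' CSV (default) or TSV with one column per registry field; list-valued
#' cells are semicolon-joined.
#'
#' @param path Input path.
#' @param sep Field separator (`","` or `"\t"`; guessed from the extension
#'   when `NULL`).
#' @return data.frame with the registry columns.
#' @export
read_registry <- function(path, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE, quote = "\"",
                          stringsAsFactors = FALSE, na.strings = "",
                          comment.char = "")
  if ("pathology_only" %in% names(df)) {
    df$pathology_only <- .as_flag(df$pathology_only)
  }
  df
}

#' Write a curated registry
#'
#' @param registry data.frame of curated entries.
#' @param path Output path.
#' @param sep Field separator (guessed from the extension when `NULL`).
#' @export
write_registry <- function(registry, path, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(registry, path, sep = sep, quote = sep == ",",
                     row.names = FALSE, na = "", qmethod = "double")
  invisible(path)
}
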