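# Ontology ingest and ancestor-closure annotation propagation.

#' Read an OBO ontology
#'
#' Parses the `[Term]` stanzas of an OBO 1.2/1.4 file into an ontology DAG.
#' Only the fields the scoring pipeline consumes are retained: term id, name,
#' namespace, obsolescence flag, `alt_id` aliases, and the child-to-parent
#' edges given by `is_a` and `relationship: part_of` tags. Other relationship
#' types (e.g. `regulates`) are ignored by default because annotation
#' propagation conventionally follows only `is_a`/`part_of`.
#'
#' @param path Path to an OBO file, or a character vector of its lines.
#' @param relations Relationship types to keep as closure edges.
#' @return An object of class `onto_dag`: a list with `terms` (data.frame with
#'   columns `id`, `name`, `namespace`, `obsolete`), `parents` (named list
#'   mapping each term id to its direct parent ids), and `alt` (named
#'   character vector mapping alternative ids to canonical ids).
#' @examples
#' obo <- c("format-version: 1.2", "",
#'          "[Term]", "id: GO:0000001", "name: root",
#'          "namespace: cellular_component", "",
#'          "[Term]", "id: GO:0000002", "name: child",
#'          "namespace: cellular_component", "is_a: GO:0000001 ! root")
#' dag <- read_obo(obo)
#' ancestor_closure(dag, "GO:0000002")
#' @export
read_obo <- function(path, relations = c("is_a", "part_of")) {
  lines <- if (length(path) == 1L && !grepl("\n", path) && file.exists(path)) {
    readLines(path, warn = FALSE)
  } else {
    as.character(path)
  }
  lines <- sub("\\s+$", "", lines)

  # stanza boundaries
  starts <- grep("^\\[", lines)
  term_starts <- which(lines == "[Term]")
  if (!length(term_starts)) {
    stop("no [Term] stanzas found in OBO input", call. = FALSE)
  }
  ends <- c(starts[-1] - 1L, length(lines))
  stanza_end <- ends[match(term_starts, starts)]

  ids <- character(0); names_ <- character(0); ns <- character(0)
  obso <- logical(0)
  parents <- list(); alt_from <- character(0); alt_to <- character(0)

  for (k in seq_along(term_starts)) {
    body <- lines[seq(term_starts[k] + 1L, stanza_end[k])]
    body <- body[nzchar(body) & !grepl("^!", body)]
    bad <- body[!grepl("^[A-Za-z_]+:", body)]
    if (length(bad)) {
      line_no <- term_starts[k] + match(bad[1], lines[seq(term_starts[k] + 1L, stanza_end[k])])
      stop(sprintf("malformed OBO tag at line %d: '%s'", line_no, bad[1]),
           call. = FALSE)
    }
    tag <- sub(":.*$", "", body)
    val <- sub("^[A-Za-z_]+:\\s*", "", body)
    val <- sub("\\s*!.*$", "", val)          # strip trailing comments
    id <- val[tag == "id"][1]
    if (is.na(id)) {
      stop(sprintf("[Term] stanza starting at line %d has no id tag",
                   term_starts[k]), call. = FALSE)
    }
    ids <- c(ids, id)
    names_ <- c(names_, if (any(tag == "name")) val[tag == "name"][1] else NA_character_)
    ns <- c(ns, if (any(tag == "namespace")) val[tag == "namespace"][1] else NA_character_)
    obso <- c(obso, any(tag == "is_obsolete" & tolower(val) %in% c("true", "1")))

    par <- val[tag == "is_a" & "is_a" %in% relations]
    rel <- val[tag == "relationship"]
    if (length(rel)) {
      rtype <- sub("\\s.*$", "", rel)
      rtarget <- sub("^\\S+\\s+", "", rel)
      par <- c(par, rtarget[rtype %in% setdiff(relations, "is_a")])
    }
    parents[[id]] <- unique(par)

    av <- val[tag == "alt_id"]
    if (length(av)) {
      alt_from <- c(alt_from, av)
      alt_to <- c(alt_to, rep(id, length(av)))
    }
  }

  if (anyDuplicated(ids)) {
    stop("duplicate term ids in OBO input: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  all_parents <- unique(unlist(parents, use.names = FALSE))
  missing <- setdiff(all_parents, ids)
  if (length(missing)) {
    stop("edge endpoints not declared as terms: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }

  dag <- structure(
    list(terms = data.frame(id = ids, name = names_, namespace = ns,
                            obsolete = obso, stringsAsFactors = FALSE),
         parents = parents,
         alt = stats::setNames(alt_to, alt_from)),
    class = "onto_dag")
  .check_acyclic(dag)
  dag
}

# Kahn's algorithm over child->parent edges; cycles leave nodes unprocessed.
.check_acyclic <- function(dag) {
  ids <- dag$terms$id
  indeg <- stats::setNames(integer(length(ids)), ids)  # number of parents left
  for (id in ids) indeg[[id]] <- length(dag$parents[[id]])
  children <- split(
    rep(ids, lengths(dag$parents[ids])),
    unlist(dag$parents[ids], use.names = FALSE))
  queue <- ids[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]; seen <- seen + 1L
    for (ch in children[[v]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen < length(ids)) {
    stop("ontology relation graph contains a cycle involving: ",
         paste(names(indeg)[indeg > 0L], collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.onto_dag <- function(x, ...) {
  cat(sprintf("Ontology DAG: %d terms (%d obsolete), %d edges, %d alt ids\n",
              nrow(x$terms), sum(x$terms$obsolete),
              sum(lengths(x$parents)), length(x$alt)))
  invisible(x)
}

#' Resolve term ids to canonical form
#'
#' Maps `alt_id` aliases to their canonical term id; canonical ids pass
#' through unchanged.
#'
#' @param dag An `onto_dag`.
#' @param terms Character vector of term ids.
#' @return Character vector of canonical ids (NA where unknown).
#' @export
resolve_terms <- function(dag, terms) {
  out <- as.character(terms)
  is_alt <- out %in% names(dag$alt)
  out[is_alt] <- unname(dag$alt[out[is_alt]])
  out[!out %in% dag$terms$id] <- NA_character_
  out
}

#' Ancestor closure of a term set
#'
#' Augments a set of term ids with all transitive ancestors reachable via
#' `is_a`/`part_of` edges. Obsolete terms are excluded from the result.
#' The closure is idempotent and monotone in its input.
#'
#' @param dag An `onto_dag`.
#' @param terms Character vector of term ids (alt ids are canonicalized).
#' @return Sorted character vector: the input united with all its ancestors.
#' @export
ancestor_closure <- function(dag, terms) {
  if (!length(terms)) return(character(0))
  canon <- resolve_terms(dag, terms)
  if (anyNA(canon)) {
    stop("unknown term id(s): ",
         paste(unique(terms[is.na(canon)]), collapse = ", "), call. = FALSE)
  }
  obsolete <- dag$terms$id[dag$terms$obsolete]
  frontier <- setdiff(unique(canon), obsolete)
  out <- frontier
  while (length(frontier)) {
    up <- unique(unlist(dag$parents[frontier], use.names = FALSE))
    frontier <- setdiff(up, out)
    out <- c(out, frontier)
  }
  sort(setdiff(out, obsolete))
}

#' Read a protein-to-GO annotation table
#'
#' Accepts either a two-column TSV (`protein_id<TAB>go_id`, optional header)
#' or a GAF 2.x file, from which only the object id (column 2) and GO id
#' (column 5) are used. GAF comment lines start with `!`.
#'
#' @param path Path to the annotation file.
#' @return A named list mapping protein id to a character vector of term ids
#'   (an annotation set).
#' @export
read_annotations <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  gaf <- any(grepl("^!", lines))
  lines <- lines[!grepl("^!", lines)]
  if (!length(lines)) return(stats::setNames(list(), character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncol1 <- length(parts[[1]])
  if (gaf || ncol1 >= 5L) {
    prot <- vapply(parts, `[`, "", 2L)
    term <- vapply(parts, `[`, "", 5L)
  } else {
    if (any(lengths(parts) < 2L)) {
      stop("annotation row with fewer than 2 columns at line ",
           which(lengths(parts) < 2L)[1], call. = FALSE)
    }
    prot <- vapply(parts, `[`, "", 1L)
    term <- vapply(parts, `[`, "", 2L)
    # drop a header row if present
    if (!grepl("^GO:\\d{7}$", term[1]) && prot[1] %in% c("protein_id", "protein")) {
      prot <- prot[-1]; term <- term[-1]
    }
  }
  lapply(split(term, prot), unique)
}

#' Propagate annotations to ancestors
#'
#' Replaces each protein's annotation set by its ancestor closure over the
#' DAG. Obsolete terms are dropped with a warning; alt ids are canonicalized.
#'
#' @param annotations Named list mapping protein id to term ids.
#' @param dag An `onto_dag`.
#' @return Named list of ancestor-closed term sets, in input order.
#' @export
annotate_proteins <- function(annotations, dag) {
  if (!length(annotations)) return(stats::setNames(list(), character(0)))
  obsolete <- dag$terms$id[dag$terms$obsolete]
  dropped <- character(0)
  out <- lapply(annotations, function(terms) {
    canon <- resolve_terms(dag, terms)
    if (anyNA(canon)) {
      stop("unknown term id(s): ",
           paste(unique(terms[is.na(canon)]), collapse = ", "), call. = FALSE)
    }
    hit <- canon %in% obsolete
    if (any(hit)) dropped <<- c(dropped, canon[hit])
    keep <- canon[!hit]
    if (!length(keep)) character(0) else ancestor_closure(dag, keep)
  })
  if (length(dropped)) {
    warning(sprintf("dropped %d obsolete term annotation(s): %s",
                    length(dropped),
                    paste(unique(dropped), collapse = ", ")), call. = FALSE)
  }
  out
}
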