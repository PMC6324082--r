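# Seeded synthetic generators for every input the package consumes: a toy
# ontology, an interactome with planted hubs and bridges, a labelled training
# cohort with planted informative GO features, and a curated registry. All
# randomness flows through the package's portable integer RNG, so output is
# byte-identical across platforms for a given seed.

#' Synthetic study specification
#'
#' Parameters of the synthetic generators. The defaults emulate the study
#' conditions the package is designed around: a training cohort of 160
#' translocating and 139 non-translocating proteins whose positives carry
#' roughly twice the interactome degree of negatives, a handful of GO terms
#' truly associated with the label, a registry of 213 curated translocating
#' entries of which 53 translocate only under pathological conditions, and
#' 139 curated negative entries.
#'
#' @param seed Integer seed; every generator derives its stream from it.
#' @param n_terms Number of ontology terms.
#' @param n_positive,n_negative Cohort class sizes.
#' @param degree_effect Ratio of mean interactome degree, positives over
#'   negatives (1 = no planted degree signal).
#' @param n_informative_go Number of GO terms truly associated with the label.
#' @param informative_effect Difference in Bernoulli annotation rates between
#'   classes for informative terms (0 = null).
#' @param noise_go Number of label-independent GO terms annotated at the base
#'   rate in both classes.
#' @param base_rate Annotation rate of noise terms (and of informative terms
#'   in the negative class).
#' @param mean_degree Target mean degree of negative-class proteins.
#' @param n_bridges Number of planted bridge nodes joining the two network
#'   blocks.
#' @param n_entries Curated translocating entries in the synthetic registry.
#' @param n_pathology_only How many of those are pathology-only.
#' @param field_population Probability that an optional registry field is
#'   populated.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(seed = 0L, n_terms = 60L,
                           n_positive = 160L, n_negative = 139L,
                           degree_effect = 2, n_informative_go = 3L,
                           informative_effect = 0.6, noise_go = 20L,
                           base_rate = 0.15, mean_degree = 6,
                           n_bridges = 3L,
                           n_entries = 213L, n_pathology_only = 53L,
                           field_population = 0.7) {
  stopifnot(n_terms >= 3L, n_positive > 0L, n_negative > 0L,
            degree_effect > 0, n_informative_go >= 0L, noise_go >= 0L,
            base_rate > 0, base_rate < 1,
            base_rate + informative_effect < 1,
            n_pathology_only <= n_entries, field_population >= 0,
            field_population <= 1)
  structure(list(seed = as.integer(seed), n_terms = as.integer(n_terms),
                 n_positive = as.integer(n_positive),
                 n_negative = as.integer(n_negative),
                 degree_effect = degree_effect,
                 n_informative_go = as.integer(n_informative_go),
                 informative_effect = informative_effect,
                 noise_go = as.integer(noise_go), base_rate = base_rate,
                 mean_degree = mean_degree, n_bridges = as.integer(n_bridges),
                 n_entries = as.integer(n_entries),
                 n_pathology_only = as.integer(n_pathology_only),
                 field_population = field_population),
            class = "synthetic_spec")
}

.synth_term_id <- function(i) sprintf("GO:%07d", i)
.synth_protein_id <- function(i) sprintf("P%05d", i)

# OBO text for a random rooted DAG. Terms are partitioned into namespaces
# (one namespace below 12 terms, else three); the first term of each
# namespace is its root, every later term is a child of its predecessor
# (chain backbone, so three terms form a pure chain) and, from the fourth
# term of a namespace on, may gain a second random earlier parent.
.synth_obo_lines <- function(spec) {
  rng <- .lcg_new(spec$seed + 101L)
  n <- spec$n_terms
  ns_names <- c("cellular_component", "biological_process",
                "molecular_function")
  n_ns <- if (n < 12L) 1L else 3L
  ns_of <- rep(seq_len(n_ns), each = ceiling(n / n_ns))[seq_len(n)]
  lines <- c("format-version: 1.2", "ontology: synthetic-go")
  for (i in seq_len(n)) {
    lines <- c(lines, "", "[Term]",
               paste0("id: ", .synth_term_id(i)),
               paste0("name: synthetic term ", i),
               paste0("namespace: ", ns_names[ns_of[i]]))
    in_ns <- which(ns_of == ns_of[i] & seq_len(n) < i)
    if (length(in_ns)) {
      parents <- max(in_ns)                     # chain backbone
      pool <- setdiff(in_ns, parents)
      if (length(pool) >= 2L && .lcg_bernoulli(rng, 0.3)) {
        parents <- c(parents, pool[.lcg_int(rng, length(pool))])
      }
      rel <- ifelse(.lcg_bernoulli(rng, 0.25, length(parents)),
                    "part_of", "is_a")
      for (k in seq_along(parents)) {
        lines <- c(lines,
                   if (rel[k] == "is_a") {
                     paste0("is_a: ", .synth_term_id(parents[k]))
                   } else {
                     paste0("relationship: part_of ", .synth_term_id(parents[k]))
                   })
      }
    }
  }
  lines
}

#' Generate a synthetic ontology
#'
#' A random rooted DAG (chain backbone plus random extra parents) emitted as
#' OBO text and re-read through [read_obo()], so the result is guaranteed to
#' pass the load-time validation. Deterministic per seed.
#'
#' @param spec A [synthetic_spec()].
#' @return An `onto_dag` whose `"obo_lines"` attribute holds the exact OBO
#'   text (see [write_obo()]).
#' @export
make_ontology <- function(spec = synthetic_spec()) {
  lines <- .synth_obo_lines(spec)
  dag <- read_obo(lines)
  attr(dag, "obo_lines") <- lines
  dag
}

#' Write an ontology as OBO
#'
#' Writes the generator's original OBO text when available, otherwise
#' serializes the DAG stanza by stanza.
#'
#' @param dag An `onto_dag`.
#' @param path Output path.
#' @export
write_obo <- function(dag, path) {
  lines <- attr(dag, "obo_lines")
  if (is.null(lines)) {
    lines <- c("format-version: 1.2")
    for (i in seq_len(nrow(dag$terms))) {
      id <- dag$terms$id[i]
      lines <- c(lines, "", "[Term]", paste0("id: ", id),
                 paste0("name: ", dag$terms$name[i]),
                 paste0("namespace: ", dag$terms$namespace[i]),
                 if (dag$terms$obsolete[i]) "is_obsolete: true",
                 paste0("is_a: ", dag$parents[[id]]))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Generate a synthetic interactome
#'
#' A two-block modular graph: within-block edges follow a degree-weighted
#' (Chung-Lu style) random model in which designated positive-class proteins
#' carry `degree_effect` times the weight of negatives, so their mean degree
#' is elevated by that factor; `n_bridges` planted bridge nodes receive edges
#' into both blocks and join them. Deterministic per seed.
#'
#' @param spec A [synthetic_spec()].
#' @return An igraph object with graph attributes `bridges` (planted bridge
#'   node names), `block` (per-vertex block id, aligned to vertex order) and
#'   `positives` (names of the elevated-degree nodes).
#' @export
make_interactome <- function(spec = synthetic_spec()) {
  n <- spec$n_positive + spec$n_negative
  if (n < 10L) stop("need at least 10 proteins", call. = FALSE)
  rng <- .lcg_new(spec$seed + 202L)
  ids <- .synth_protein_id(seq_len(n))
  is_pos <- seq_len(n) <= spec$n_positive
  block <- ifelse(.lcg_bernoulli(rng, 0.5, n), 1L, 2L)
  w <- ifelse(is_pos, spec$mean_degree * spec$degree_effect, spec$mean_degree)
  from <- character(0); to <- character(0)
  for (b in 1:2) {
    members <- which(block == b)
    if (length(members) < 2L) next
    S <- sum(w[members])
    for (ai in seq_along(members)[-length(members)]) {
      i <- members[ai]
      rest <- members[(ai + 1L):length(members)]
      p <- pmin(1, w[i] * w[rest] / S)
      hit <- .lcg_unif(rng, length(rest)) < p
      if (any(hit)) {
        from <- c(from, rep(ids[i], sum(hit)))
        to <- c(to, ids[rest[hit]])
      }
    }
  }
  # planted bridges: the last n_bridges nodes get edges into both blocks
  bridge_idx <- if (spec$n_bridges > 0L) (n - spec$n_bridges + 1L):n else integer(0)
  k_each <- max(3L, ceiling(spec$mean_degree))
  for (i in bridge_idx) {
    for (b in 1:2) {
      members <- setdiff(which(block == b), i)
      take <- members[.lcg_shuffle(rng, length(members))][seq_len(min(k_each, length(members)))]
      from <- c(from, rep(ids[i], length(take)))
      to <- c(to, ids[take])
    }
  }
  g <- read_edge_list(paste(from, to, sep = "\t"), quiet = TRUE)
  # carry isolated proteins too
  iso <- setdiff(ids, igraph::V(g)$name)
  if (length(iso)) g <- igraph::add_vertices(g, length(iso), name = iso)
  g <- igraph::set_graph_attr(g, "bridges", ids[bridge_idx])
  g <- igraph::set_graph_attr(g, "block",
                              block[match(igraph::V(g)$name, ids)])
  g <- igraph::set_graph_attr(g, "positives", ids[is_pos])
  g
}

#' Generate a labelled cohort with planted informative GO features
#'
#' Chooses `n_informative_go` informative and `noise_go` noise terms from the
#' ontology. Informative terms annotate positive-class proteins at rate
#' `base_rate + informative_effect` and negatives at `base_rate`; noise terms
#' annotate both classes at `base_rate`. Degree and bridgeness come from the
#' supplied interactome via [topology_table()]. Deterministic per seed.
#'
#' @param spec A [synthetic_spec()].
#' @param dag Ontology from [make_ontology()].
#' @param graph Interactome from [make_interactome()].
#' @return List with `cohort` (data.frame: `protein_id`, `label`, one 0/1
#'   column per chosen GO term, `degree`, `bridgeness`), `annotations`
#'   (named list protein -> annotated term ids), `informative_terms`,
#'   `noise_terms`.
#' @export
make_cohort <- function(spec = synthetic_spec(), dag = make_ontology(spec),
                        graph = make_interactome(spec)) {
  need <- spec$n_informative_go + spec$noise_go
  if (spec$n_terms < need + 1L) {
    stop("ontology too small for the requested informative + noise terms",
         call. = FALSE)
  }
  rng <- .lcg_new(spec$seed + 303L)
  n <- spec$n_positive + spec$n_negative
  ids <- .synth_protein_id(seq_len(n))
  label <- as.integer(seq_len(n) <= spec$n_positive)
  # deepest terms first, so planted terms are leaves with distinct closures
  pick <- spec$n_terms - seq_len(need) + 1L
  informative <- .synth_term_id(pick[seq_len(spec$n_informative_go)])
  noise <- setdiff(.synth_term_id(pick), informative)

  cols <- list()
  for (t in informative) {
    p <- ifelse(label == 1L, spec$base_rate + spec$informative_effect,
                spec$base_rate)
    cols[[t]] <- as.integer(.lcg_unif(rng, n) < p)
  }
  for (t in noise) {
    cols[[t]] <- as.integer(.lcg_bernoulli(rng, spec$base_rate, n))
  }
  topo <- topology_table(graph, seed = spec$seed)
  idx <- match(ids, topo$protein_id)
  cohort <- data.frame(protein_id = ids, label = label,
                       stringsAsFactors = FALSE, check.names = FALSE)
  for (t in names(cols)) cohort[[t]] <- cols[[t]]
  cohort$degree <- topo$degree[idx]
  cohort$bridgeness <- topo$bridgeness[idx]

  ann_terms <- names(cols)
  annotations <- lapply(seq_len(n), function(i) {
    ann_terms[vapply(cols, `[`, 0L, i) == 1L]
  })
  names(annotations) <- ids
  list(cohort = cohort, annotations = annotations,
       informative_terms = informative, noise_terms = noise)
}

#' Generate a synthetic curated registry
#'
#' Schema-valid curated entries mirroring the curation workflow: `n_entries`
#' translocating proteins of which `n_pathology_only` translocate only under
#' pathological conditions, plus `n_negative` negative-set entries cycled
#' through the five negative categories. Optional fields are populated
#' independently with probability `field_population`, which drives the DCS
#' distribution. Deterministic per seed.
#'
#' @param spec A [synthetic_spec()].
#' @return data.frame with the registry columns.
#' @export
make_curated_registry <- function(spec = synthetic_spec()) {
  rng <- .lcg_new(spec$seed + 404L)
  n_tr <- spec$n_entries
  n_neg <- spec$n_negative
  n <- n_tr + n_neg
  ac <- sprintf("Q%05d", seq_len(n))
  optional <- names(dcs_weights())
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    translocating <- i <= n_tr
    locs <- MAJOR_LOCALIZATIONS[.lcg_shuffle(rng, 6L)[1:2]]
    e <- stats::setNames(as.list(rep(NA_character_, length(REGISTRY_COLUMNS))),
                         REGISTRY_COLUMNS)
    e$uniprot_ac <- ac[i]
    e$gene_name <- sprintf("SYN%04d", i)
    e$protein_names <- sprintf("Synthetic protein %d", i)
    e$initial_localization <- locs[1]
    if (translocating) {
      e$target_localization <- locs[2]
      e$pathology_only <- i <= spec$n_pathology_only
      e$negative_category <- NA_character_
    } else {
      e$target_localization <- NA_character_
      e$pathology_only <- FALSE
      e$negative_category <- NEGATIVE_CATEGORIES[((i - n_tr - 1L) %% 5L) + 1L]
    }
    fill <- .lcg_bernoulli(rng, spec$field_population, length(optional))
    for (k in seq_along(optional)) {
      if (fill[k]) {
        e[[optional[k]]] <- switch(optional[k],
          pubmed_ids = paste(10000000L + .lcg_int(rng, 9999999L, 2L),
                             collapse = ";"),
          pathways = sprintf("hsa%05d", .lcg_int(rng, 5000L)),
          initial_localization_minor = sprintf("minor_%d", .lcg_int(rng, 20L)),
          target_localization_minor = sprintf("minor_%d", .lcg_int(rng, 20L)),
          sprintf("%s of entry %d", optional[k], i))
      }
    }
    rows[[i]] <- as.data.frame(e, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$pathology_only <- as.logical(out$pathology_only)
  rownames(out) <- NULL
  out
}

#' Write an annotation table
#'
#' Two-column TSV `protein_id<TAB>go_id`, one pair per row.
#'
#' @param annotations Named list protein id -> term ids.
#' @param path Output path.
#' @export
write_annotations <- function(annotations, path) {
  prot <- rep(names(annotations), lengths(annotations))
  term <- unlist(annotations, use.names = FALSE)
  writeLines(paste(prot, term, sep = "\t"), path)
  invisible(path)
}

#' Write an interactome edge list
#'
#' @param graph An igraph object.
#' @param path Output TSV path.
#' @export
write_edge_list <- function(graph, path) {
  el <- igraph::as_edgelist(graph)
  writeLines(c("interactor_a\tinteractor_b",
               if (nrow(el)) paste(el[, 1], el[, 2], sep = "\t")), path)
  invisible(path)
}

#' Write / read a labelled cohort
#'
#' TSV feature matrix with `protein_id`, `label` and one column per feature.
#'
#' @param cohort Cohort data.frame (see [make_cohort()]).
#' @param path File path.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    na.strings = "", check.names = FALSE)
}
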