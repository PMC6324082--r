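# Independent brute-force oracles used by the correctness suites. These are
# deliberately naive implementations kept separate from the package's own
# code paths.

# Transitive ancestors by plain recursive DFS over the parent lists.
oracle_closure <- function(dag, terms) {
  seen <- character(0)
  visit <- function(t) {
    if (t %in% seen) return(invisible())
    seen <<- c(seen, t)
    for (p in dag$parents[[t]]) visit(p)
  }
  for (t in terms) visit(t)
  obsolete <- dag$terms$id[dag$terms$obsolete]
  sort(setdiff(seen, obsolete))
}

# Connected components by label flooding over an edge matrix.
oracle_components <- function(edges, nodes) {
  comp <- stats::setNames(seq_along(nodes), nodes)
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(edges))) {
      a <- edges[i, 1]; b <- edges[i, 2]
      m <- min(comp[[a]], comp[[b]])
      if (comp[[a]] != m || comp[[b]] != m) {
        comp[[a]] <- m; comp[[b]] <- m; changed <- TRUE
      }
    }
    if (!changed) break
  }
  split(names(comp), comp)
}

# F1 of "positive iff score >= t" by direct confusion-matrix counting.
oracle_f1_at <- function(t, scores, labels) {
  pred <- as.integer(scores >= t)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  rec <- tp / sum(labels == 1)
  if (is.na(prec) || prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
}

# Best F1 over a dense 0.001-step threshold grid spanning the score range.
oracle_f1_grid <- function(scores, labels) {
  grid <- seq(min(scores) - 0.001, max(scores) + 0.001, by = 0.001)
  max(vapply(grid, oracle_f1_at, numeric(1), scores = scores,
             labels = labels))
}

# Raw weighted-sum score by an explicit element loop.
oracle_weighted_sum <- function(x, weights) {
  total <- 0
  for (i in seq_along(x)) total <- total + weights[i] * x[i]
  total
}

# The 9-node barbell: two 4-cliques each fully joined to a shared cut vertex.
barbell_graph <- function() {
  a <- paste0("a", 1:4); b <- paste0("b", 1:4)
  edges <- character(0)
  for (s in list(a, b)) {
    for (i in 1:3) for (j in (i + 1):4) edges <- c(edges, s[i], s[j])
  }
  for (x in c(a, b)) edges <- c(edges, "v", x)
  igraph::make_graph(edges, directed = FALSE)
}

# Tiny OBO fixtures assembled in code.
obo_chain3 <- c(
  "format-version: 1.2", "",
  "[Term]", "id: GO:0000003", "name: C", "namespace: biological_process", "",
  "[Term]", "id: GO:0000002", "name: B", "namespace: biological_process",
  "is_a: GO:0000003", "",
  "[Term]", "id: GO:0000001", "name: A", "namespace: biological_process",
  "is_a: GO:0000002")

# A schema-valid translocating curated entry.
valid_entry <- function(...) {
  e <- list(uniprot_ac = "P12345", gene_name = "GENE1",
            protein_names = "Protein one", pubmed_ids = "12345678",
            initial_localization = "cytoplasm",
            initial_localization_minor = NA_character_,
            target_localization = "nucleus",
            target_localization_minor = NA_character_,
            partners_initial = "P00001", partners_target = "P00002",
            functions_initial = "kinase", functions_target = "scaffold",
            mechanism = "phosphorylation-gated import",
            detection_method = "immunofluorescence",
            structural_info = "NLS at N-terminus",
            disease_group = "cancer", disease = "carcinoma",
            pathological_role = "driver", pathways = "hsa04110",
            pathology_only = FALSE, negative_category = NA_character_)
  utils::modifyList(e, list(...))
}
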