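test_that("generators are deterministic per seed", {
  spec <- synthetic_spec(seed = 21, n_terms = 25, n_positive = 40,
                         n_negative = 30, noise_go = 5)
  expect_identical(attr(make_ontology(spec), "obo_lines"),
                   attr(make_ontology(spec), "obo_lines"))
  g1 <- make_interactome(spec); g2 <- make_interactome(spec)
  expect_identical(igraph::as_edgelist(g1), igraph::as_edgelist(g2))
  c1 <- make_cohort(spec, make_ontology(spec), g1)
  c2 <- make_cohort(spec, make_ontology(spec), g2)
  expect_identical(c1$cohort, c2$cohort)
  expect_identical(make_curated_registry(spec), make_curated_registry(spec))
  # a different seed changes the draw
  g3 <- make_interactome(synthetic_spec(seed = 22, n_terms = 25,
                                        n_positive = 40, n_negative = 30))
  expect_false(identical(igraph::as_edgelist(g1), igraph::as_edgelist(g3)))
})

test_that("a three-term ontology is a chain and larger DAGs validate acyclic", {
  dag3 <- make_ontology(synthetic_spec(seed = 1, n_terms = 3))
  expect_equal(nrow(dag3$terms), 3)
  expect_equal(unname(lengths(dag3$parents[dag3$terms$id])), c(0L, 1L, 1L))
  expect_equal(ancestor_closure(dag3, "GO:0000003"), dag3$terms$id)

  # load-time validation (read_obo) accepts a 100-term generated DAG
  dag100 <- make_ontology(synthetic_spec(seed = 6, n_terms = 100))
  expect_equal(nrow(dag100$terms), 100)
  expect_setequal(unique(dag100$terms$namespace),
                  c("cellular_component", "biological_process",
                    "molecular_function"))
})

test_that("planted degree contrast matches the requested effect size", {
  spec <- synthetic_spec(seed = 8, degree_effect = 2)
  g <- make_interactome(spec)
  topo <- topology_table(g, seed = 8)
  pos <- igraph::graph_attr(g, "positives")
  bridges <- igraph::graph_attr(g, "bridges")
  use <- !(topo$protein_id %in% bridges)
  ratio <- mean(topo$degree[use & topo$protein_id %in% pos]) /
    mean(topo$degree[use & !topo$protein_id %in% pos])
  expect_gt(ratio, 1.6)
  expect_lt(ratio, 2.4)
})

test_that("a unit degree effect plants no degree signal", {
  pvals <- vapply(1:20, function(s) {
    spec <- synthetic_spec(seed = 100 + s, degree_effect = 1,
                           n_positive = 60, n_negative = 60, n_bridges = 0)
    g <- make_interactome(spec)
    topo <- topology_table(g, seed = s)
    pos <- topo$protein_id %in% igraph::graph_attr(g, "positives")
    suppressWarnings(stats::wilcox.test(topo$degree[pos],
                                        topo$degree[!pos])$p.value)
  }, numeric(1))
  expect_gte(sum(pvals > 0.01), 18)
})

test_that("planted bridge nodes land in the bridgeness top decile", {
  spec <- synthetic_spec(seed = 3)
  g <- make_interactome(spec)
  gc <- giant_component(g)
  br <- bridgeness(gc, seed = 3)
  bridges <- intersect(igraph::graph_attr(g, "bridges"), names(br))
  expect_gt(length(bridges), 0)
  expect_true(all(rank(-br)[bridges] <= length(br) / 10))
})

test_that("cohorts have the declared size and a null effect gives chance AUC", {
  spec <- synthetic_spec(seed = 14, n_positive = 50, n_negative = 40,
                         noise_go = 6)
  syn <- make_cohort(spec, make_ontology(spec), make_interactome(spec))
  expect_equal(nrow(syn$cohort), 90)
  expect_equal(sum(syn$cohort$label), 50)
  expect_length(syn$informative_terms, spec$n_informative_go)

  # zero informative effect and no degree contrast: held-out AUC is chance
  null_spec <- synthetic_spec(seed = 15, informative_effect = 0,
                              degree_effect = 1, n_positive = 60,
                              n_negative = 60, noise_go = 6, n_bridges = 0)
  null <- make_cohort(null_spec, make_ontology(null_spec),
                      make_interactome(null_spec))
  cv <- cross_validate(null$cohort,
                       training_config(repeats = 25, seed = 15,
                                       nrounds = 40))
  expect_gt(unname(cv$summary["mean"]), 0.40)
  expect_lt(unname(cv$summary["mean"]), 0.60)
})

test_that("generated files round-trip through the package's own readers", {
  spec <- synthetic_spec(seed = 31, n_terms = 20, n_positive = 25,
                         n_negative = 20, noise_go = 4, n_entries = 10,
                         n_pathology_only = 2, n_bridges = 1)
  dag <- make_ontology(spec)
  g <- make_interactome(spec)
  syn <- make_cohort(spec, dag, g)
  dir <- tempfile(); dir.create(dir)

  obo <- file.path(dir, "o.obo")
  write_obo(dag, obo)
  dag2 <- read_obo(obo)
  expect_equal(dag2$terms, dag$terms)
  expect_equal(dag2$parents, dag$parents)

  edges <- file.path(dir, "e.tsv")
  write_edge_list(g, edges)
  g2 <- read_edge_list(edges, quiet = TRUE)
  expect_equal(igraph::ecount(g2), igraph::ecount(g))

  ann <- file.path(dir, "a.tsv")
  write_annotations(syn$annotations, ann)
  back <- read_annotations(ann)
  nonempty <- names(syn$annotations)[lengths(syn$annotations) > 0]
  expect_setequal(names(back), nonempty)
  for (p in nonempty[1:5]) expect_setequal(back[[p]], syn$annotations[[p]])

  coh <- file.path(dir, "c.tsv")
  write_cohort(syn$cohort, coh)
  expect_equal(read_cohort(coh), syn$cohort, ignore_attr = TRUE)
})
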