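test_that("the packaged model has the published shape and weights", {
  for (variant in c("high_precision", "published")) {
    w <- tes_weights(variant)
    expect_equal(nrow(w), 19)
    expect_equal(sum(w$kind == "go_term"), 15)
    expect_setequal(w$threshold[w$kind == "degree_below"], c(14.5, 62.5))
    expect_setequal(w$threshold[w$kind == "bridgeness_below"],
                    c(2.5e-06, 0.000292))
    expect_false(anyDuplicated(w$feature_id) > 0)
  }
  hp <- tes_weights("high_precision")
  expect_equal(hp$weight[hp$feature_id == "GO:0009887"], 2.675)
  expect_equal(hp$weight[hp$feature_id == "GO:0005737"], 1.353)
  expect_equal(hp$weight[hp$feature_id == "degree_below_62.5"], -0.497)
})

test_that("binarization follows the indicator semantics with unknowns as false", {
  w <- tes_weights()
  # a hub with 20 neighbours, two GO terms, no bridgeness record
  pa <- protein_features("A", go_terms = c("GO:0009887", "GO:0005737"),
                         degree = 20)
  x <- binarize_features(pa, w)
  expect_setequal(names(x)[x == 1],
                  c("GO:0009887", "GO:0005737", "degree_below_62.5"))

  # nothing annotated, high degree: all indicators false
  expect_true(all(binarize_features(protein_features("B", degree = 100), w) == 0))

  # degree indicators are cumulative: 10 < 14.5 < 62.5
  x10 <- binarize_features(protein_features("C", degree = 10), w)
  expect_equal(unname(x10[c("degree_below_14.5", "degree_below_62.5")]),
               c(1L, 1L))

  # a defined bridgeness of 0 activates both bridgeness indicators
  xb <- binarize_features(protein_features("D", degree = 100, bridgeness = 0), w)
  expect_equal(sum(xb), 2L)
})

test_that("raw_tes reproduces the worked hub example and the empty sum", {
  w <- tes_weights()
  pa <- protein_features("A", go_terms = c("GO:0009887", "GO:0005737"),
                         degree = 20)
  expect_equal(raw_tes(binarize_features(pa, w), w), 3.531)
  expect_identical(raw_tes(binarize_features(pa, w), w),
                   -0.497 + 2.675 + 1.353)
  expect_equal(raw_tes(rep(0L, 19), w), 0)
  expect_error(raw_tes(rep(0L, 5), w), "length")

  # all nine positively weighted GO terms active, nothing else (2-decimal table)
  pub <- tes_weights("published")
  x <- as.integer(pub$kind == "go_term" & pub$weight > 0)
  expect_equal(raw_tes(x, pub), 9.95)
  expect_equal(raw_tes(x, pub), oracle_weighted_sum(x, pub$weight))
})

test_that("raw_tes equals brute-force summation on all 2^7 indicator subsets", {
  tab <- data.frame(
    feature_id = paste0("f", 1:7), kind = "go_term",
    term = paste0("GO:000000", 1:7), threshold = NA_real_,
    weight = c(2.5, -1.1, 0.4, -0.3, 1.7, -2.2, 0.05))
  for (mask in 0:127) {
    x <- as.integer(intToBits(mask)[1:7])
    expect_equal(raw_tes(x, tab), oracle_weighted_sum(x, tab$weight))
  }
})

test_that("activating features moves raw_tes in the direction of their sign", {
  w <- tes_weights()
  x <- rep(0L, 19)
  for (i in seq_len(19)) {
    xi <- x; xi[i] <- 1L
    if (w$weight[i] > 0) {
      expect_gt(raw_tes(xi, w), raw_tes(x, w))
    } else {
      expect_lt(raw_tes(xi, w), raw_tes(x, w))
    }
  }
})

test_that("min-max normalization maps extremes to 0/1 and is affine-invariant", {
  expect_equal(normalize_tes(c(1, 2, 3)), c(0, 0.5, 1))
  raw <- c(-2.1, 0.3, 1.7, 3.531, 0.9)
  expect_equal(normalize_tes(raw), normalize_tes(3.2 * raw + 11))
  expect_error(normalize_tes(c(2, 2, 2)), "degenerate")
  # frozen reference range clips new values into [0, 1]
  expect_equal(normalize_tes(c(-1, 0, 5, 10), reference = c(0, 5)),
               c(0, 0, 1, 1))
})

test_that("classification partitions scores with boundaries in low_confidence", {
  expect_equal(as.character(classify_tes(0.9807)), "high_confidence")
  expect_equal(as.character(classify_tes(0.50)), "low_confidence")
  expect_equal(as.character(classify_tes(0.10)), "non_translocating")
  expect_equal(as.character(classify_tes(c(0.4487, 0.6167))),
               rep("low_confidence", 2))
  expect_error(classify_tes(0.5, lower = 0.7, upper = 0.6), "lower < upper")
  expect_error(classify_tes(1.5), "\\[0, 1\\]")
})

test_that("score_cohort runs the full pipeline in input order", {
  w <- tes_weights()
  feats <- list(
    protein_features("low", degree = 5),                       # many negatives
    protein_features("mid", go_terms = c("GO:0005829", "GO:0005737",
                                         "GO:0048523"), degree = 20),
    protein_features("top", go_terms = c("GO:0009887", "GO:0006109",
                                         "GO:0005737"), degree = 100))
  res <- score_cohort(feats, w)
  expect_equal(res$protein_id, c("low", "mid", "top"))
  expect_equal(res$tes[res$protein_id == "top"], 1)
  expect_equal(res$tes[res$protein_id == "low"], 0)
  expect_equal(as.character(res$class),
               c("non_translocating", "low_confidence", "high_confidence"))
  expect_equal(sum(table(res$class)), nrow(res))

  # the synthetic training cohort scores end to end
  spec <- synthetic_spec(seed = 11)
  syn <- make_cohort(spec, make_ontology(spec), make_interactome(spec))
  ff <- data.frame(protein_id = syn$cohort$protein_id,
                   degree = syn$cohort$degree,
                   bridgeness = syn$cohort$bridgeness,
                   go_terms = vapply(syn$annotations,
                                     paste, "", collapse = ";")[syn$cohort$protein_id])
  res2 <- score_cohort(ff, w)
  expect_equal(nrow(res2), spec$n_positive + spec$n_negative)
  expect_false(anyNA(res2$raw_tes))
  expect_false(anyNA(res2$tes))
  expect_false(anyNA(res2$class))
  expect_true(all(res2$tes >= 0 & res2$tes <= 1))
  expect_equal(max(res2$tes), 1)
  expect_equal(min(res2$tes), 0)
})
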