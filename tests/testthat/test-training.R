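test_that("stump fitting recovers a planted signal deterministically", {
  spec <- synthetic_spec(seed = 5, n_positive = 80, n_negative = 70,
                         noise_go = 8)
  syn <- make_cohort(spec, make_ontology(spec), make_interactome(spec))
  ens <- fit_stump_ensemble(syn$cohort)
  expect_s3_class(ens, "stump_ensemble")
  expect_true(all(c("feature", "split", "left", "right") %in% names(ens$trees)))
  # planted informative terms dominate the gain importance over noise terms
  gi <- ens$gain_importance
  expect_gt(min(gi[syn$informative_terms]), max(gi[syn$noise_terms]))
  # planted terms are positively associated with the label
  expect_true(all(ens$importance[syn$informative_terms] > 0))
  # same data, same config: identical ensembles
  ens2 <- fit_stump_ensemble(syn$cohort)
  expect_identical(ens$trees, ens2$trees)
  expect_identical(ens$importance, ens2$importance)

  one_class <- syn$cohort; one_class$label <- 1L
  expect_error(fit_stump_ensemble(one_class), "both classes")
})

test_that("a feature equal to the label receives the dominant importance", {
  n <- 100
  cohort <- data.frame(label = rep(0:1, n / 2),
                       signal = rep(0:1, n / 2),
                       junk1 = rep(c(0, 1, 1, 0), n / 4),
                       junk2 = seq_len(n) %% 3)
  ens <- fit_stump_ensemble(cohort, training_config(nrounds = 50))
  expect_equal(names(which.max(ens$gain_importance)), "signal")
  expect_gt(ens$gain_importance["signal"], 0.9)
  pred <- predict(ens, cohort[, -1], type = "response")
  expect_true(all((pred > 0.5) == (cohort$label == 1)))
})

test_that("the stump booster matches an external gradient-boosting engine", {
  skip_if_not_installed("xgboost")
  spec <- synthetic_spec(seed = 5, n_positive = 80, n_negative = 70,
                         noise_go = 8)
  syn <- make_cohort(spec, make_ontology(spec), make_interactome(spec))
  X <- as.matrix(syn$cohort[, !(names(syn$cohort) %in%
                                  c("protein_id", "label"))])
  y <- syn$cohort$label
  ens <- fit_stump_ensemble(syn$cohort, training_config(nrounds = 50))
  dm <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
  bst <- xgboost::xgb.train(
    params = list(max_depth = 1, eta = 0.3, lambda = 1,
                  min_child_weight = 0, objective = "binary:logistic",
                  base_score = 0.5, nthread = 1),
    data = dm, nrounds = 50)
  expect_equal(predict(ens, X),
               predict(bst, dm, outputmargin = TRUE),
               tolerance = 1e-5, ignore_attr = TRUE)
})

test_that("select_features applies a strict importance filter", {
  expect_setequal(select_features(c(a = 0.5, b = 0.01, c = 0.03)), c("a", "c"))
  expect_setequal(select_features(c(a = 0.02, b = 0.021)), "b")  # strict >
  expect_length(select_features(stats::setNames(numeric(0), character(0))), 0)
  # negative leaf-sum importances select on magnitude
  expect_setequal(select_features(c(a = -0.5, b = 0.001)), "a")
})

test_that("cross_validate reports one AUC per repeat and handles edge cohorts", {
  sep <- data.frame(label = rep(0:1, each = 25), x = rep(0:1, each = 25))
  cv <- cross_validate(sep, training_config(repeats = 10, seed = 1,
                                            nrounds = 20))
  expect_length(cv$auc, 10)
  expect_equal(cv$auc, rep(1, 10))          # perfectly separable
  expect_equal(unname(cv$summary["mean"]), 1)

  expect_error(cross_validate(data.frame(label = c(0, 1), x = c(0, 1)),
                              training_config(folds = 5)),
               "stratify|smaller")

  # per-run curves are computed on pooled held-out predictions
  cvc <- cross_validate(sep, training_config(repeats = 2, seed = 1,
                                             nrounds = 10), curves = TRUE)
  expect_length(cvc$curves, 2)
  expect_true(all(c("recall", "precision", "fallout", "f1", "mcc") %in%
                    names(cvc$curves[[1]])))
})

test_that("fold assignment is stratified and re-randomized per repeat", {
  y <- c(rep(1L, 30), rep(0L, 20))
  rng <- transloc:::.lcg_new(42)
  f1 <- transloc:::.stratified_folds(y, 5, rng)
  f2 <- transloc:::.stratified_folds(y, 5, rng)
  expect_false(identical(f1, f2))
  for (f in list(f1, f2)) {
    tab <- table(f, y)
    expect_true(all(tab[, "1"] == 6))
    expect_true(all(tab[, "0"] == 4))
  }
})

test_that("the internal AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(9)
  for (i in 1:5) {
    labels <- rbinom(60, 1, 0.4)
    if (length(unique(labels)) < 2) next
    scores <- rnorm(60) + labels
    expect_equal(transloc:::.auc(scores, labels),
                 as.numeric(pROC::auc(pROC::roc(labels, scores,
                                                quiet = TRUE,
                                                direction = "<"))),
                 tolerance = 1e-10)
  }
})

test_that("f1_threshold_scan brute-forces the observed-score candidates", {
  scan <- f1_threshold_scan(c(0.9, 0.8, 0.1), c(1, 1, 0))
  expect_equal(scan$threshold, 0.8)
  expect_equal(scan$f1, 1)
  # separable scores always admit a perfect F1
  scan2 <- f1_threshold_scan(c(5, 4, 3, 2, 1), c(1, 1, 1, 0, 0))
  expect_equal(scan2$f1, 1)
  expect_error(f1_threshold_scan(c(1, 2), c(1, 1)), "both classes")
  # ties resolve to the smallest optimal threshold
  scan3 <- f1_threshold_scan(c(0.2, 0.4, 0.6, 0.8), c(0, 1, 1, 1))
  expect_equal(scan3$threshold, 0.4)
})

test_that("the F1 optimum matches a dense-grid oracle and is rank-invariant", {
  set.seed(17)
  for (i in 1:40) {
    n <- 30
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    scores <- round(runif(n), 3)
    scan <- f1_threshold_scan(scores, labels)
    expect_equal(scan$f1, oracle_f1_grid(scores, labels), tolerance = 1e-12)
    # strictly monotone transform of scores transforms the optimum with it
    scan_t <- f1_threshold_scan(exp(2 * scores), labels)
    expect_equal(scan_t$threshold, exp(2 * scan$threshold))
    expect_equal(scan_t$f1, scan$f1)
  }
})

test_that("high_confidence_cutoff is the top negative score, blind to positives", {
  expect_equal(high_confidence_cutoff(c(0.1, 0.3, 0.6167)), 0.6167)
  expect_equal(high_confidence_cutoff(0.2), 0.2)
  expect_error(high_confidence_cutoff(numeric(0)), "negative-set")
  # invariant to whatever the positives score
  scores <- c(0.95, 0.9, 0.55, 0.4, 0.2)
  labels <- c(1, 1, 0, 0, 1)
  expect_equal(high_confidence_cutoff(scores[labels == 0]), 0.55)
})

test_that("as_weight_table expands stumps into scoreable indicator features", {
  spec <- synthetic_spec(seed = 13, n_positive = 60, n_negative = 50,
                         noise_go = 5)
  syn <- make_cohort(spec, make_ontology(spec), make_interactome(spec))
  ens <- fit_stump_ensemble(syn$cohort, training_config(nrounds = 40))
  tab <- as_weight_table(ens)
  expect_true(all(tab$kind %in% c("go_term", "degree_below",
                                  "bridgeness_below")))
  expect_false(anyDuplicated(tab$feature_id) > 0)
  # GO-term weights carry the ensemble's signed leaf-sum importance
  for (t in intersect(tab$term, syn$informative_terms)) {
    expect_equal(tab$weight[match(t, tab$term)],
                 unname(ens$importance[t]), tolerance = 1e-12)
  }
  # the expanded table scores a protein identically to the ensemble margin
  # difference (up to base), for a protein with all indicators false
  x0 <- rep(0L, nrow(tab))
  expect_equal(raw_tes(x0, tab), 0)
})
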