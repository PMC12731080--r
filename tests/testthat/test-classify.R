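# Hierarchical two-stage classification: specs, hierarchy contract,
# determinism and backend behaviour on small separable data.

make_features <- function(noise = noise_model(), n_sessions = 2,
                          base_seed = 30L) {
  ds <- mini_dataset(n_sessions = n_sessions, base_seed = base_seed,
                     noise = noise)
  extract_features(ds, "TB", include_euler = TRUE)
}

test_that("classifier specs carry the stage-specific defaults", {
  expect_equal(classifier_spec("KNN", "S1")$hyperparams$k, 5L)
  expect_equal(classifier_spec("KNN", "S2")$hyperparams$k, 9L)
  expect_equal(classifier_spec("RF", "S1")$hyperparams$num_trees, 310L)
  ab1 <- classifier_spec("ADABOOST", "S1")
  ab2 <- classifier_spec("ADABOOST", "S2")
  expect_equal(ab1$hyperparams$iterations, 150L)
  expect_equal(ab2$hyperparams$iterations, 200L)
  expect_equal(ab1$hyperparams$max_splits, 250L)
  expect_equal(classifier_spec("KNN", "S2", k = 3)$hyperparams$k, 3)
  expect_error(classifier_spec("SVM", "S1", k = 3), "unknown hyperparameter")
})

test_that("hierarchy contract: stage-1 transitions always map to label 0", {
  fe <- make_features()
  model <- fit_hierarchical(fe, seed = 1L)
  pred <- predict(model, fe)
  expect_true(all(pred$.pred[pred$.pred_stage1 == "transition"] == 0L))
  expect_true(all(pred$.pred[pred$.pred_stage1 == "brushing"] ==
                    pred$.pred_region[pred$.pred_stage1 == "brushing"]))
  expect_true(all(pred$.pred %in% 0:18))
})

test_that("fit refuses degenerate training labels and mismatched schemas", {
  fe <- make_features()
  only_trans <- fe[fe$window_label == 0, ]
  attr(only_trans, "schema") <- attr(fe, "schema")
  expect_error(fit_hierarchical(only_trans), "transition")
  model <- fit_hierarchical(fe, seed = 1L)
  wrong <- extract_features(
    mini_dataset(n_sessions = 2, base_seed = 31L), "TB", include_euler = FALSE
  )
  expect_error(predict(model, wrong), "schema mismatch")
})

test_that("refitting with the same seed reproduces predictions exactly", {
  fe <- make_features()
  for (fam in c("RF", "KNN", "ADABOOST")) {
    spec1 <- classifier_spec(fam, "S1")
    spec2 <- classifier_spec(fam, "S2")
    if (fam == "ADABOOST") { # keep the slow family quick
      spec1$hyperparams$iterations <- 10L
      spec2$hyperparams$iterations <- 10L
    }
    m1 <- fit_hierarchical(fe, spec1, spec2, seed = 7L)
    m2 <- fit_hierarchical(fe, spec1, spec2, seed = 7L)
    expect_identical(predict(m1, fe)$.pred, predict(m2, fe)$.pred,
                     info = fam)
  }
})

test_that("every family separates the noise-free regime (>= 99% raw windows)", {
  # full scripted protocol, zero sensor noise, no between-session
  # perturbation: the separable regime in which raw window predictions must
  # equal ground truth except possibly at windows straddling a label change
  ds <- generate_dataset(n_sessions = 2, base_seed = 40L, noise = noise_free(),
                         anchor_jitter_sd = 0, freq_jitter = 0)
  fe <- extract_features(ds, "TB", include_euler = TRUE)
  train <- fe[fe$session_id == "S01", ]
  test <- fe[fe$session_id == "S02", ]
  attr(train, "schema") <- attr(fe, "schema")
  attr(test, "schema") <- attr(fe, "schema")
  runs <- rle(test$window_label)
  ends <- cumsum(runs$lengths)
  boundary <- sort(unique(pmax(pmin(c(ends, ends + 1L), nrow(test)), 1L)))
  interior <- setdiff(seq_len(nrow(test)), boundary)
  for (fam in c("SVM", "NB", "KNN", "DT", "RF", "ADABOOST")) {
    spec1 <- classifier_spec(fam, "S1")
    spec2 <- classifier_spec(fam, "S2")
    if (fam == "ADABOOST") {
      spec1$hyperparams$iterations <- 20L
      spec2$hyperparams$iterations <- 20L
    }
    model <- fit_hierarchical(train, spec1, spec2, seed = 3L)
    pred <- predict(model, test)
    acc_interior <- mean(pred$.pred[interior] == pred$window_label[interior])
    expect_gte(acc_interior, 0.99)
    expect_gte(mean(pred$.pred == pred$window_label), 0.95)
  }
})

test_that("empty feature matrices give empty predictions", {
  fe <- make_features()
  model <- fit_hierarchical(fe, seed = 1L)
  empty <- fe[0, ]
  attr(empty, "schema") <- attr(fe, "schema")
  pred <- predict(model, empty)
  expect_equal(nrow(pred), 0L)
  expect_true(all(c(".pred_stage1", ".pred_region", ".pred") %in% names(pred)))
})

test_that("the SAMME booster matches a reference AdaBoost on a toy problem", {
  # diagonal class boundary in 2-D: a single axis-aligned stump is weak
  # (~75-80%), a boosted stump ensemble approximates the diagonal; reference
  # = explicit re-derivation of the SAMME weight-update recurrence on the
  # fitted stumps
  set.seed(88)
  n <- 200
  x <- cbind(runif(n), runif(n))
  y <- factor(ifelse(x[, 1] + x[, 2] > 1, "a", "b"))
  single <- brushtrack:::fit_samme(x, y, iterations = 1, max_splits = 1)
  fit <- brushtrack:::fit_samme(x, y, iterations = 40, max_splits = 1)
  pred <- brushtrack:::predict_samme(fit, x)
  expect_gt(mean(pred == y), 0.95)
  expect_gt(mean(pred == y), mean(brushtrack:::predict_samme(single, x) == y))
  # weights/alphas satisfy the SAMME recurrence for the trees actually fitted
  w <- rep(1 / n, n)
  K <- nlevels(y)
  for (m in seq_along(fit$learners)) {
    pm <- factor(brushtrack:::predict_rpart_df(fit$learners[[m]], x),
                 levels = levels(y))
    err <- sum(w[pm != y])
    if (err > 1e-12) {
      alpha <- log((1 - err) / err) + log(K - 1)
      expect_equal(fit$alphas[m], alpha)
      w <- w * exp(alpha * (pm != y))
      w <- w / sum(w)
    }
  }
  # the split cap is honoured
  splits <- vapply(fit$learners, function(t) sum(t$frame$var != "<leaf>"), numeric(1))
  expect_true(all(splits <= 1))
})
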