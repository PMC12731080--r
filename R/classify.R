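# Two-stage hierarchical classification: stage 1 separates brushing from
# transition windows, stage 2 assigns one of the 18 dental regions to windows
# stage 1 calls brushing. Six classifier families are supported with the
# stage-specific defaults used throughout the package.

FAMILIES <- c("SVM", "NB", "KNN", "DT", "RF", "ADABOOST")

#' Classifier specification
#'
#' Family plus stage-specific hyperparameter defaults: linear-kernel SVM;
#' Gaussian naive Bayes; k-NN with k = 5 (stage 1) or k = 9 (stage 2);
#' decision tree with default controls; random forest with 310 trees;
#' AdaBoost (multiclass SAMME over decision-tree weak learners) with at most
#' 250 splits per tree and 150 (stage 1) or 200 (stage 2) boosting
#' iterations.
#'
#' @param family One of `"SVM"`, `"NB"`, `"KNN"`, `"DT"`, `"RF"`,
#'   `"ADABOOST"`.
#' @param stage `"S1"` (brushing/transition) or `"S2"` (18 regions).
#' @param ... Hyperparameter overrides: `k` (KNN), `num_trees` (RF),
#'   `iterations` and `max_splits` (ADABOOST), `cost` (SVM).
#' @return A `classifier_spec` list.
#' @export
classifier_spec <- function(family = c("RF", "SVM", "NB", "KNN", "DT", "ADABOOST"),
                            stage = c("S1", "S2"), ...) {
  family <- match.arg(family)
  stage <- match.arg(stage)
  hp <- switch(family,
    SVM = list(cost = 1),
    NB = list(),
    KNN = list(k = if (stage == "S1") 5L else 9L),
    DT = list(),
    RF = list(num_trees = 310L),
    ADABOOST = list(max_splits = 250L, iterations = if (stage == "S1") 150L else 200L)
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(hp))
  if (length(unknown)) {
    stop("unknown hyperparameter(s) for ", family, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  hp[names(dots)] <- dots
  structure(list(family = family, stage = stage, hyperparams = hp),
            class = "classifier_spec")
}

# Does this family want z-scored inputs by default? Distance- and
# margin-based learners do; tree ensembles are scale-invariant.
wants_standardization <- function(family) family %in% c("SVM", "KNN", "NB")

fit_scaler <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  # constant features (including constant-up-to-float-dust) are left centred
  # rather than having their rounding noise amplified to unit variance
  degen <- !is.finite(sd) | sd <= 1e-10 * pmax(abs(mu), 1)
  sd[degen] <- 1
  list(mean = mu, sd = sd)
}

apply_scaler <- function(x, scaler) {
  if (is.null(scaler)) return(x)
  sweep(sweep(x, 2, scaler$mean), 2, scaler$sd, "/")
}

# --- single-stage backends ---------------------------------------------------

fit_single <- function(spec, x, y, seed, standardize = NULL) {
  y <- droplevels(factor(y))
  if (nlevels(y) < 2) stop("single-class training set", call. = FALSE)
  if (is.null(standardize)) standardize <- wants_standardization(spec$family)
  scaler <- if (standardize) fit_scaler(x) else NULL
  xs <- apply_scaler(x, scaler)
  set.seed(seed)
  hp <- spec$hyperparams
  fit <- switch(spec$family,
    SVM = e1071::svm(xs, y, kernel = "linear", cost = hp$cost, scale = FALSE),
    NB = fit_nb(xs, y),
    KNN = list(train = xs, cl = y, k = hp$k),
    # fully grown, unpruned CART (the default of this field's reference
    # decision-tree implementations; rpart's cp pruning underfits 18 classes)
    DT = fit_rpart_df(xs, y, rpart::rpart.control(cp = 0, minsplit = 2,
                                                  minbucket = 1, xval = 0)),
    RF = ranger::ranger(
      x = as.data.frame(xs), y = y, num.trees = hp$num_trees,
      seed = seed, num.threads = 1
    ),
    ADABOOST = fit_samme(xs, y, iterations = hp$iterations,
                         max_splits = hp$max_splits)
  )
  structure(
    list(spec = spec, fit = fit, scaler = scaler, levels = levels(y), seed = seed),
    class = "single_stage_fit"
  )
}

predict_single <- function(model, x) {
  xs <- apply_scaler(x, model$scaler)
  fit <- model$fit
  out <- switch(model$spec$family,
    SVM = as.character(stats::predict(fit, xs)),
    NB = predict_nb(fit, xs),
    KNN = {
      # class::knn breaks exact vote ties at random; re-seed for determinism
      set.seed(model$seed)
      as.character(class::knn(fit$train, xs, fit$cl, k = fit$k))
    },
    DT = predict_rpart_df(fit, xs),
    RF = as.character(stats::predict(fit, data = as.data.frame(xs),
                                     num.threads = 1)$predictions),
    ADABOOST = predict_samme(fit, xs)
  )
  factor(out, levels = model$levels)
}

# rpart on a feature matrix, with syntactic-name bookkeeping. Values are
# snapped to 12 significant digits first: columns that are constant up to
# float dust otherwise derail rpart's split search (a near-tied column can
# terminate a node before informative variables are considered).
fit_rpart_df <- function(x, y, control, weights = NULL) {
  df <- as.data.frame(signif(x, 12))
  names(df) <- paste0("V", seq_along(df))
  df$.y <- y
  if (is.null(weights)) {
    rpart::rpart(.y ~ ., data = df, method = "class", control = control)
  } else {
    rpart::rpart(.y ~ ., data = df, method = "class", weights = weights,
                 control = control)
  }
}

predict_rpart_df <- function(fit, x) {
  df <- as.data.frame(signif(x, 12))
  names(df) <- paste0("V", seq_along(df))
  as.character(stats::predict(fit, df, type = "class"))
}

# Gaussian naive Bayes with a variance floor so exactly-constant
# within-class features (common in low-noise synthetic data) stay finite.
fit_nb <- function(x, y, var_floor_frac = 1e-3) {
  fit <- e1071::naiveBayes(x, y)
  global_sd <- apply(x, 2, stats::sd)
  for (j in seq_along(fit$tables)) {
    floor_j <- max(var_floor_frac * global_sd[j], 1e-9)
    fit$tables[[j]][, 2] <- pmax(fit$tables[[j]][, 2], floor_j)
  }
  fit
}

# Log-space Gaussian NB prediction. e1071's predict() floors small densities
# at a fixed threshold, which inverts class rankings when many features are
# near-degenerate; summing dnorm(log = TRUE) keeps the full penalty scale.
predict_nb <- function(fit, x) {
  classes <- rownames(fit$tables[[1]])
  means <- vapply(fit$tables, function(tb) tb[, 1], numeric(length(classes)))
  sds <- vapply(fit$tables, function(tb) tb[, 2], numeric(length(classes)))
  ll <- vapply(seq_along(classes), function(i) {
    rowSums(stats::dnorm(x, rep(means[i, ], each = nrow(x)),
                         rep(sds[i, ], each = nrow(x)), log = TRUE))
  }, numeric(nrow(x)))
  if (nrow(x) == 1) ll <- matrix(ll, nrow = 1)
  ll <- sweep(ll, 2, log(as.numeric(fit$apriori[classes])), "+")
  classes[max.col(ll, ties.method = "first")]
}

# --- AdaBoost (SAMME) over depth-capped rpart weak learners ------------------
# The weak tree is grown with cp = 0 and pruned back to at most `max_splits`
# internal splits using its own complexity table.

fit_samme_tree <- function(x, y, w, max_splits) {
  control <- rpart::rpart.control(
    cp = 0, xval = 0, maxdepth = 8, minsplit = 4, minbucket = 2,
    maxcompete = 0, maxsurrogate = 0, usesurrogate = 0
  )
  fit <- fit_rpart_df(x, y, control, weights = w)
  cp <- fit$cptable
  if (!is.null(cp) && any(cp[, "nsplit"] > max_splits)) {
    ok <- cp[cp[, "nsplit"] <= max_splits, , drop = FALSE]
    fit <- rpart::prune(fit, cp = ok[nrow(ok), "CP"])
  }
  fit
}

fit_samme <- function(x, y, iterations, max_splits) {
  y <- droplevels(factor(y))
  n <- nrow(x)
  K <- nlevels(y)
  w <- rep(1 / n, n)
  learners <- list()
  alphas <- numeric(0)
  for (m in seq_len(iterations)) {
    tree <- fit_samme_tree(x, y, w * n, max_splits)
    pred <- factor(predict_rpart_df(tree, x), levels = levels(y))
    miss <- pred != y
    err <- sum(w[miss])
    if (err <= 1e-12) { # perfect weak learner: keep it with a large vote, stop
      learners[[length(learners) + 1L]] <- tree
      alphas <- c(alphas, log(1e12) + log(K - 1))
      break
    }
    if (err >= 1 - 1 / K) break # no better than chance under SAMME
    alpha <- log((1 - err) / err) + log(K - 1)
    learners[[length(learners) + 1L]] <- tree
    alphas <- c(alphas, alpha)
    w <- w * exp(alpha * miss)
    w <- w / sum(w)
  }
  if (!length(learners)) { # fall back to a single unboosted tree
    learners <- list(fit_samme_tree(x, y, w * n, max_splits))
    alphas <- 1
  }
  list(learners = learners, alphas = alphas, levels = levels(y))
}

predict_samme <- function(fit, x) {
  votes <- matrix(0, nrow(x), length(fit$levels),
                  dimnames = list(NULL, fit$levels))
  for (m in seq_along(fit$learners)) {
    pred <- predict_rpart_df(fit$learners[[m]], x)
    votes[cbind(seq_len(nrow(x)), match(pred, fit$levels))] <-
      votes[cbind(seq_len(nrow(x)), match(pred, fit$levels))] + fit$alphas[m]
  }
  fit$levels[max.col(votes, ties.method = "first")]
}

# --- hierarchical model ------------------------------------------------------

feature_columns <- function(features) {
  schema <- attr(features, "schema")
  if (!is.null(schema)) return(schema$feature)
  setdiff(names(features), c("session_id", "window_start", "window_label"))
}

#' Fit the two-stage hierarchical model
#'
#' Stage 1 is trained on all windows with the binary target
#' brushing/transition (transition = ground-truth label 0); stage 2 is
#' trained on the ground-truth brushing windows only, with the 18 region
#' labels as target. Features are z-scored (statistics fitted on the training
#' data only) for the SVM, k-NN and naive Bayes families by default.
#'
#' @param features Feature tibble from [extract_features()] (must include
#'   `window_label`).
#' @param spec_s1,spec_s2 [classifier_spec()] for the two stages.
#' @param standardize Logical or `NULL`; `NULL` picks the per-family default.
#' @param seed Integer seed covering both stages' stochastic components.
#' @return A `brush_hier` model object.
#' @export
fit_hierarchical <- function(features,
                             spec_s1 = classifier_spec("RF", "S1"),
                             spec_s2 = classifier_spec("RF", "S2"),
                             standardize = NULL, seed = 1L) {
  cols <- feature_columns(features)
  x <- as.matrix(features[, cols])
  lab <- features$window_label
  if (!any(lab == 0) || length(unique(lab[lab > 0])) < 2) {
    stop("training labels must include transition (0) and at least 2 region classes",
         call. = FALSE)
  }
  y1 <- factor(ifelse(lab == 0, "transition", "brushing"),
               levels = c("transition", "brushing"))
  s1 <- fit_single(spec_s1, x, y1, seed = seed, standardize = standardize)
  keep <- lab > 0
  y2 <- factor(lab[keep], levels = sort(unique(lab[keep])))
  s2 <- fit_single(spec_s2, x[keep, , drop = FALSE], y2,
                   seed = seed + 1L, standardize = standardize)
  structure(
    list(stage1 = s1, stage2 = s2, feature_names = cols, seed = seed),
    class = "brush_hier"
  )
}

#' Predict window labels with a hierarchical model
#'
#' Applies stage 1 to every window; windows predicted as transitions get
#' label 0, the rest get the stage-2 region prediction. No temporal
#' post-processing is applied here (see [postprocess_labels()]).
#'
#' @param object A `brush_hier` model.
#' @param new_data Feature tibble with the same schema as the training data.
#' @param ... Unused.
#' @return A tibble with the bookkeeping columns of `new_data` plus
#'   `.pred_stage1` (`"brushing"`/`"transition"`), `.pred_region` (the
#'   stage-2 region for every window) and `.pred` (the merged 0..18 label).
#' @export
predict.brush_hier <- function(object, new_data, ...) {
  cols <- feature_columns(new_data)
  if (!identical(cols, object$feature_names)) {
    stop("feature schema mismatch between model and new data", call. = FALSE)
  }
  keep <- intersect(c("session_id", "window_start", "window_label"), names(new_data))
  out <- tibble::as_tibble(new_data[, keep])
  if (nrow(new_data) == 0) {
    out$.pred_stage1 <- character()
    out$.pred_region <- integer()
    out$.pred <- integer()
    return(out)
  }
  x <- as.matrix(new_data[, cols])
  p1 <- predict_single(object$stage1, x)
  p2 <- as.integer(as.character(predict_single(object$stage2, x)))
  out$.pred_stage1 <- as.character(p1)
  out$.pred_region <- p2
  out$.pred <- ifelse(out$.pred_stage1 == "transition", 0L, p2)
  out
}
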