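# Leave-one-session-out evaluation and confusion-matrix metrics over the
# 19-class label space (18 brushing regions + transition region 0).

LABEL_LEVELS <- 0:18

#' 19-class confusion matrix
#'
#' @param truth,estimate Equal-length label vectors in 0..18; rows of the
#'   result are true classes, columns predicted classes.
#' @return A 19 x 19 integer matrix of class `brush_confusion`.
#' @export
confusion_matrix <- function(truth, estimate) {
  if (length(truth) != length(estimate)) {
    stop("truth and estimate must have equal length", call. = FALSE)
  }
  stopifnot(all(truth %in% LABEL_LEVELS), all(estimate %in% LABEL_LEVELS))
  cm <- table(
    truth = factor(truth, levels = LABEL_LEVELS),
    estimate = factor(estimate, levels = LABEL_LEVELS)
  )
  cm <- unclass(as.matrix(cm))
  storage.mode(cm) <- "integer"
  class(cm) <- c("brush_confusion", class(cm))
  cm
}

#' Accuracy, sensitivity, precision and F1 from a confusion matrix
#'
#' Accuracy is the overall fraction of correctly classified windows
#' (trace / total). Sensitivity TP/(TP+FN) and precision TP/(TP+FP) are
#' computed one-vs-rest per class and macro-averaged (unweighted) over the
#' classes present in the true labels; a class never predicted has precision
#' 0 by convention. The F1-score is the harmonic mean of the macro
#' sensitivity and macro precision, defined as 0 when their sum is 0. All
#' values are percentages. `average = "micro"` pools the one-vs-rest counts
#' instead (for single-label multiclass data micro sensitivity equals
#' accuracy).
#'
#' @param cm Confusion matrix from [confusion_matrix()] (or any square count
#'   matrix with true classes in rows).
#' @param average `"macro"` (default) or `"micro"`.
#' @return A one-row tibble with columns `accuracy`, `sensitivity`,
#'   `precision`, `f1` (percent).
#' @export
compute_metrics <- function(cm, average = c("macro", "micro")) {
  average <- match.arg(average)
  cm <- unclass(cm)
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  present <- rowSums(cm) > 0
  if (average == "macro") {
    sens_c <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
    prec_c <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
    sens <- mean(sens_c[present])
    prec <- mean(prec_c[present])
  } else {
    sens <- sum(tp[present]) / sum((tp + fn)[present])
    prec <- if (sum((tp + fp)[present]) > 0) {
      sum(tp[present]) / sum((tp + fp)[present])
    } else 0
  }
  f1 <- if (sens + prec > 0) 2 * sens * prec / (sens + prec) else 0
  tibble::tibble(
    accuracy = 100 * sum(tp) / total,
    sensitivity = 100 * sens,
    precision = 100 * prec,
    f1 = 100 * f1
  )
}

#' Per-class one-vs-rest recall and precision
#'
#' @param cm Confusion matrix from [confusion_matrix()].
#' @return A tibble with one row per class present in the true labels:
#'   `class`, `n_true`, `sensitivity`, `precision` (percent).
#' @export
per_class_metrics <- function(cm) {
  cm <- unclass(cm)
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  present <- rowSums(cm) > 0
  tibble::tibble(
    class = as.integer(rownames(cm))[present],
    n_true = as.integer(rowSums(cm))[present],
    sensitivity = 100 * ifelse((tp + fn)[present] > 0,
                               (tp / (tp + fn))[present], 0),
    precision = 100 * ifelse((tp + fp)[present] > 0,
                             (tp / (tp + fp))[present], 0)
  )
}

#' Pipeline configuration for end-to-end evaluation
#'
#' Bundles every knob of the feature -> hierarchy -> post-processing pipeline
#' so a leave-one-session-out run is fully described by one object.
#'
#' @param modality `"TB"`, `"WR"` or `"TB_WR"`.
#' @param include_euler Include Euler-angle channels?
#' @param spec_s1,spec_s2 Stage classifier specifications
#'   ([classifier_spec()]).
#' @param standardize `NULL` (per-family default), `TRUE` or `FALSE`.
#' @param postprocess Apply contextual smoothing + majority voting?
#' @param max_island,iterative Smoothing parameters.
#' @param stage1_presmooth Also smooth the binary stage-1 sequence before
#'   merging stage-2 labels?
#' @param size,overlap Sliding-window geometry.
#' @param base_seed Base seed; per-fold seeds are derived as
#'   `base_seed + 7919 * fold`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(modality = "TB_WR", include_euler = TRUE,
                            spec_s1 = classifier_spec("RF", "S1"),
                            spec_s2 = classifier_spec("RF", "S2"),
                            standardize = NULL, postprocess = TRUE,
                            max_island = 2, iterative = FALSE,
                            stage1_presmooth = FALSE,
                            size = 20, overlap = 0.5, base_seed = 1L) {
  stopifnot(modality %in% c("TB", "WR", "TB_WR"))
  structure(
    list(
      modality = modality, include_euler = include_euler,
      spec_s1 = spec_s1, spec_s2 = spec_s2,
      standardize = standardize, postprocess = postprocess,
      max_island = max_island, iterative = iterative,
      stage1_presmooth = stage1_presmooth,
      size = size, overlap = overlap, base_seed = as.integer(base_seed)
    ),
    class = "pipeline_config"
  )
}

fold_seed <- function(base_seed, fold) as.integer(base_seed + 7919L * fold)

# Merge raw predictions into a post-processed sequence per the config.
apply_postprocessing <- function(pred_tbl, config) {
  if (!config$postprocess) return(pred_tbl$.pred)
  seqs <- split(seq_len(nrow(pred_tbl)), pred_tbl$session_id)
  out <- pred_tbl$.pred
  for (idx in seqs) {
    raw <- pred_tbl$.pred[idx]
    if (config$stage1_presmooth) {
      b <- smooth_labels(ifelse(raw == 0L, "T", "B"),
                         max_island = config$max_island,
                         iterative = config$iterative)
      raw <- ifelse(b == "T", 0L, ifelse(raw == 0L, pred_tbl$.pred_region[idx], raw))
    }
    out[idx] <- postprocess_labels(raw, max_island = config$max_island,
                                   iterative = config$iterative)
  }
  out
}

#' Leave-one-session-out cross-validation of the full pipeline
#'
#' For each session, trains the two-stage hierarchical model on all other
#' sessions and evaluates on the held-out session: feature extraction,
#' hierarchical prediction, optional post-processing, confusion matrix and
#' metrics. Fold seeds are derived deterministically from the base seed.
#'
#' @param sessions Session tibble covering at least 2 sessions.
#' @param config A [pipeline_config()].
#' @param features Optional precomputed output of [extract_features()] for
#'   this config (e.g. a [select_feature_block()] subset); extracted from
#'   `sessions` when `NULL`. `sessions` may be `NULL` when this is supplied.
#' @return A `brush_loso` object: per-fold metrics (`$folds`), per-fold
#'   confusion matrices (`$confusions`), pooled confusion (`$confusion_total`),
#'   averaged row-normalised confusion in percent (`$confusion_avg`),
#'   window-level predictions (`$predictions`) with raw and post-processed
#'   labels, and the config. Use [tidy()]/[glance()]/[autoplot()] to inspect.
#' @export
loso_cv <- function(sessions, config = pipeline_config(), features = NULL) {
  if (is.null(features)) {
    features <- extract_features(
      sessions, modality = config$modality,
      include_euler = config$include_euler,
      size = config$size, overlap = config$overlap
    )
  }
  ids <- unique(features$session_id)
  if (length(ids) < 2) stop("leave-one-session-out needs at least 2 sessions", call. = FALSE)
  folds <- list(); confusions <- list(); preds <- list()
  for (f in seq_along(ids)) {
    held <- ids[f]
    train <- features[features$session_id != held, ]
    test <- features[features$session_id == held, ]
    attr(train, "schema") <- attr(features, "schema")
    attr(test, "schema") <- attr(features, "schema")
    model <- fit_hierarchical(
      train, spec_s1 = config$spec_s1, spec_s2 = config$spec_s2,
      standardize = config$standardize, seed = fold_seed(config$base_seed, f)
    )
    pred <- stats::predict(model, test)
    pred$.pred_post <- apply_postprocessing(pred, config)
    final <- if (config$postprocess) pred$.pred_post else pred$.pred
    cm <- confusion_matrix(pred$window_label, final)
    m <- compute_metrics(cm)
    m_raw <- compute_metrics(confusion_matrix(pred$window_label, pred$.pred))
    folds[[f]] <- dplyr::bind_cols(
      tibble::tibble(fold = f, session_id = held,
                     n_windows = nrow(test)),
      m,
      tibble::tibble(accuracy_raw = m_raw$accuracy, f1_raw = m_raw$f1)
    )
    confusions[[f]] <- cm
    preds[[f]] <- dplyr::mutate(pred, fold = f)
  }
  cms <- lapply(confusions, unclass)
  total <- Reduce(`+`, cms)
  # row-normalise each fold to percentages, then average over folds where the
  # true class occurs (every row of the result sums to 100 when present)
  norm <- lapply(cms, function(m) {
    rs <- rowSums(m)
    out <- 100 * m / ifelse(rs > 0, rs, NA_real_)
    out
  })
  avg <- apply(simplify2array(norm), c(1, 2), mean, na.rm = TRUE)
  avg[is.nan(avg)] <- 0
  structure(
    list(
      folds = dplyr::bind_rows(folds),
      confusions = confusions,
      confusion_total = structure(total, class = c("brush_confusion", class(total))),
      confusion_avg = avg,
      predictions = dplyr::bind_rows(preds),
      config = config
    ),
    class = "brush_loso"
  )
}
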