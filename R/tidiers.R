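# broom-style tidiers for fitted objects and LOSO results.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy per-fold metrics of a LOSO run
#'
#' @param x A `brush_loso` object from [loso_cv()].
#' @param ... Unused.
#' @return A tibble with one row per fold: session held out, window count,
#'   accuracy/sensitivity/precision/f1 (percent) and the pre-post-processing
#'   accuracy and F1 for comparison.
#' @method tidy brush_loso
#' @export
tidy.brush_loso <- function(x, ...) {
  x$folds
}

#' One-row summary of a LOSO run (mean and sd across folds)
#'
#' @param x A `brush_loso` object.
#' @param ... Unused.
#' @return A one-row tibble: mean and sd of each metric across folds, plus
#'   fold count, total windows, and the configuration's modality/classifier.
#' @method glance brush_loso
#' @export
glance.brush_loso <- function(x, ...) {
  f <- x$folds
  tibble::tibble(
    n_folds = nrow(f),
    n_windows = sum(f$n_windows),
    accuracy = mean(f$accuracy), accuracy_sd = stats::sd(f$accuracy),
    sensitivity = mean(f$sensitivity), sensitivity_sd = stats::sd(f$sensitivity),
    precision = mean(f$precision), precision_sd = stats::sd(f$precision),
    f1 = mean(f$f1), f1_sd = stats::sd(f$f1),
    accuracy_raw = mean(f$accuracy_raw),
    modality = x$config$modality,
    include_euler = x$config$include_euler,
    family_s1 = x$config$spec_s1$family,
    family_s2 = x$config$spec_s2$family
  )
}

#' Tidy a hierarchical model
#'
#' @param x A `brush_hier` model from [fit_hierarchical()].
#' @param ... Unused.
#' @return A tibble with one row per stage: family, number of classes and of
#'   features, and whether inputs are standardized.
#' @method tidy brush_hier
#' @export
tidy.brush_hier <- function(x, ...) {
  stage_row <- function(s, name) {
    tibble::tibble(
      stage = name, family = s$spec$family,
      n_classes = length(s$levels),
      n_features = length(x$feature_names),
      standardized = !is.null(s$scaler)
    )
  }
  dplyr::bind_rows(stage_row(x$stage1, "S1"), stage_row(x$stage2, "S2"))
}

#' @method glance brush_hier
#' @export
glance.brush_hier <- function(x, ...) {
  tibble::tibble(
    family_s1 = x$stage1$spec$family,
    family_s2 = x$stage2$spec$family,
    n_features = length(x$feature_names),
    n_regions = length(x$stage2$levels),
    seed = x$seed
  )
}

#' @export
print.brush_loso <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "Leave-one-session-out run: %d folds, %d windows\n  %s / %s, modality %s, Euler %s\n",
    g$n_folds, g$n_windows, g$family_s1, g$family_s2, g$modality,
    ifelse(g$include_euler, "yes", "no")
  ))
  cat(sprintf(
    "  accuracy %.2f +/- %.2f%%  sensitivity %.2f%%  precision %.2f%%  F1 %.2f%%\n",
    g$accuracy, g$accuracy_sd, g$sensitivity, g$precision, g$f1
  ))
  invisible(x)
}

#' @export
print.brush_hier <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "Hierarchical brushing-region model: stage 1 %s, stage 2 %s (%d regions, %d features)\n",
    g$family_s1, g$family_s2, g$n_regions, g$n_features
  ))
  invisible(x)
}
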