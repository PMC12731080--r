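# Temporal post-processing of window label sequences: contextual smoothing of
# short mispredicted islands, then per-segment majority voting between
# transitions.

#' Contextual smoothing of a label sequence
#'
#' Rewrites short "islands": every maximal run of at most `max_island`
#' identical labels whose left and right neighbouring runs both exist and
#' carry the same label is rewritten to that flanking label. The pass is
#' computed on the run decomposition of the input sequence (rewrites do not
#' cascade); runs touching either end of the sequence are never rewritten,
#' since they lack a flank on one side. With `iterative = TRUE` the pass is
#' repeated until a fixed point.
#'
#' @param seq Vector of labels (any atomic type).
#' @param max_island Maximum island length to rewrite (default 2).
#' @param iterative Repeat until no island remains? Default `FALSE`.
#' @return The smoothed sequence, same type and length as the input.
#' @examples
#' smooth_labels(c("B", "B", "T", "B", "B")) # island removed
#' smooth_labels(c("B", "T", "T", "T", "B")) # length-3 island kept
#' @export
smooth_labels <- function(seq, max_island = 2, iterative = FALSE) {
  if (length(seq) == 0) stop("empty label sequence", call. = FALSE)
  repeat {
    r <- rle(as.vector(seq))
    k <- length(r$values)
    vals <- r$values
    if (k >= 3) {
      for (i in 2:(k - 1)) {
        if (r$lengths[i] <= max_island && r$values[i - 1] == r$values[i + 1]) {
          vals[i] <- r$values[i - 1] # original flank labels, single pass
        }
      }
    }
    out <- inverse.rle(list(lengths = r$lengths, values = vals))
    if (!iterative || identical(out, as.vector(seq))) break
    seq <- out
  }
  out
}

#' Run decomposition into transition and brushing segments
#'
#' Splits a merged 0..18 label sequence into maximal transition runs
#' (label 0) and brushing segments — each maximal stretch of non-zero labels
#' between transitions is one segment, regardless of how many distinct region
#' labels it contains. Leading/trailing brushing segments without a flanking
#' transition are allowed.
#'
#' @param seq Integer vector of labels in 0..18.
#' @return A tibble with columns `start`, `end` (1-based, inclusive) and
#'   `segment_type` (`"transition"` or `"brushing"`).
#' @export
segment_runs <- function(seq) {
  if (length(seq) == 0) stop("empty label sequence", call. = FALSE)
  r <- rle(as.integer(seq) != 0L)
  end <- cumsum(r$lengths)
  start <- end - r$lengths + 1L
  tibble::tibble(
    start = start, end = end,
    segment_type = ifelse(r$values, "brushing", "transition")
  )
}

#' Majority vote within one brushing segment
#'
#' Returns the modal label; ties are broken in favour of the earliest
#' occurring label among the tied set, which makes the vote deterministic.
#'
#' @param labels Non-empty vector of region labels.
#' @return The winning label (same type as the input).
#' @export
majority_vote <- function(labels) {
  if (length(labels) == 0) stop("empty segment", call. = FALSE)
  u <- unique(labels) # first-occurrence order
  counts <- tabulate(match(labels, u))
  u[which.max(counts)] # which.max takes the first maximum = earliest label
}

#' Full post-processing pipeline for a merged label sequence
#'
#' Contextual smoothing on the merged 19-class sequence, then per-segment
#' majority voting: every brushing segment (maximal non-zero stretch between
#' transitions) is rewritten to its modal region label. Transition windows
#' keep label 0. The smooth-then-vote pass is repeated until the sequence is
#' stable, which makes the pipeline idempotent; each pass strictly reduces
#' the number of label runs, so this terminates, and on typical prediction
#' sequences the first pass is already stable.
#'
#' @param seq Integer vector of labels in 0..18.
#' @param max_island,iterative Passed to [smooth_labels()].
#' @return Post-processed integer label sequence.
#' @examples
#' postprocess_labels(c(0L, 3L, 3L, 4L, 3L, 0L)) # segment votes to 3
#' @export
postprocess_labels <- function(seq, max_island = 2, iterative = FALSE) {
  out <- as.integer(seq)
  repeat {
    prev <- out
    out <- as.integer(smooth_labels(prev, max_island = max_island,
                                    iterative = iterative))
    runs <- segment_runs(out)
    for (i in which(runs$segment_type == "brushing")) {
      idx <- runs$start[i]:runs$end[i]
      out[idx] <- as.integer(majority_vote(out[idx]))
    }
    if (identical(out, prev)) break
  }
  out
}
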