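# Derived signal channels and sliding-window feature extraction.

SIGNAL_COLS <- c("ax", "ay", "az", "gx", "gy", "gz", "qw", "qx", "qy", "qz")
SESSION_COLS <- c("t", SIGNAL_COLS, "label")
STAT_NAMES <- c("mean", "max", "min", "variance", "std", "kurtosis", "skewness", "range")
BASE_CHANNELS <- c(
  "ax", "ay", "az", "gx", "gy", "gz",
  "a_norm", "g_norm", "a_hori", "g_hori",
  "a_coro", "g_coro", "a_sagi", "g_sagi"
)
EULER_CHANNELS <- c("pitch", "roll", "yaw")

#' Vector norm and anatomical-plane projection norms
#'
#' For a tri-axial signal (ox, oy, oz) — acceleration or angular velocity —
#' computes the Euclidean norm and the norms of its projections onto the
#' horizontal (y-z), coronal (x-z) and sagittal (x-y) planes:
#' norm = sqrt(ox^2 + oy^2 + oz^2), hori = sqrt(oy^2 + oz^2),
#' coro = sqrt(ox^2 + oz^2), sagi = sqrt(ox^2 + oy^2).
#'
#' @param v A length-3 numeric vector, or an n x 3 matrix of row vectors.
#' @return A tibble with columns `norm`, `hori`, `coro`, `sagi` (one row per
#'   input vector), all non-negative.
#' @examples
#' channel_norms(c(3, 4, 0)) # norm 5, hori 4, coro 3, sagi 5
#' @export
channel_norms <- function(v) {
  if (is.null(dim(v))) {
    if (length(v) != 3) stop("expected a 3-vector", call. = FALSE)
    v <- matrix(v, nrow = 1)
  }
  v <- as.matrix(v)
  if (ncol(v) != 3) stop("expected 3 columns (x, y, z)", call. = FALSE)
  if (!all(is.finite(v))) {
    stop("signal-quality error: non-finite components in tri-axial signal", call. = FALSE)
  }
  x <- v[, 1]; y <- v[, 2]; z <- v[, 3]
  tibble::tibble(
    norm = sqrt(x^2 + y^2 + z^2),
    hori = sqrt(y^2 + z^2),
    coro = sqrt(x^2 + z^2),
    sagi = sqrt(x^2 + y^2)
  )
}

#' Build the derived channel matrix for one sensor stream
#'
#' Expands the raw tri-axial acceleration and angular velocity of a single
#' sensor stream into the per-sample channel set used for feature extraction:
#' the six raw axes, the two Euclidean norms, the six plane-projection norms
#' (14 channels), and optionally the quaternion-derived pitch/roll/yaw
#' (17 channels).
#'
#' @param stream A data frame with columns `ax ay az gx gy gz qw qx qy qz`
#'   (one placement of a session; extra columns are ignored).
#' @param include_euler Logical; append Euler-angle channels?
#' @return A numeric matrix, one row per sample, with named channel columns.
#' @export
build_channels <- function(stream, include_euler = FALSE) {
  stream <- as.data.frame(stream)
  missing_cols <- setdiff(SIGNAL_COLS, names(stream))
  if (length(missing_cols)) {
    stop("stream is missing columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(stream) == 0) stop("empty stream", call. = FALSE)
  acc <- as.matrix(stream[, c("ax", "ay", "az")])
  gyr <- as.matrix(stream[, c("gx", "gy", "gz")])
  an <- channel_norms(acc)
  gn <- channel_norms(gyr)
  out <- cbind(
    acc, gyr,
    a_norm = an$norm, g_norm = gn$norm,
    a_hori = an$hori, g_hori = gn$hori,
    a_coro = an$coro, g_coro = gn$coro,
    a_sagi = an$sagi, g_sagi = gn$sagi
  )
  colnames(out) <- BASE_CHANNELS
  if (include_euler) {
    eu <- quat_to_euler(as.matrix(stream[, c("qw", "qx", "qy", "qz")]))
    out <- cbind(out, pitch = eu$pitch, roll = eu$roll, yaw = eu$yaw)
  }
  out
}

#' Sliding-window start indices
#'
#' Enumerates fixed-size, 50%-overlapping (by default) windows over a stream of
#' `n_samples` samples. Windows that would overrun the stream are dropped; no
#' padding is applied.
#'
#' @param n_samples Number of samples in the stream.
#' @param size Window length in samples (default 20, i.e. 1/3 s at 60 Hz).
#' @param overlap Fractional overlap between consecutive windows in \[0, 1);
#'   `size * (1 - overlap)` must be a whole number of samples.
#' @return A tibble with columns `start` (0-based sample index) and `length`.
#'   Empty (zero rows) when `n_samples < size`.
#' @examples
#' slide_windows(60) # 5 windows starting at 0, 10, 20, 30, 40
#' @export
slide_windows <- function(n_samples, size = 20, overlap = 0.5) {
  stopifnot(size > 0, overlap >= 0, overlap < 1)
  step <- size * (1 - overlap)
  if (abs(step - round(step)) > 1e-9) {
    stop("size * (1 - overlap) must be a whole number of samples", call. = FALSE)
  }
  step <- as.integer(round(step))
  if (n_samples < size) {
    return(tibble::tibble(start = integer(), length = integer()))
  }
  starts <- seq.int(0L, n_samples - size, by = step)
  tibble::tibble(start = as.integer(starts), length = as.integer(size))
}

#' Time-domain summary statistics for one window
#'
#' Computes the eight window statistics in schema order: mean, maximum,
#' minimum, variance, standard deviation, kurtosis, skewness, range.
#' Variance and standard deviation use the sample (n - 1) denominator;
#' skewness is the Fisher-Pearson moment coefficient g1 = m3 / m2^(3/2);
#' kurtosis is the (non-excess) Pearson coefficient m4 / m2^2, with m_k the
#' k-th central sample moment. Zero-variance windows define skewness and
#' kurtosis as 0 so the feature matrix stays finite.
#'
#' @param values Numeric vector with at least 2 values.
#' @return Named numeric vector of length 8.
#' @examples
#' window_stats(c(1, 2, 3, 4))
#' @export
window_stats <- function(values) {
  if (length(values) < 2) stop("need at least 2 values per window", call. = FALSE)
  drop(window_stats_matrix(matrix(values, nrow = 1)))
}

# Row-wise window statistics: windows in rows, samples in columns.
# Returns an n x 8 matrix in STAT_NAMES order.
window_stats_matrix <- function(m) {
  n <- ncol(m)
  mu <- rowMeans(m)
  d <- m - mu
  m2 <- rowMeans(d^2)
  m3 <- rowMeans(d^3)
  m4 <- rowMeans(d^4)
  mx <- m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]
  mn <- -(-m)[cbind(seq_len(nrow(m)), max.col(-m, ties.method = "first"))]
  varv <- m2 * n / (n - 1)
  # relative threshold: float rounding on a constant window leaves m2 ~ eps^2 * scale^2
  degen <- m2 <= 1e-12 * pmax(rowMeans(m^2), 1e-300)
  kurt <- ifelse(degen, 0, m4 / m2^2)
  skew <- ifelse(degen, 0, m3 / m2^1.5)
  varv[degen] <- 0
  out <- cbind(mu, mx, mn, varv, sqrt(varv), kurt, skew, mx - mn)
  colnames(out) <- STAT_NAMES
  out
}

#' Feature schema for a sensor/statistic/channel configuration
#'
#' Enumerates the named, ordered feature columns produced by
#' [extract_features()]: for each placement (TB first, then WR for the fused
#' modality), each of the 8 statistics, applied to each of the 14 (or 17 with
#' Euler angles) derived channels — 112 or 136 features per sensor.
#'
#' @param modality One of `"TB"`, `"WR"`, `"TB_WR"`.
#' @param include_euler Logical; include pitch/roll/yaw channels?
#' @return A tibble with columns `feature`, `placement`, `statistic`,
#'   `channel`, in column order of the feature matrix.
#' @examples
#' nrow(feature_schema("TB", include_euler = FALSE)) # 112
#' nrow(feature_schema("TB_WR", include_euler = TRUE)) # 272
#' @export
feature_schema <- function(modality = c("TB", "WR", "TB_WR"), include_euler = FALSE) {
  modality <- match.arg(modality)
  placements <- switch(modality, TB = "TB", WR = "WR", TB_WR = c("TB", "WR"))
  channels <- c(BASE_CHANNELS, if (include_euler) EULER_CHANNELS)
  grid <- expand.grid(
    channel = channels, statistic = STAT_NAMES, placement = placements,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  tibble::tibble(
    feature = paste(grid$placement, grid$statistic, grid$channel, sep = "_"),
    placement = grid$placement,
    statistic = grid$statistic,
    channel = grid$channel
  )
}

#' Assign a ground-truth label to each window
#'
#' Each window takes the majority label of its samples; ties are resolved to 0
#' (transition), the conservative choice for brushing-time estimates.
#'
#' @param sample_labels Integer vector of per-sample labels in 0..18.
#' @param windows Window tibble from [slide_windows()].
#' @return Integer vector of per-window labels.
#' @export
label_windows <- function(sample_labels, windows) {
  sample_labels <- as.integer(sample_labels)
  vapply(seq_len(nrow(windows)), function(i) {
    idx <- windows$start[i] + seq_len(windows$length[i])
    lab <- sample_labels[idx]
    counts <- tabulate(lab + 1L, nbins = 19L)
    top <- which(counts == max(counts)) - 1L
    if (length(top) > 1L) 0L else top
  }, integer(1))
}

#' Extract windowed features from labelled sessions
#'
#' Applies the derived-channel expansion, the 20-sample / 50%-overlap sliding
#' window and the eight window statistics to each session's sensor streams,
#' producing one feature row per window. For the fused `TB_WR` modality the TB
#' feature block precedes the WR block (plain column concatenation).
#'
#' @param sessions Session tibble (columns `session_id`, `placement`, `t`,
#'   `ax..az`, `gx..gz`, `qw..qz`, `label`), e.g. from [generate_dataset()] or
#'   [read_session_dir()].
#' @param modality `"TB"`, `"WR"` or `"TB_WR"`.
#' @param include_euler Logical; add Euler-angle channels (136 features per
#'   sensor instead of 112)?
#' @param size,overlap Window length and fractional overlap
#'   (see [slide_windows()]).
#' @return A tibble with bookkeeping columns `session_id`, `window_start`,
#'   `window_label`, followed by the schema-named feature columns; the schema
#'   tibble is attached as attribute `"schema"`.
#' @export
extract_features <- function(sessions, modality = c("TB", "WR", "TB_WR"),
                             include_euler = FALSE, size = 20, overlap = 0.5) {
  modality <- match.arg(modality)
  placements <- switch(modality, TB = "TB", WR = "WR", TB_WR = c("TB", "WR"))
  sessions <- validate_sessions(sessions)
  schema <- feature_schema(modality, include_euler)
  per_session <- lapply(split(sessions, sessions$session_id), function(ses) {
    streams <- split(ses, ses$placement)
    missing_pl <- setdiff(placements, names(streams))
    if (length(missing_pl)) {
      stop("session ", ses$session_id[1], " is missing stream(s): ",
           paste(missing_pl, collapse = ", "), call. = FALSE)
    }
    lens <- vapply(streams[placements], nrow, integer(1))
    if (length(unique(lens)) != 1) {
      stop("session ", ses$session_id[1],
           ": TB and WR streams must share the window grid (equal length)",
           call. = FALSE)
    }
    windows <- slide_windows(lens[1], size = size, overlap = overlap)
    if (nrow(windows) == 0) return(NULL)
    idx <- outer(windows$start, seq_len(size), `+`) # n_win x size sample indices
    blocks <- lapply(placements, function(pl) {
      ch <- build_channels(streams[[pl]], include_euler = include_euler)
      block <- matrix(NA_real_, nrow(windows), 8L * ncol(ch))
      for (j in seq_len(ncol(ch))) {
        wm <- matrix(ch[, j][idx], nrow(windows), size)
        block[, (seq_len(8L) - 1L) * ncol(ch) + j] <- window_stats_matrix(wm)
      }
      block
    })
    feats <- do.call(cbind, blocks)
    colnames(feats) <- schema$feature
    labels <- label_windows(streams[[placements[1]]]$label, windows)
    dplyr::bind_cols(
      tibble::tibble(
        session_id = ses$session_id[1],
        window_start = windows$start,
        window_label = labels
      ),
      tibble::as_tibble(feats)
    )
  })
  out <- dplyr::bind_rows(per_session)
  if (anyNA(out) || any(!is.finite(as.matrix(out[schema$feature])))) {
    stop("feature extraction produced non-finite values", call. = FALSE)
  }
  attr(out, "schema") <- schema
  out
}

#' Select a sub-modality feature block from an extracted feature table
#'
#' The fused, Euler-augmented feature table contains every other configuration
#' as a column subset; this helper selects the block for a smaller modality
#' and/or the non-Euler channel set without re-extracting, and refreshes the
#' attached schema.
#'
#' @param features Output of [extract_features()].
#' @param modality,include_euler Target configuration (must be a subset of the
#'   source configuration).
#' @return A feature tibble of the target configuration.
#' @export
select_feature_block <- function(features, modality = c("TB", "WR", "TB_WR"),
                                 include_euler = FALSE) {
  modality <- match.arg(modality)
  schema <- feature_schema(modality, include_euler)
  missing_cols <- setdiff(schema$feature, names(features))
  if (length(missing_cols)) {
    stop("source features do not contain the requested block (missing ",
         length(missing_cols), " columns)", call. = FALSE)
  }
  out <- features[, c("session_id", "window_start", "window_label", schema$feature)]
  attr(out, "schema") <- schema
  out
}

validate_sessions <- function(sessions) {
  sessions <- tibble::as_tibble(sessions)
  needed <- c("session_id", "placement", SESSION_COLS)
  missing_cols <- setdiff(needed, names(sessions))
  if (length(missing_cols)) {
    stop("sessions are missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  sessions
}

# Strict stream checks applied on CSV ingest: monotone, near-uniform time base
# and unit quaternions.
validate_stream <- function(stream, rate_hz = 60, file = "stream") {
  dt <- diff(stream$t)
  if (length(dt) && any(dt <= 0)) {
    row <- which(dt <= 0)[1] + 1L
    stop(file, ": timestamps not strictly increasing at row ", row, call. = FALSE)
  }
  nominal <- 1 / rate_hz
  if (length(dt) && any(abs(dt - nominal) > 0.01 * nominal)) {
    row <- which(abs(dt - nominal) > 0.01 * nominal)[1] + 1L
    stop(file, ": sample spacing deviates more than 1% from 1/", rate_hz,
         " s at row ", row, call. = FALSE)
  }
  q <- as.matrix(stream[, c("qw", "qx", "qy", "qz")])
  nrm <- sqrt(rowSums(q^2))
  if (any(!is.finite(nrm)) || any(nrm < 1e-12)) {
    stop(file, ": invalid quaternion (zero or non-finite norm)", call. = FALSE)
  }
  stream[, c("qw", "qx", "qy", "qz")] <- q / nrm
  stream
}
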