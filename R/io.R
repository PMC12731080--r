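# Session CSV dialect and run manifests. One CSV per sensor per session with
# columns t, ax, ay, az, gx, gy, gz, qw, qx, qy, qz, label; a YAML manifest
# records placements, gyro units, seeds and generator parameters so any
# artifact can be reproduced byte-for-byte.

CSV_COLUMNS <- c("t", "ax", "ay", "az", "gx", "gy", "gz",
                 "qw", "qx", "qy", "qz", "label")

#' Write sessions as per-sensor CSV files plus a manifest
#'
#' @param sessions Session tibble (e.g. from [generate_dataset()]).
#' @param dir Output directory (created if needed).
#' @param gyro_unit Unit the gyro columns are written in (`"rad_s"`).
#' @param params Optional named list of generator parameters to embed in the
#'   manifest.
#' @return Invisibly, the manifest path.
#' @export
write_session_dir <- function(sessions, dir, gyro_unit = "rad_s", params = list()) {
  sessions <- validate_sessions(sessions)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory ", dir, call. = FALSE)
  entries <- list()
  for (sid in unique(sessions$session_id)) {
    for (pl in unique(sessions$placement[sessions$session_id == sid])) {
      s <- sessions[sessions$session_id == sid & sessions$placement == pl, ]
      file <- file.path(dir, paste0(sid, "_", pl, ".csv"))
      df <- as.data.frame(s[, CSV_COLUMNS])
      utils::write.csv(format(df, digits = 10, trim = TRUE, scientific = FALSE),
                       file, row.names = FALSE, quote = FALSE)
      entries[[length(entries) + 1L]] <- list(
        session_id = sid, placement = pl, file = basename(file),
        n_samples = nrow(s)
      )
    }
  }
  manifest <- list(
    format = "brushtrack-session-csv",
    version = as.character(utils::packageVersion("brushtrack")),
    gyro_unit = gyro_unit,
    rate_hz = 60,
    sessions = entries,
    params = params
  )
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, path)
  invisible(path)
}

#' Read one session-sensor CSV
#'
#' Validates the header, strictly increasing and near-uniform timestamps and
#' non-degenerate quaternions (normalised on ingest); converts gyro values to
#' rad/s if declared in deg/s.
#'
#' @param path CSV file path.
#' @param placement `"TB"` or `"WR"`.
#' @param session_id Session identifier to attach.
#' @param gyro_unit `"rad_s"` or `"deg_s"`.
#' @param rate_hz Expected sampling rate.
#' @return A session tibble for one placement.
#' @export
read_session_csv <- function(path, placement, session_id,
                             gyro_unit = c("rad_s", "deg_s"), rate_hz = 60) {
  gyro_unit <- match.arg(gyro_unit)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  missing_cols <- setdiff(CSV_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop(basename(path), ": missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0) stop(basename(path), ": empty session file", call. = FALSE)
  df <- df[, CSV_COLUMNS]
  if (gyro_unit == "deg_s") {
    df[, c("gx", "gy", "gz")] <- df[, c("gx", "gy", "gz")] * pi / 180
  }
  df <- validate_stream(df, rate_hz = rate_hz, file = basename(path))
  dplyr::bind_cols(
    tibble::tibble(session_id = session_id, placement = placement),
    tibble::as_tibble(df)
  )
}

#' Read a session directory written by [write_session_dir()]
#'
#' @param dir Directory containing the per-sensor CSVs and `manifest.yaml`.
#' @return A session tibble with all sessions and placements stacked.
#' @export
read_session_dir <- function(dir) {
  path <- file.path(dir, "manifest.yaml")
  if (!file.exists(path)) stop("no manifest.yaml in ", dir, call. = FALSE)
  manifest <- yaml::read_yaml(path)
  streams <- lapply(manifest$sessions, function(e) {
    read_session_csv(
      file.path(dir, e$file), placement = e$placement,
      session_id = e$session_id,
      gyro_unit = if (is.null(manifest$gyro_unit)) "rad_s" else manifest$gyro_unit,
      rate_hz = if (is.null(manifest$rate_hz)) 60 else manifest$rate_hz
    )
  })
  dplyr::bind_rows(streams)
}

#' Export an extracted feature table as CSV
#'
#' Columns: `session_id`, `window_start`, `window_label`, then the
#' schema-named feature columns.
#'
#' @param features Output of [extract_features()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_features_csv <- function(features, path) {
  utils::write.csv(as.data.frame(features), path, row.names = FALSE)
  invisible(path)
}

#' Export a LOSO report as JSON plus confusion CSVs
#'
#' Writes `<stem>.json` (per-fold and summary metrics, config echo, seeds)
#' and `<stem>_confusion_total.csv` / `<stem>_confusion_avg.csv`.
#'
#' @param result A `brush_loso` object.
#' @param stem Output path stem (no extension).
#' @return Invisibly, the JSON path.
#' @export
write_report <- function(result, stem) {
  cfg <- result$config
  report <- list(
    summary = as.list(glance(result)),
    folds = result$folds,
    config = list(
      modality = cfg$modality, include_euler = cfg$include_euler,
      family_s1 = cfg$spec_s1$family, family_s2 = cfg$spec_s2$family,
      hyperparams_s1 = cfg$spec_s1$hyperparams,
      hyperparams_s2 = cfg$spec_s2$hyperparams,
      postprocess = cfg$postprocess, max_island = cfg$max_island,
      stage1_presmooth = cfg$stage1_presmooth,
      size = cfg$size, overlap = cfg$overlap, base_seed = cfg$base_seed,
      fold_seeds = fold_seed(cfg$base_seed, seq_len(nrow(result$folds)))
    )
  )
  json_path <- paste0(stem, ".json")
  jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  utils::write.csv(as.data.frame(unclass(result$confusion_total)),
                   paste0(stem, "_confusion_total.csv"))
  utils::write.csv(as.data.frame(result$confusion_avg),
                   paste0(stem, "_confusion_avg.csv"))
  invisible(json_path)
}
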