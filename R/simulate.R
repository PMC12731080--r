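# Synthetic brushing-session generator. Emulates the scripted protocol
# (maxilla regions 1..9 then mandible regions 10..18, ~20 strokes per region)
# and the qualitative signal phenomenology of a brush-mounted and a wrist-worn
# IMU: periodic stroke accelerations within regions, angular-velocity peaks
# and smooth orientation change during transitions, and a wrist stream that is
# a rotated, attenuated, lagged, noisier copy of the brush dynamics.

#' Default per-region motion profiles
#'
#' One row per dental region (1..18) with an orientation anchor (pitch, roll,
#' yaw in degrees), a stroke frequency and amplitude, and a brush-frame stroke
#' axis. Anchors are built from the region's jaw (pitch sign), side (yaw) and
#' surface (roll), so mirror-symmetric regions differ mainly in yaw/roll sign —
#' the same geometry that makes left/right surfaces confusable from motion
#' dynamics alone.
#'
#' @param stroke_freq Default stroke frequency, Hz.
#' @param acc_amplitude Stroke acceleration amplitude, m/s^2.
#' @return A tibble with one row per region.
#' @export
region_profiles <- function(stroke_freq = 4, acc_amplitude = 3) {
  # region id -> (jaw, side, surface) per the dentition subdivision table
  map <- tibble::tribble(
    ~region_id, ~jaw, ~side, ~surface,
    1L, "maxilla", "right", "buccal",
    2L, "maxilla", "anterior", "labial",
    3L, "maxilla", "left", "buccal",
    4L, "maxilla", "left", "occlusal",
    5L, "maxilla", "anterior", "incisal",
    6L, "maxilla", "right", "occlusal",
    7L, "maxilla", "right", "lingual",
    8L, "maxilla", "anterior", "lingual",
    9L, "maxilla", "left", "lingual",
    10L, "mandible", "right", "buccal",
    11L, "mandible", "anterior", "labial",
    12L, "mandible", "left", "buccal",
    13L, "mandible", "left", "occlusal",
    14L, "mandible", "anterior", "incisal",
    15L, "mandible", "right", "occlusal",
    16L, "mandible", "right", "lingual",
    17L, "mandible", "anterior", "lingual",
    18L, "mandible", "left", "lingual"
  )
  pitch <- ifelse(map$jaw == "maxilla", 25, -25)
  yaw <- c(right = -50, anterior = 0, left = 50)[map$side]
  roll <- c(buccal = -40, labial = -40, occlusal = 0, incisal = 0,
            lingual = 40, `NA` = 0)[map$surface]
  # stroke direction in the brush frame depends on the surface being scrubbed
  axis <- list(
    buccal = c(0, 1, 0), labial = c(0, 1, 0),
    occlusal = c(0, 0, 1), incisal = c(0, 0, 1),
    lingual = c(0, 0.7, 0.7141428)
  )
  ax <- do.call(rbind, axis[map$surface])
  ax <- ax / sqrt(rowSums(ax^2))
  tibble::tibble(
    region_id = map$region_id,
    jaw = map$jaw, side = map$side, surface = map$surface,
    pitch = as.numeric(pitch), roll = as.numeric(roll), yaw = as.numeric(yaw),
    stroke_freq = stroke_freq,
    acc_amplitude = acc_amplitude,
    axis_x = ax[, 1], axis_y = ax[, 2], axis_z = ax[, 3]
  )
}

#' Session script: region order and timing
#'
#' @param region_sequence Order in which regions are brushed; the default is
#'   the scripted protocol (maxilla 1..9 then mandible 10..18, no repeats).
#' @param strokes_per_region Brushing strokes per region (default 20).
#' @param transition_duration Seconds spent repositioning between regions.
#' @param rate_hz Sampling rate (default 60).
#' @param seed Integer seed; the generated session is fully determined by it.
#' @return A `session_script` list.
#' @export
session_script <- function(region_sequence = 1:18, strokes_per_region = 20,
                           transition_duration = 1.5, rate_hz = 60, seed = 1L) {
  if (strokes_per_region < 1) stop("strokes_per_region must be >= 1", call. = FALSE)
  stopifnot(all(region_sequence %in% 1:18), rate_hz > 0, transition_duration >= 0)
  structure(
    list(
      region_sequence = as.integer(region_sequence),
      strokes_per_region = strokes_per_region,
      transition_duration = transition_duration,
      rate_hz = rate_hz,
      seed = as.integer(seed)
    ),
    class = "session_script"
  )
}

#' Sensor noise and wrist-stream model
#'
#' @param acc_noise_sd Accelerometer noise, m/s^2.
#' @param gyro_noise_sd Gyroscope noise, rad/s.
#' @param quat_jitter_sd Orientation jitter around the region anchor, degrees.
#' @param wrist_attenuation Fraction of brush dynamics retained at the wrist.
#' @param wrist_lag Wrist lag behind the brush stream, samples.
#' @return A `noise_model` list.
#' @export
noise_model <- function(acc_noise_sd = 0.4, gyro_noise_sd = 0.08,
                        quat_jitter_sd = 4, wrist_attenuation = 0.6,
                        wrist_lag = 3L) {
  stopifnot(
    acc_noise_sd >= 0, gyro_noise_sd >= 0, quat_jitter_sd >= 0,
    wrist_attenuation > 0, wrist_attenuation <= 1, wrist_lag >= 0
  )
  structure(
    list(
      acc_noise_sd = acc_noise_sd, gyro_noise_sd = gyro_noise_sd,
      quat_jitter_sd = quat_jitter_sd, wrist_attenuation = wrist_attenuation,
      wrist_lag = as.integer(wrist_lag)
    ),
    class = "noise_model"
  )
}

GRAVITY <- c(0, 0, 9.81)

# Smooth stationary AR(1) jitter with marginal sd `sd`. phi is chosen slow
# (correlation time ~ 17 s at 60 Hz) so orientation drift contributes far less
# angular velocity than a between-region transition does.
ar1_noise <- function(n, sd, phi = 0.999) {
  if (sd == 0 || n == 0) return(numeric(n))
  innov <- stats::rnorm(n, 0, sd * sqrt(1 - phi^2))
  as.numeric(stats::filter(innov, phi, method = "recursive", init = stats::rnorm(1, 0, sd)))
}

smoothstep <- function(u) u^2 * (3 - 2 * u)

#' Generate one labelled dual-stream brushing session
#'
#' Builds the toothbrush (TB) stream region by region — sinusoidal stroke
#' acceleration along the region's stroke axis plus gravity rotated into the
#' sensor frame, orientation jittering slowly around the region anchor — with
#' smooth (spherically interpolated) orientation transitions between regions
#' whose reconstructed angular velocity produces the characteristic
#' transition gyro peaks. The wrist (WR) stream is a rotated, attenuated,
#' lagged copy of the brush dynamics with additional independent noise.
#' Samples carry ground-truth labels: the region id while brushing, 0 during
#' transitions.
#'
#' @param script A [session_script()].
#' @param profiles Region profile tibble from [region_profiles()].
#' @param noise A [noise_model()].
#' @param session_id Identifier stored in the `session_id` column.
#' @return A session tibble (TB and WR rows stacked) with columns
#'   `session_id, placement, t, ax..az, gx..gz, qw..qz, label`.
#' @export
generate_session <- function(script = session_script(),
                             profiles = region_profiles(),
                             noise = noise_model(),
                             session_id = "S01") {
  stopifnot(inherits(script, "session_script"), inherits(noise, "noise_model"))
  if (!all(script$region_sequence %in% profiles$region_id)) {
    stop("profiles must cover every region in the script", call. = FALSE)
  }
  set.seed(script$seed)
  rate <- script$rate_hz
  n_trans <- as.integer(round(script$transition_duration * rate))
  prof <- profiles[match(script$region_sequence, profiles$region_id), ]
  anchor_q <- euler_to_quat(prof$pitch, prof$roll, prof$yaw)

  quat <- list(); labels <- list(); stroke <- list()
  for (k in seq_len(nrow(prof))) {
    n_b <- as.integer(round(rate * script$strokes_per_region / prof$stroke_freq[k]))
    tt <- (seq_len(n_b) - 1) / rate
    jit <- cbind(
      ar1_noise(n_b, noise$quat_jitter_sd),
      ar1_noise(n_b, noise$quat_jitter_sd),
      ar1_noise(n_b, noise$quat_jitter_sd)
    )
    eu0 <- quat_to_euler(anchor_q[k, , drop = FALSE])
    q_b <- euler_to_quat(eu0$pitch + jit[, 1], eu0$roll + jit[, 2], eu0$yaw + jit[, 3])
    axis <- c(prof$axis_x[k], prof$axis_y[k], prof$axis_z[k])
    s_b <- outer(prof$acc_amplitude[k] * sin(2 * pi * prof$stroke_freq[k] * tt), axis)
    quat[[length(quat) + 1L]] <- q_b
    stroke[[length(stroke) + 1L]] <- s_b
    labels[[length(labels) + 1L]] <- rep(prof$region_id[k], n_b)
    if (k < nrow(prof) && n_trans > 0) {
      u <- smoothstep(seq_len(n_trans) / (n_trans + 1))
      q_t <- quat_slerp(anchor_q[k, ], anchor_q[k + 1, ], u)
      quat[[length(quat) + 1L]] <- q_t
      stroke[[length(stroke) + 1L]] <- matrix(0, n_trans, 3)
      labels[[length(labels) + 1L]] <- rep(0L, n_trans)
    }
  }
  q <- do.call(rbind, quat)
  stroke <- do.call(rbind, stroke)
  label <- unlist(labels)
  n <- nrow(q)

  # gravity in the sensor frame: world -> body rotation is the conjugate
  grav <- quat_rotate(quat_conjugate(q), matrix(GRAVITY, n, 3, byrow = TRUE))
  acc_tb <- grav + stroke + matrix(stats::rnorm(3 * n, 0, noise$acc_noise_sd), n, 3)
  gyro_tb <- quat_to_gyro(q, rate) +
    matrix(stats::rnorm(3 * n, 0, noise$gyro_noise_sd), n, 3)

  # wrist: fixed mounting rotation, attenuated lagged dynamics, extra noise
  q_off <- euler_to_quat(15, 25, -10)
  lag_idx <- pmax(seq_len(n) - noise$wrist_lag, 1L)
  R_off_t <- function(v) quat_rotate(quat_conjugate(q_off), v)
  acc_wr <- R_off_t(grav[lag_idx, , drop = FALSE] +
                      noise$wrist_attenuation * stroke[lag_idx, , drop = FALSE]) +
    matrix(stats::rnorm(3 * n, 0, noise$acc_noise_sd), n, 3)
  gyro_wr <- R_off_t(noise$wrist_attenuation * quat_to_gyro(q, rate)[lag_idx, , drop = FALSE]) +
    matrix(stats::rnorm(3 * n, 0, noise$gyro_noise_sd), n, 3)
  wr_jit <- cbind(
    ar1_noise(n, noise$quat_jitter_sd),
    ar1_noise(n, noise$quat_jitter_sd),
    ar1_noise(n, noise$quat_jitter_sd)
  )
  q_wr_base <- quat_multiply(q[lag_idx, , drop = FALSE], q_off)
  eu_wr <- quat_to_euler(q_wr_base)
  q_wr <- euler_to_quat(
    pmin(pmax(eu_wr$pitch + wr_jit[, 1], -89.9), 89.9),
    eu_wr$roll + wr_jit[, 2],
    eu_wr$yaw + wr_jit[, 3]
  )

  t <- (seq_len(n) - 1) / rate
  mk <- function(placement, acc, gyr, qm) {
    dimnames(acc) <- NULL; dimnames(gyr) <- NULL; dimnames(qm) <- NULL
    tibble::tibble(
      session_id = session_id, placement = placement, t = t,
      ax = acc[, 1], ay = acc[, 2], az = acc[, 3],
      gx = gyr[, 1], gy = gyr[, 2], gz = gyr[, 3],
      qw = qm[, 1], qx = qm[, 2], qy = qm[, 3], qz = qm[, 4],
      label = as.integer(label)
    )
  }
  dplyr::bind_rows(mk("TB", acc_tb, gyro_tb, q), mk("WR", acc_wr, gyro_wr, q_wr))
}

#' Generate a multi-session dataset with intra-subject variability
#'
#' Produces `n_sessions` sessions with per-session seeds `base_seed + i` and
#' small per-session perturbations of the region anchors and stroke
#' frequencies, emulating day-to-day variability of a single subject brushing
#' to the same script.
#'
#' @param n_sessions Number of sessions (>= 2 so leave-one-session-out
#'   evaluation is possible). Default 10, the shipped desk-scale regime.
#' @param base_seed Integer; drives all randomness.
#' @param script,profiles,noise Shared session parameters (see
#'   [session_script()], [region_profiles()], [noise_model()]).
#' @param anchor_jitter_sd Per-session anchor perturbation, degrees.
#' @param freq_jitter Relative per-session stroke-frequency perturbation.
#' @return One session tibble with all sessions stacked (`session_id` column
#'   distinguishes them).
#' @export
generate_dataset <- function(n_sessions = 10, base_seed = 1L,
                             script = session_script(),
                             profiles = region_profiles(),
                             noise = noise_model(),
                             anchor_jitter_sd = 3, freq_jitter = 0.03) {
  if (n_sessions < 2) {
    stop("need at least 2 sessions (leave-one-session-out requires >= 2 folds)",
         call. = FALSE)
  }
  sessions <- lapply(seq_len(n_sessions), function(i) {
    seed_i <- as.integer(base_seed + i)
    set.seed(seed_i)
    prof_i <- profiles
    prof_i$pitch <- prof_i$pitch + stats::rnorm(nrow(prof_i), 0, anchor_jitter_sd)
    prof_i$roll <- prof_i$roll + stats::rnorm(nrow(prof_i), 0, anchor_jitter_sd)
    prof_i$yaw <- prof_i$yaw + stats::rnorm(nrow(prof_i), 0, anchor_jitter_sd)
    prof_i$stroke_freq <- prof_i$stroke_freq *
      (1 + stats::rnorm(nrow(prof_i), 0, freq_jitter))
    script_i <- script
    script_i$seed <- seed_i
    generate_session(script_i, prof_i, noise,
                     session_id = sprintf("S%02d", i))
  })
  dplyr::bind_rows(sessions)
}
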