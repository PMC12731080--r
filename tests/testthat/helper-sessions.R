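# Small, fast session fixtures built in code. A "mini" script uses fewer
# regions and strokes than the full protocol so unit tests stay quick; the
# full default script is exercised in the acceptance tests.

mini_script <- function(seed = 1L, regions = c(1L, 4L, 7L, 10L, 14L, 18L),
                        strokes = 6, transition = 1) {
  session_script(
    region_sequence = regions, strokes_per_region = strokes,
    transition_duration = transition, seed = seed
  )
}

mini_dataset <- function(n_sessions = 3, base_seed = 10L, noise = noise_model(),
                         regions = c(1L, 4L, 7L, 10L, 14L, 18L)) {
  generate_dataset(
    n_sessions = n_sessions, base_seed = base_seed,
    script = mini_script(regions = regions), noise = noise,
    profiles = region_profiles()
  )
}

noise_free <- function() {
  noise_model(acc_noise_sd = 0, gyro_noise_sd = 0, quat_jitter_sd = 0,
              wrist_attenuation = 1, wrist_lag = 0)
}

# Independent Euler oracle: quaternion -> rotation matrix -> Z-Y-X angles.
rotmat_euler <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
  c(
    pitch = asin(min(max(-R[3, 1], -1), 1)),
    roll = atan2(R[3, 2], R[3, 3]),
    yaw = atan2(R[2, 1], R[1, 1])
  ) * 180 / pi
}

# Brute-force contextual-smoothing oracle: per-run scan written independently
# of the package implementation (no rle; explicit neighbour search).
smooth_oracle <- function(x, max_island = 2) {
  n <- length(x)
  out <- x
  i <- 1
  while (i <= n) {
    j <- i
    while (j < n && x[j + 1] == x[i]) j <- j + 1
    if (i > 1 && j < n && (j - i + 1) <= max_island && x[i - 1] == x[j + 1]) {
      out[i:j] <- x[i - 1]
    }
    i <- j + 1
  }
  out
}
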