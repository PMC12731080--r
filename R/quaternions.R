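# Quaternion helpers. Convention: q = (qw, qx, qy, qz), unit norm, Hamilton
# product, body-to-world rotation, aerospace (yaw-pitch-roll, Z-Y'-X'') Euler
# sequence. Euler angles are in degrees throughout the package.

#' Convert unit quaternions to Euler angles
#'
#' Computes pitch, roll and yaw (in degrees) from orientation quaternions using
#' the aerospace yaw-pitch-roll convention:
#' pitch = asin(2(qw qy - qz qx)),
#' roll  = atan2(2(qw qx + qy qz), 1 - 2(qx^2 + qy^2)),
#' yaw   = atan2(2(qw qz + qx qy), 1 - 2(qy^2 + qz^2)).
#' Quaternions are re-normalised on input; the asin argument is clamped to
#' \[-1, 1\] so that gimbal-lock orientations (|pitch| = 90 degrees) return
#' finite angles.
#'
#' @param quat Numeric matrix with 4 columns (qw, qx, qy, qz), or a length-4
#'   vector for a single quaternion.
#' @return A tibble with columns `pitch`, `roll`, `yaw` in degrees, one row per
#'   input quaternion.
#' @examples
#' quat_to_euler(c(1, 0, 0, 0))
#' quat_to_euler(c(sqrt(2) / 2, sqrt(2) / 2, 0, 0)) # 90 degree roll
#' @export
quat_to_euler <- function(quat) {
  q <- as_quat_matrix(quat)
  nrm <- sqrt(rowSums(q^2))
  if (any(!is.finite(nrm)) || any(nrm < 1e-12)) {
    stop("quaternions must be finite and non-zero", call. = FALSE)
  }
  q <- q / nrm
  qw <- q[, 1]; qx <- q[, 2]; qy <- q[, 3]; qz <- q[, 4]
  s <- pmin(pmax(2 * (qw * qy - qz * qx), -1), 1)
  pitch <- asin(s)
  roll <- atan2(2 * (qw * qx + qy * qz), 1 - 2 * (qx^2 + qy^2))
  yaw <- atan2(2 * (qw * qz + qx * qy), 1 - 2 * (qy^2 + qz^2))
  tibble::tibble(
    pitch = pitch * 180 / pi,
    roll = roll * 180 / pi,
    yaw = yaw * 180 / pi
  )
}

#' Convert Euler angles to unit quaternions
#'
#' Inverse of [quat_to_euler()] (away from gimbal lock), using the same
#' yaw-pitch-roll rotation sequence.
#'
#' @param pitch,roll,yaw Angles in degrees (vectorised).
#' @return Numeric matrix with columns qw, qx, qy, qz; rows are unit
#'   quaternions.
#' @export
euler_to_quat <- function(pitch, roll, yaw) {
  hp <- pitch * pi / 360; hr <- roll * pi / 360; hy <- yaw * pi / 360
  cp <- cos(hp); sp <- sin(hp)
  cr <- cos(hr); sr <- sin(hr)
  cy <- cos(hy); sy <- sin(hy)
  q <- cbind(
    qw = cr * cp * cy + sr * sp * sy,
    qx = sr * cp * cy - cr * sp * sy,
    qy = cr * sp * cy + sr * cp * sy,
    qz = cr * cp * sy - sr * sp * cy
  )
  q / sqrt(rowSums(q^2))
}

as_quat_matrix <- function(quat) {
  if (is.null(dim(quat))) {
    if (length(quat) != 4) stop("a quaternion has 4 components", call. = FALSE)
    quat <- matrix(quat, nrow = 1)
  }
  quat <- as.matrix(quat)
  if (ncol(quat) != 4) stop("quaternion matrix must have 4 columns", call. = FALSE)
  storage.mode(quat) <- "double"
  quat
}

# Hamilton product of two quaternion matrices (row-wise, recycled).
quat_multiply <- function(a, b) {
  a <- as_quat_matrix(a); b <- as_quat_matrix(b)
  n <- max(nrow(a), nrow(b))
  if (nrow(a) == 1) a <- a[rep(1, n), , drop = FALSE]
  if (nrow(b) == 1) b <- b[rep(1, n), , drop = FALSE]
  cbind(
    a[, 1] * b[, 1] - a[, 2] * b[, 2] - a[, 3] * b[, 3] - a[, 4] * b[, 4],
    a[, 1] * b[, 2] + a[, 2] * b[, 1] + a[, 3] * b[, 4] - a[, 4] * b[, 3],
    a[, 1] * b[, 3] - a[, 2] * b[, 4] + a[, 3] * b[, 1] + a[, 4] * b[, 2],
    a[, 1] * b[, 4] + a[, 2] * b[, 3] - a[, 3] * b[, 2] + a[, 4] * b[, 1]
  )
}

quat_conjugate <- function(q) {
  q <- as_quat_matrix(q)
  cbind(q[, 1], -q[, 2], -q[, 3], -q[, 4])
}

# Spherical linear interpolation between two unit quaternions at fractions u.
quat_slerp <- function(q0, q1, u) {
  q0 <- as.numeric(q0); q1 <- as.numeric(q1)
  d <- sum(q0 * q1)
  if (d < 0) { q1 <- -q1; d <- -d }
  d <- min(d, 1)
  if (d > 1 - 1e-10) {
    out <- outer(1 - u, q0) + outer(u, q1)
  } else {
    th <- acos(d)
    out <- outer(sin((1 - u) * th) / sin(th), q0) + outer(sin(u * th) / sin(th), q1)
  }
  out / sqrt(rowSums(out^2))
}

# Body-frame angular velocity (rad/s) reconstructed from consecutive
# orientation quaternions: omega_t ~ 2 * Im(q_t^-1 q_{t+1}) * rate.
# The last sample repeats the previous one to keep the length.
quat_to_gyro <- function(q, rate_hz) {
  n <- nrow(q)
  if (n < 2) return(matrix(0, n, 3))
  dq <- quat_multiply(quat_conjugate(q[-n, , drop = FALSE]), q[-1, , drop = FALSE])
  flip <- dq[, 1] < 0
  dq[flip, ] <- -dq[flip, ]
  w <- pmin(pmax(dq[, 1], -1), 1)
  ang <- 2 * acos(w)
  vn <- sqrt(rowSums(dq[, 2:4, drop = FALSE]^2))
  axis <- dq[, 2:4, drop = FALSE] / ifelse(vn > 1e-12, vn, 1)
  omega <- axis * ang * rate_hz
  omega[vn <= 1e-12, ] <- 0
  rbind(omega, omega[n - 1, , drop = FALSE])
}

# Rotate body-frame vectors v (n x 3) by quaternions q (n x 4): world = R v.
quat_rotate <- function(q, v) {
  qv <- cbind(0, v)
  out <- quat_multiply(quat_multiply(q, qv), quat_conjugate(q))
  out[, 2:4, drop = FALSE]
}
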