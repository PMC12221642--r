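# Small 3D rotation toolbox. Rotations are 3x3 proper orthonormal
# matrices mapping head-frame coordinates into world coordinates
# (columns = world coordinates of the head X, Y, Z axes).

vnorm <- function(v) sqrt(sum(v * v))

normalize3 <- function(v) {
  n <- vnorm(v)
  if (n < .Machine$double.eps) stop("cannot normalize a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Geodesic angle (rad) between two rotations.
rot_angle <- function(R1, R2) {
  tr <- sum(diag(crossprod(R1, R2)))
  acos(max(-1, min(1, (tr - 1) / 2)))
}

# Angle (rad) between two 3-vectors.
vec_angle <- function(a, b) {
  ca <- sum(a * b) / (vnorm(a) * vnorm(b))
  acos(max(-1, min(1, ca)))
}

# Rotation matrix -> rotation vector (axis * angle, rad).
rot_to_vec <- function(R) {
  ang <- acos(max(-1, min(1, (sum(diag(R)) - 1) / 2)))
  if (ang < 1e-12) return(c(0, 0, 0))
  if (abs(pi - ang) < 1e-6) {
    # near pi: axis from the symmetric part
    B <- (R + diag(3)) / 2
    axis <- sqrt(pmax(0, diag(B)))
    # fix signs from off-diagonals
    if (axis[1] > 0) {
      axis[2] <- sign(B[1, 2]) * axis[2]
      axis[3] <- sign(B[1, 3]) * axis[3]
    } else if (axis[2] > 0) {
      axis[3] <- sign(B[2, 3]) * axis[3]
    }
    return(normalize3(axis) * ang)
  }
  axis <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) /
    (2 * sin(ang))
  axis * ang
}

# Rotation vector -> rotation matrix (Rodrigues).
vec_to_rot <- function(v) {
  ang <- vnorm(v)
  if (ang < 1e-12) return(diag(3))
  k <- v / ang
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
}

# Nearest proper rotation to an arbitrary 3x3 matrix (SVD projection).
orthonormalize_rot <- function(M) {
  s <- svd(M)
  R <- s$u %*% t(s$v)
  if (det(R) < 0) {
    u <- s$u
    u[, 3] <- -u[, 3]
    R <- u %*% t(s$v)
  }
  R
}

# Geodesic interpolation R(t) between R0 (t=0) and R1 (t=1).
rot_slerp <- function(R0, R1, t) {
  d <- rot_to_vec(crossprod(R0, R1))
  R0 %*% vec_to_rot(d * t)
}

# Rotation about a given axis by an angle (rad).
rot_about <- function(axis, ang) vec_to_rot(normalize3(axis) * ang)
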