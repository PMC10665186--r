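## Rotation and Euler-angle utilities.
##
## Two conventions are used package-wide and nowhere else:
##  * particle orientations (rot, tilt, psi): R = Rz(psi) %*% Ry(tilt) %*% Rz(rot),
##    the common subtomogram-averaging Z-Y-Z convention. The body z axis in the
##    lab frame is (cos(psi) sin(tilt), sin(psi) sin(tilt), cos(tilt)), so a
##    filament tangent determines tilt and psi while rot (spin about the
##    tangent) stays free.
##  * crown poses (alpha, beta, gamma): intrinsic Z-Y-X,
##    R = Rz(alpha) %*% Ry(beta) %*% Rx(gamma), expressed in the local
##    cylinder frame (x tangential, y radial outward, z axial).
## All angles are degrees, normalized to (-180, 180].

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Normalize angles in degrees to the interval (-180, 180]
#'
#' @param x numeric vector of angles in degrees.
#' @return numeric vector of the same length with each angle reduced modulo
#'   360 into (-180, 180].
#' @export
normalize_angle <- function(x) {
  y <- x %% 360
  hi <- !is.na(y) & y > 180
  y[hi] <- y[hi] - 360
  ## map -180 (from y == 180 boundary handled above) onto +180
  y[!is.na(y) & y == -180] <- 180
  y
}

rot_x <- function(deg) {
  t <- deg2rad(deg); c <- cos(t); s <- sin(t)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3)
}

rot_y <- function(deg) {
  t <- deg2rad(deg); c <- cos(t); s <- sin(t)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
}

rot_z <- function(deg) {
  t <- deg2rad(deg); c <- cos(t); s <- sin(t)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

#' Rotation matrix from intrinsic Z-Y-X Euler angles
#'
#' Used for crown poses: `R = Rz(alpha) %*% Ry(beta) %*% Rx(gamma)`.
#'
#' @param alpha,beta,gamma angles in degrees.
#' @return a 3x3 rotation matrix.
#' @export
euler_zyx_to_mat <- function(alpha, beta, gamma) {
  rot_z(alpha) %*% rot_y(beta) %*% rot_x(gamma)
}

#' Euler angles (intrinsic Z-Y-X) from a rotation matrix
#'
#' Inverse of [euler_zyx_to_mat()]. Near gimbal lock (|beta| within `gimbal_tol`
#' degrees of 90) only the sum/difference of alpha and gamma is determined;
#' gamma is then set to 0 and the result carries attribute `gimbal = TRUE`.
#'
#' @param R a 3x3 rotation matrix.
#' @param gimbal_tol degrees; closeness of |beta| to 90 that triggers the
#'   degenerate branch (default 0.1).
#' @return named numeric vector `c(alpha, beta, gamma)` in degrees, each in
#'   (-180, 180].
#' @export
mat_to_euler_zyx <- function(R, gimbal_tol = 0.1) {
  sy <- -R[3, 1]
  sy <- max(-1, min(1, sy))
  beta <- rad2deg(asin(sy))
  gimbal <- abs(abs(beta) - 90) < gimbal_tol
  if (gimbal) {
    ## beta ~ +/-90: alpha and gamma degenerate; report combined angle as alpha
    alpha <- rad2deg(atan2(-R[1, 2], R[2, 2]))
    gamma <- 0
  } else {
    alpha <- rad2deg(atan2(R[2, 1], R[1, 1]))
    gamma <- rad2deg(atan2(R[3, 2], R[3, 3]))
  }
  out <- c(alpha = normalize_angle(alpha), beta = normalize_angle(beta),
           gamma = normalize_angle(gamma))
  attr(out, "gimbal") <- gimbal
  out
}

#' Rotation matrix from particle orientation angles (Z-Y-Z)
#'
#' `R = Rz(psi) %*% Ry(tilt) %*% Rz(rot)`; the matrix maps body-frame vectors
#' into the lab frame.
#'
#' @param rot,tilt,psi angles in degrees.
#' @return a 3x3 rotation matrix.
#' @export
euler_zyz_to_mat <- function(rot, tilt, psi) {
  rot_z(psi) %*% rot_y(tilt) %*% rot_z(rot)
}

#' Particle orientation angles (Z-Y-Z) from a rotation matrix
#'
#' Inverse of [euler_zyz_to_mat()]. When tilt is within `tol` of 0 or 180 the
#' psi/rot pair degenerates; rot is set to 0 and attribute `gimbal = TRUE` is
#' attached.
#'
#' @param R a 3x3 rotation matrix.
#' @param tol degrees (default 1e-6).
#' @return named numeric vector `c(rot, tilt, psi)` in degrees.
#' @export
mat_to_euler_zyz <- function(R, tol = 1e-6) {
  ct <- max(-1, min(1, R[3, 3]))
  tilt <- rad2deg(acos(ct))
  gimbal <- tilt < tol || tilt > 180 - tol
  if (gimbal) {
    psi <- rad2deg(atan2(R[2, 1], R[1, 1]))
    rot <- 0
  } else {
    psi <- rad2deg(atan2(R[2, 3], R[1, 3]))
    rot <- rad2deg(atan2(R[3, 2], -R[3, 1]))
  }
  out <- c(rot = normalize_angle(rot), tilt = normalize_angle(tilt),
           psi = normalize_angle(psi))
  attr(out, "gimbal") <- gimbal
  out
}

## unit vector, erroring on (near-)zero input
unit_vec <- function(v, what = "vector") {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalize near-zero ", what)
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

## random rotation matrix (uniform via QR of Gaussian), used by tests
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
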