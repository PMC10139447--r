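# Head frame: right-handed, x rightward, y up, z forward (into the scene).
# All 3-D positions are in centimeters; all angles cross the API in degrees.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Helmholtz direction vector from azimuth/elevation
#'
#' Helmholtz coordinates measure azimuth by latitude and elevation by
#' longitude: the elevation rotation (about the interaural x axis) is applied
#' first, then azimuth. The forward direction is `(0, 0, 1)`; positive
#' azimuth points rightward, positive elevation upward.
#'
#' @param az,el Azimuth and elevation in degrees (vectors of equal length,
#'   or one may be length 1).
#' @return An `n x 3` matrix of unit direction vectors `(x, y, z)`.
#' @examples
#' helm_dir(0, 0)            # straight ahead
#' helm_dir(10, 0)           # 10 deg right
#' @export
helm_dir <- function(az, el) {
  a <- deg2rad(az); e <- deg2rad(el)
  n <- max(length(a), length(e))
  a <- rep_len(a, n); e <- rep_len(e, n)
  cbind(x = sin(a), y = cos(a) * sin(e), z = cos(a) * cos(e))
}

#' Helmholtz azimuth/elevation of direction vectors
#'
#' Inverse of [helm_dir()]. Azimuth is the latitude `atan2(x, sqrt(y^2+z^2))`
#' (range +/-90 deg); elevation is the longitude `atan2(y, z)`.
#'
#' @param v An `n x 3` matrix (or length-3 vector) of directions; need not
#'   be unit length.
#' @return A data.frame with columns `az` and `el` in degrees.
#' @export
helm_angles <- function(v) {
  v <- rbind3(v)
  data.frame(az = rad2deg(atan2(v[, 1], sqrt(v[, 2]^2 + v[, 3]^2))),
             el = rad2deg(atan2(v[, 2], v[, 3])))
}

# coerce a length-3 vector to a 1x3 matrix
rbind3 <- function(v) {
  if (is.null(dim(v))) matrix(v, ncol = 3) else v
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

# Rodrigues rotation about a unit axis by `deg` degrees.
rot_axis_angle <- function(axis, deg) {
  axis <- axis / sqrt(sum(axis^2))
  t <- deg2rad(deg)
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(t) * K + (1 - cos(t)) * (K %*% K)
}

#' Angle between direction vectors
#'
#' @param u,v `n x 3` matrices (or length-3 vectors) of directions.
#' @return Angles in degrees, elementwise.
#' @export
angle_between <- function(u, v) {
  u <- rbind3(u); v <- rbind3(v)
  n <- max(nrow(u), nrow(v))
  if (nrow(u) == 1L) u <- u[rep(1L, n), , drop = FALSE]
  if (nrow(v) == 1L) v <- v[rep(1L, n), , drop = FALSE]
  dotp <- rowSums(u * v)
  cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  rad2deg(atan2(sqrt(rowSums(cr^2)), dotp))
}

# Rotation whose forward axis is the Helmholtz (az, el) gaze direction:
# R = R_x(-el) %*% R_y(az) maps eye-frame (0,0,1) to helm_dir(az, el).
helm_rotation <- function(az, el) rot_x(-el) %*% rot_y(az)

# Decompose a rotation as R_x(-el) %*% R_y(az) %*% R_z(torsion); returns the
# Helmholtz gaze angles plus the residual cycloduction (torsion) in degrees.
helm_decompose <- function(R) {
  fwd <- R %*% c(0, 0, 1)
  ang <- helm_angles(t(fwd))
  M <- t(helm_rotation(ang$az, ang$el)) %*% R
  list(az = ang$az, el = ang$el, torsion = rad2deg(atan2(M[2, 1], M[1, 1])))
}
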