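#' Ocular kinematics: fixation poses with Listing's extended law (L2)
#'
#' An eye pose is the rigid orientation of one eye: a rotation `R` taking
#' eye-frame vectors into the head frame (the eye-frame forward axis maps to
#' the visual axis), the eye center (cm, head frame) and the residual
#' cycloduction (torsion, deg) relative to the Helmholtz gaze parameterization.
#'
#' Listing's law states that, with the head upright and gaze far, eye
#' orientations are rotations from primary position about axes confined to a
#' plane (Listing's plane). During convergence the laws extends (L2): each
#' eye's Listing plane rotates *temporally* by `gain/2` times the vergence
#' angle, with gain about 0.8 in observers with normal binocular vision. The
#' implementation composes exact rotations: the primary direction of each
#' eye is yawed temporally by `(gain/2) * vergence`, and the eye orientation
#' is the single rotation about an axis in the rotated Listing plane that
#' carries the rotated primary direction to the target direction. At zero
#' vergence (gain irrelevant) this reduces to pure Listing's law.
#'
#' @name eye-pose
NULL

#' Vergence angle at a fixation point
#'
#' Angle between the two eyes' visual axes when both fixate `fixation`.
#'
#' @param fixation Fixation point, head frame, cm.
#' @param iod Inter-ocular distance, cm.
#' @param origin Midpoint of the eye centers (default head origin).
#' @return Vergence in degrees (0 for infinitely far fixation).
#' @export
vergence_angle <- function(fixation, iod = 6.33, origin = c(0, 0, 0)) {
  eL <- origin + c(-iod / 2, 0, 0); eR <- origin + c(iod / 2, 0, 0)
  angle_between(fixation - eL, fixation - eR)
}

# single-eye pose: rotation carrying the yawed primary direction to the
# target direction, about an axis perpendicular to both (Listing construction)
.listing_pose <- function(center, fixation, primary_yaw_deg) {
  v <- fixation - center
  if (v[3] <= 0) stop("fixation behind the eyes")
  v <- v / sqrt(sum(v^2))
  Rp <- rot_y(primary_yaw_deg)
  p <- as.numeric(Rp %*% c(0, 0, 1))
  ax <- c(p[2] * v[3] - p[3] * v[2],
          p[3] * v[1] - p[1] * v[3],
          p[1] * v[2] - p[2] * v[1])
  s <- sqrt(sum(ax^2))
  R <- if (s < 1e-14) Rp
       else rot_axis_angle(ax, rad2deg(atan2(s, sum(p * v)))) %*% Rp
  dec <- helm_decompose(R)
  structure(list(R = R, center = center, torsion = dec$torsion,
                 az = dec$az, el = dec$el),
            class = "eye_pose")
}

#' Pose both eyes on a fixation point under L2
#'
#' @param fixation Fixation point, head frame, cm (must be in front of both
#'   eyes).
#' @param iod Inter-ocular distance, cm.
#' @param listing_gain L2 gain (0 = pure Listing's law; default 0.8).
#' @param origin Midpoint of the eye centers, cm.
#' @return List with `left` and `right` `eye_pose` objects and the
#'   `vergence` (deg).
#' @examples
#' p <- eye_poses(c(0, 0, 50))          # converged 50 cm straight ahead
#' c(p$left$torsion, p$right$torsion)   # zero at zero elevation
#' @export
eye_poses <- function(fixation, iod = 6.33, listing_gain = 0.8,
                      origin = c(0, 0, 0)) {
  verg <- vergence_angle(fixation, iod, origin)
  delta <- listing_gain / 2 * verg
  eL <- origin + c(-iod / 2, 0, 0); eR <- origin + c(iod / 2, 0, 0)
  # temporal = leftward (negative yaw) for the left eye, rightward for right
  list(left = .listing_pose(eL, fixation, -delta),
       right = .listing_pose(eR, fixation, +delta),
       vergence = verg, fixation = fixation, iod = iod,
       listing_gain = listing_gain)
}

#' Cyclopean reference pose
#'
#' Pure Listing's-law pose at the midpoint of the eye centers, used to
#' assign visual-field positions (the cyclopean eye has no temporal side,
#' so no Listing-plane rotation is applied).
#'
#' @inheritParams eye_poses
#' @return An `eye_pose`.
#' @export
cyclopean_pose <- function(fixation, origin = c(0, 0, 0)) {
  .listing_pose(origin, fixation, 0)
}

#' @export
print.eye_pose <- function(x, ...) {
  cat(sprintf("eye_pose: gaze (%.2f, %.2f) deg, torsion %.3f deg, center (%.2f, %.2f, %.2f) cm\n",
              x$az, x$el, x$torsion, x$center[1], x$center[2], x$center[3]))
  invisible(x)
}

#' Project head-frame points into an eye's Helmholtz coordinates
#'
#' Each point is expressed in the eye frame (`q = R^T (P - center)`) and
#' converted to Helmholtz angles: azimuth = latitude, elevation = longitude.
#' The fixation point of the pose maps to (0, 0).
#'
#' @param points `n x 3` matrix of head-frame points, cm.
#' @param pose An `eye_pose`.
#' @return data.frame with `az`, `el` in degrees.
#' @export
project_to_eye <- function(points, pose) {
  q <- sweep(rbind3(points), 2, pose$center) %*% pose$R
  if (any(rowSums(q^2) < 1e-20)) stop("point coincident with eye center")
  helm_angles(q)
}
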