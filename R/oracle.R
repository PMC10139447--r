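#' Exact ray-casting disparity oracle
#'
#' Brute-force reference for the depth-buffer disparity pipeline: for each
#' requested field direction a cyclopean ray is cast directly against the
#' scene primitives (no depth-buffer discretization), and the hit point's
#' Helmholtz direction in each eye is computed by per-point trigonometry
#' under exactly the same L2 eye poses used by the pipeline. A sample is
#' undefined when the cyclopean ray misses the scene or when either eye's
#' view of the hit point is blocked by a nearer primitive (shadow-ray
#' test).
#'
#' @param scene A `scene_spec`.
#' @param fixation Fixation point, head frame, cm (in front of both eyes;
#'   it need not lie on a scene surface).
#' @param grid data.frame with `az`, `el`: field directions (deg) in the
#'   cyclopean reference frame, e.g. expand.grid over a [field_grid()]'s
#'   centers.
#' @param iod Inter-ocular distance, cm.
#' @param listing_gain L2 gain.
#' @param origin Midpoint of the eye centers, cm.
#' @return A `disparity_samples` data.frame (same contract as
#'   [disparity_field()]).
#' @export
ground_truth_disparity <- function(scene, fixation, grid, iod = 6.33,
                                   listing_gain = 0.8, origin = c(0, 0, 0)) {
  poses <- eye_poses(fixation, iod = iod, listing_gain = listing_gain,
                     origin = origin)
  cyc <- cyclopean_pose(fixation, origin = origin)
  dirs <- helm_dir(grid$az, grid$el) %*% t(cyc$R)
  hit <- ray_cast(scene, matrix(origin, 1, 3), dirs)
  n <- nrow(grid)
  hdisp <- vdisp <- rep(NA_real_, n)
  defined <- is.finite(hit$t)
  if (any(defined)) {
    P <- sweep(dirs[defined, , drop = FALSE] * hit$t[defined], 2, origin, `+`)
    vis <- function(pose) {
      rel <- sweep(P, 2, pose$center)
      d <- sqrt(rowSums(rel^2))
      sh <- ray_cast(scene, matrix(pose$center, 1, 3), rel / d)
      !(is.finite(sh$t) & sh$t < d * (1 - 1e-6))
    }
    both <- vis(poses$left) & vis(poses$right)
    aL <- project_to_eye(P, poses$left)
    aR <- project_to_eye(P, poses$right)
    h <- ifelse(both, aL$az - aR$az, NA_real_)
    v <- ifelse(both, aL$el - aR$el, NA_real_)
    hdisp[defined] <- h; vdisp[defined] <- v
    defined[defined] <- both
  }
  out <- data.frame(az = grid$az, el = grid$el, hdisp = hdisp,
                    vdisp = vdisp, defined = defined)
  class(out) <- c("disparity_samples", "data.frame")
  out
}
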