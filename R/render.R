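#' Render a view-space depth frame of a scene
#'
#' Casts one ray per pixel from the camera position and records the
#' *view-space* depth of the nearest primitive: the distance along the
#' camera's optical axis (the z coordinate of the hit point in the camera
#' frame), not the ray length. Pixels hitting nothing, or hitting beyond the
#' far plane, carry the far value; hits in front of the near plane are
#' clamped to `near`.
#'
#' @param scene A `scene_spec` with at least one primitive.
#' @param camera A [camera_model()].
#' @param head_pose Optional camera pose: list with `R` (3x3 rotation,
#'   head-from-camera) and `t` (camera position in head frame, cm).
#'   Default: camera at the head origin looking along +z.
#' @param timestamp Frame timestamp in seconds.
#' @return A [depth_frame()], values in meters.
#' @export
render_depth <- function(scene, camera, head_pose = NULL, timestamp = 0) {
  if (!length(scene$primitives)) stop("scene has no primitives")
  if (is.null(head_pose)) head_pose <- list(R = diag(3), t = c(0, 0, 0))
  dirs_cam <- pixel_directions(camera)
  dims <- attr(dirs_cam, "dim_px")
  dirs_head <- dirs_cam %*% t(head_pose$R)
  hit <- ray_cast(scene, matrix(head_pose$t, 1, 3), dirs_head)
  # axial (view-space) depth in meters: ray length times the camera-frame
  # z component of the unit ray direction
  z_m <- hit$t * dirs_cam[, 3] / 100
  z_m[!is.finite(z_m) | z_m > camera$far] <- camera$far
  z_m <- pmax(z_m, camera$near)
  depth_frame(matrix(z_m, dims[1], dims[2]), camera, timestamp)
}
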