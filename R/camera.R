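#' Pinhole camera model for depth buffers
#'
#' Describes the virtual camera that produced (or will produce) a depth
#' buffer: pixel resolution, horizontal/vertical fields of view and the
#' near/far clipping distances used by the nonlinear depth encoding.
#' The default resolution matches the 4x-down-sampled 363 x 403 depth
#' textures used for acquisition; when `vfov` is omitted it is derived from
#' `hfov` assuming square pixels.
#'
#' @param width,height Resolution in pixels.
#' @param hfov Horizontal field of view in degrees, in (0, 180).
#' @param vfov Vertical field of view in degrees, or `NULL` for square
#'   pixels: `vfov = 2 atan(tan(hfov/2) * height / width)`.
#' @param near,far Clipping distances in meters, `0 < near < far`.
#' @return An object of class `camera_model`.
#' @examples
#' cam <- camera_model()
#' cam$resolution
#' @export
camera_model <- function(width = 363L, height = 403L, hfov = 90,
                         vfov = NULL, near = 0.3, far = 50) {
  stopifnot(width >= 1, height >= 1, near > 0, far > near,
            hfov > 0, hfov < 180)
  if (is.null(vfov))
    vfov <- 2 * rad2deg(atan(tan(deg2rad(hfov / 2)) * height / width))
  stopifnot(vfov > 0, vfov < 180)
  structure(list(resolution = c(width = as.integer(width),
                                height = as.integer(height)),
                 hfov = hfov, vfov = vfov, near = near, far = far),
            class = "camera_model")
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf("camera_model: %d x %d px, fov %.1f x %.1f deg, near %.2f m, far %.1f m\n",
              x$resolution[1], x$resolution[2], x$hfov, x$vfov, x$near, x$far))
  invisible(x)
}

# Unit ray directions through every pixel center, row-major over the image
# grid (row 1 = top of image = highest elevation). Returns an n x 3 matrix
# with attribute "dim_px" = c(height, width).
pixel_directions <- function(camera) {
  w <- camera$resolution[["width"]]; h <- camera$resolution[["height"]]
  tx <- tan(deg2rad(camera$hfov / 2))
  ty <- tan(deg2rad(camera$vfov / 2))
  # pixel centers on the z = 1 image plane
  xs <- tx * (2 * (seq_len(w) - 0.5) / w - 1)
  ys <- ty * (1 - 2 * (seq_len(h) - 0.5) / h)
  d <- cbind(x = rep(xs, each = h), y = rep(ys, times = w), z = 1)
  d <- d / sqrt(rowSums(d^2))
  attr(d, "dim_px") <- c(h, w)
  d
}

#' Construct a depth frame
#'
#' A depth frame stores per-pixel view-space depth in meters: the distance
#' along the camera's optical axis (not the ray length) to the nearest
#' surface. Pixels with no surface carry the far-plane value.
#'
#' @param values Numeric matrix (`height x width`) of depths in meters.
#' @param camera The [camera_model()] that produced the frame.
#' @param timestamp Acquisition time in seconds.
#' @return An object of class `depth_frame`.
#' @export
depth_frame <- function(values, camera, timestamp = 0) {
  stopifnot(is.matrix(values),
            nrow(values) == camera$resolution[["height"]],
            ncol(values) == camera$resolution[["width"]])
  if (any(values < camera$near - 1e-9 | values > camera$far + 1e-9))
    stop("depth values outside [near, far]")
  structure(list(values = values, camera = camera, timestamp = timestamp),
            class = "depth_frame")
}

#' @export
print.depth_frame <- function(x, ...) {
  cat(sprintf("depth_frame: %d x %d px at t=%.3f s, depth range [%.3f, %.3f] m\n",
              ncol(x$values), nrow(x$values), x$timestamp,
              min(x$values), max(x$values)))
  invisible(x)
}
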