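#' Nonlinear 16-bit depth encoding
#'
#' Depth buffers store view-space depth with a reversed projective mapping
#' that allocates precision non-linearly between the clipping planes:
#' `v = far * (z - near) / (z * (far - near))`, scaled to 16-bit integers.
#' The mapping is strictly monotone in `z`, sends `near` to code 0 and `far`
#' to code 65535, and is inverted exactly (up to quantization) by
#' [decode_depth()]. Because the camera's `near`/`far` constants are part of
#' the mapping they are recorded in the session manifest, making the codec
#' self-describing.
#'
#' @param meters Numeric matrix/vector of view-space depths, all within
#'   `[near, far]`.
#' @param camera A [camera_model()] supplying `near` and `far`.
#' @return Integer codes in 0..65535 with the same shape as `meters`.
#' @examples
#' cam <- camera_model(near = 0.3, far = 50)
#' encode_depth(cam$near, cam)   # 0
#' encode_depth(cam$far, cam)    # 65535
#' @export
encode_depth <- function(meters, camera) {
  near <- camera$near; far <- camera$far
  if (any(meters < near - 1e-12 | meters > far + 1e-12))
    stop("depth value outside [near, far]")
  v <- far * (meters - near) / (pmax(meters, near) * (far - near))
  codes <- round(pmin(pmax(v, 0), 1) * 65535)
  storage.mode(codes) <- "integer"
  codes
}

#' Decode 16-bit depth codes to meters
#'
#' Exact inverse of [encode_depth()]'s mapping on representable values:
#' `z = far * near / (far - v * (far - near))` with `v = code / 65535`.
#'
#' @param codes Integer (or numeric) codes in 0..65535.
#' @param camera A [camera_model()].
#' @return Depths in meters, same shape as `codes`.
#' @export
decode_depth <- function(codes, camera) {
  if (any(codes < 0 | codes > 65535)) stop("code outside 16-bit range")
  near <- camera$near; far <- camera$far
  v <- codes / 65535
  z <- far * near / (far - v * (far - near))
  if (is.matrix(codes)) z <- matrix(z, nrow(codes), ncol(codes))
  z
}

#' Analytic quantization bound of the depth codec
#'
#' The worst-case round-trip error at depth `z` is half a code step times
#' the decoding map's derivative, `dz/dv = z^2 (far - near) / (far * near)`,
#' taken at the far end of the half-step interval (the derivative grows
#' with z, so the one-sided sup is the rigorous bound):
#' `|err| <= delta * z'^2 (far-near)/(far*near)` with `delta = 0.5/65535`
#' and `z' = z / (1 - delta (far-near) z / (far near))`.
#'
#' @param meters Depths in meters.
#' @param camera A [camera_model()].
#' @return Maximum absolute round-trip error at each depth, in meters.
#' @export
depth_quantization_bound <- function(meters, camera) {
  near <- camera$near; far <- camera$far
  delta <- 0.5 / 65535
  k <- (far - near) / (far * near)
  delta * k * (meters / (1 - delta * k * meters))^2
}
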