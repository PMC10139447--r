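# Scene reconstruction from depth buffers and Helmholtz retinal disparity
# fields: back-projection, per-eye visibility, disparity computation with
# L2 eye poses, field-map binning, equal-weight pooling across games.

#' Back-project a depth frame to a head-frame point cloud
#'
#' Pinhole inverse of [render_depth()]: each pixel's camera-frame ray is
#' scaled so its axial (z) coordinate equals the stored view-space depth.
#' Far-plane pixels (no surface) are excluded.
#'
#' @param frame A [depth_frame()].
#' @param camera Camera model (default: the frame's own).
#' @param head_pose Optional camera pose (`R`, `t`) as in [render_depth()].
#' @return `n x 3` matrix of points in head coordinates, cm, with attribute
#'   `"pixel"` giving the linear pixel index of each point.
#' @export
backproject <- function(frame, camera = frame$camera, head_pose = NULL) {
  stopifnot(nrow(frame$values) == camera$resolution[["height"]],
            ncol(frame$values) == camera$resolution[["width"]])
  dirs <- pixel_directions(camera)
  z_cm <- as.vector(frame$values) * 100
  keep <- as.vector(frame$values) < camera$far * (1 - 1e-9)
  pts <- dirs[keep, , drop = FALSE] / dirs[keep, 3] * z_cm[keep]
  if (!is.null(head_pose))
    pts <- sweep(pts %*% t(head_pose$R), 2, head_pose$t, `+`)
  attr(pts, "pixel") <- which(keep)
  pts
}

#' Per-eye visibility of a point cloud
#'
#' Emulates natural (half-)occlusion: a point is visible to an eye iff no
#' other cloud point projects into the same angular cell at a meaningfully
#' smaller eye distance. Cell size defaults to the camera pixel pitch (the
#' depth buffer cannot resolve finer occlusions); a relative depth tolerance
#' keeps same-surface neighbours from shadowing each other.
#'
#' @param points `n x 3` cloud, cm.
#' @param poses Eye poses from [eye_poses()].
#' @param pitch_deg Angular cell size, deg (default 90/363, the default
#'   camera's pixel pitch).
#' @param depth_tol Relative depth ratio above which a nearer point in the
#'   same cell occludes (default 1.05).
#' @return `n x 2` logical matrix, columns `left`, `right`.
#' @export
occlusion_masks <- function(points, poses, pitch_deg = 90 / 363,
                            depth_tol = 1.05) {
  points <- rbind3(points)
  if (!nrow(points)) stop("empty point cloud")
  one_eye <- function(pose) {
    ang <- project_to_eye(points, pose)
    dist <- sqrt(rowSums(sweep(points, 2, pose$center)^2))
    key <- paste(floor(ang$az / pitch_deg), floor(ang$el / pitch_deg))
    cellmin <- stats::ave(dist, key, FUN = min)
    dist <= cellmin * depth_tol
  }
  cbind(left = one_eye(poses$left), right = one_eye(poses$right))
}

#' Retinal disparity field of a point cloud
#'
#' Projects every binocularly visible point into both eyes and takes
#' Helmholtz angle differences: horizontal disparity = left azimuth - right
#' azimuth, vertical = left elevation - right elevation. With this sign
#' convention points nearer than fixation have positive (crossed)
#' horizontal disparity. Field positions are the Helmholtz direction of
#' each point from the cyclopean reference pose (pure Listing pose at the
#' midpoint of the eye centers, fixating the same point).
#'
#' @param points `n x 3` cloud, cm.
#' @param poses Eye poses from [eye_poses()] (must carry `fixation`).
#' @param masks Optional visibility matrix from [occlusion_masks()];
#'   `NULL` treats every point as binocularly visible.
#' @return data.frame of class `disparity_samples`: `az`, `el` (field
#'   position, deg), `hdisp`, `vdisp` (deg), `defined`. Undefined records
#'   carry NA disparities.
#' @export
disparity_field <- function(points, poses, masks = NULL) {
  points <- rbind3(points)
  if (is.null(poses$fixation))
    stop("poses must carry the fixation point (use eye_poses())")
  cyc <- cyclopean_pose(poses$fixation,
                        origin = (poses$left$center + poses$right$center) / 2)
  field <- project_to_eye(points, cyc)
  aL <- project_to_eye(points, poses$left)
  aR <- project_to_eye(points, poses$right)
  defined <- if (is.null(masks)) rep(TRUE, nrow(points))
             else masks[, 1] & masks[, 2]
  out <- data.frame(az = field$az, el = field$el,
                    hdisp = ifelse(defined, aL$az - aR$az, NA_real_),
                    vdisp = ifelse(defined, aL$el - aR$el, NA_real_),
                    defined = defined)
  class(out) <- c("disparity_samples", "data.frame")
  out
}

#' Head-centric disparity audit
#'
#' Helmholtz disparities referenced to the head (identity eye orientations
#' at each eye center, no dependence on fixation). Because Helmholtz
#' elevation is the longitude about the interaural axis and the two eye
#' centers differ only along that axis, head-centric *vertical* disparity
#' is identically zero for any scene; a nonzero value signals a geometry
#' bug in rendering or reconstruction. Horizontal head-centric disparity
#' varies with object distance as usual.
#'
#' @param points `n x 3` cloud, cm.
#' @param iod Inter-ocular distance, cm.
#' @param origin Midpoint of the eye centers.
#' @return List: `disparities` (data.frame `hdisp`, `vdisp`, deg),
#'   `max_abs_vertical` and `ok` (TRUE iff max |vertical| < `tol`).
#' @param tol Audit tolerance in degrees (default 1e-9).
#' @export
head_centric_check <- function(points, iod = 6.33, origin = c(0, 0, 0),
                               tol = 1e-9) {
  points <- rbind3(points)
  aL <- helm_angles(sweep(points, 2, origin + c(-iod / 2, 0, 0)))
  aR <- helm_angles(sweep(points, 2, origin + c(iod / 2, 0, 0)))
  d <- data.frame(hdisp = aL$az - aR$az, vdisp = aL$el - aR$el)
  mv <- if (nrow(d)) max(abs(d$vdisp)) else 0
  list(disparities = d, max_abs_vertical = mv, ok = mv < tol)
}

#' Flag pixels adjacent to depth discontinuities
#'
#' Back-projection of a discretized depth buffer is ill-defined exactly at
#' depth edges, so comparisons against the continuous ray-casting oracle
#' exclude a 1-pixel zone around discontinuities: pixels whose depth ratio
#' to a 4-neighbour exceeds `ratio`, dilated by one pixel.
#'
#' @param frame A [depth_frame()].
#' @param ratio Depth ratio between neighbours flagged as an edge
#'   (default 1.1).
#' @return Logical matrix, TRUE at/next to an edge.
#' @export
depth_edge_mask <- function(frame, ratio = 1.1) {
  z <- frame$values
  h <- nrow(z); w <- ncol(z)
  edge <- matrix(FALSE, h, w)
  rr <- z[, -1] / z[, -w]
  jump_h <- rr > ratio | rr < 1 / ratio
  edge[, -1] <- edge[, -1] | jump_h
  edge[, -w] <- edge[, -w] | jump_h
  rc <- z[-1, ] / z[-h, ]
  jump_v <- rc > ratio | rc < 1 / ratio
  edge[-1, ] <- edge[-1, ] | jump_v
  edge[-h, ] <- edge[-h, ] | jump_v
  # dilate by one pixel
  dil <- edge
  dil[, -1] <- dil[, -1] | edge[, -w]
  dil[, -w] <- dil[, -w] | edge[, -1]
  dil[-1, ] <- dil[-1, ] | edge[-h, ]
  dil[-h, ] <- dil[-h, ] | edge[-1, ]
  dil
}

# ---- field maps -------------------------------------------------------------

#' Regular grid over the central visual field
#'
#' @param extent_deg Half-extent in degrees (grid spans +/- extent on both
#'   axes; default 10, the plotted central field).
#' @param cell_deg Cell size in degrees (default 0.5).
#' @return Object of class `field_grid` with cell edges and centers.
#' @export
field_grid <- function(extent_deg = 10, cell_deg = 0.5) {
  stopifnot(extent_deg > 0, cell_deg > 0, extent_deg >= cell_deg)
  breaks <- seq(-extent_deg, extent_deg, by = cell_deg)
  structure(list(breaks = breaks,
                 centers = (breaks[-1] + breaks[-length(breaks)]) / 2,
                 extent_deg = extent_deg, cell_deg = cell_deg),
            class = "field_grid")
}

same_grid <- function(a, b) {
  isTRUE(all.equal(a$breaks, b$breaks))
}

# linear cell index (el-major) or NA outside the grid
grid_cell <- function(grid, az, el) {
  nb <- length(grid$breaks) - 1L
  ia <- findInterval(az, grid$breaks, rightmost.closed = TRUE)
  ie <- findInterval(el, grid$breaks, rightmost.closed = TRUE)
  ok <- ia >= 1L & ia <= nb & ie >= 1L & ie <= nb
  ifelse(ok, (ia - 1L) * nb + ie, NA_integer_)
}

#' Bin disparity samples into a field map
#'
#' Per-cell median, standard deviation and count of one disparity component
#' over the defined samples, reported in arcmin. Cells with no samples are
#' empty (NA), not zero. By default the per-cell sample values are retained
#' so that maps can later be pooled across games with equal weight.
#'
#' @param samples A `disparity_samples` data.frame.
#' @param grid A [field_grid()].
#' @param component `"horizontal"` or `"vertical"`.
#' @param keep_samples Retain raw per-cell values (needed by
#'   [aggregate_sessions()]).
#' @return Object of class `field_map`: matrices `median`, `spread`,
#'   `count` (rows = elevation cells, cols = azimuth cells), `grid`,
#'   `component`, and optionally `samples`.
#' @export
bin_field_map <- function(samples, grid = field_grid(),
                          component = c("horizontal", "vertical"),
                          keep_samples = TRUE) {
  component <- match.arg(component)
  val <- if (component == "horizontal") samples$hdisp else samples$vdisp
  keep <- samples$defined & !is.na(val)
  az <- samples$az[keep]; el <- samples$el[keep]
  val <- val[keep] * 60  # arcmin
  cell <- grid_cell(grid, az, el)
  in_grid <- !is.na(cell)
  cell <- cell[in_grid]; val <- val[in_grid]
  nb <- length(grid$breaks) - 1L
  med <- spread <- matrix(NA_real_, nb, nb)
  cnt <- matrix(0L, nb, nb)
  if (length(cell)) {
    sp <- split(val, cell)
    idx <- as.integer(names(sp))
    med[idx] <- vapply(sp, stats::median, numeric(1))
    spread[idx] <- vapply(sp, function(x)
      if (length(x) > 1L) stats::sd(x) else 0, numeric(1))
    cnt[idx] <- lengths(sp)
  }
  structure(list(median = med, spread = spread, count = cnt, grid = grid,
                 component = component,
                 samples = if (keep_samples)
                   data.frame(cell = cell, value = val) else NULL),
            class = "field_map")
}

#' @export
print.field_map <- function(x, ...) {
  cat(sprintf("field_map (%s disparity): %d x %d cells over +/-%g deg, %d samples, median range [%.2f, %.2f] arcmin\n",
              x$component, nrow(x$median), ncol(x$median),
              x$grid$extent_deg, sum(x$count),
              suppressWarnings(min(x$median, na.rm = TRUE)),
              suppressWarnings(max(x$median, na.rm = TRUE))))
  invisible(x)
}

#' Weighted median
#'
#' Smallest value at which the cumulative weight reaches half the total.
#'
#' @param x Values.
#' @param w Non-negative weights.
#' @return The weighted median.
#' @export
weighted_median <- function(x, w) {
  stopifnot(length(x) == length(w), all(w >= 0))
  o <- order(x)
  cw <- cumsum(w[o])
  x[o][which(cw >= sum(w) / 2 - 1e-12)[1]]
}

#' Pool field maps across games with equal weight per game
#'
#' Sessions contribute very different sample counts, so a plain pooled
#' median would be dominated by the longest game. Instead every sample from
#' game label g gets weight `1 / (n_g * G)` (n_g = that label's total
#' sample count, G = number of distinct labels), and each cell's median and
#' spread are weighted statistics of the pooled, weight-adjusted
#' distribution. Requires maps built with `keep_samples = TRUE` on
#' identical grids.
#'
#' @param maps List of [bin_field_map()] outputs.
#' @param labels Game label per map (same length as `maps`).
#' @return A combined `field_map`.
#' @export
aggregate_sessions <- function(maps, labels) {
  stopifnot(length(maps) == length(labels), length(maps) >= 1)
  grid <- maps[[1]]$grid
  for (m in maps) {
    if (!same_grid(m$grid, grid)) stop("field maps have mismatched grids")
    if (is.null(m$samples))
      stop("aggregate_sessions needs maps built with keep_samples = TRUE")
  }
  labels <- as.character(labels)
  G <- length(unique(labels))
  n_label <- tapply(vapply(maps, function(m) nrow(m$samples), numeric(1)),
                    labels, sum)
  pooled <- do.call(rbind, lapply(seq_along(maps), function(i) {
    s <- maps[[i]]$samples
    s$w <- 1 / (n_label[[labels[i]]] * G)
    s
  }))
  nb <- length(grid$breaks) - 1L
  med <- spread <- matrix(NA_real_, nb, nb)
  cnt <- matrix(0L, nb, nb)
  sp <- split(pooled[c("value", "w")], pooled$cell)
  idx <- as.integer(names(sp))
  med[idx] <- vapply(sp, function(s) weighted_median(s$value, s$w), numeric(1))
  spread[idx] <- vapply(sp, function(s) {
    wn <- s$w / sum(s$w)
    mu <- sum(wn * s$value)
    sqrt(sum(wn * (s$value - mu)^2))
  }, numeric(1))
  cnt[idx] <- vapply(sp, nrow, integer(1))
  structure(list(median = med, spread = spread, count = cnt, grid = grid,
                 component = maps[[1]]$component,
                 samples = pooled),
            class = "field_map")
}

#' Horizontal-to-vertical disparity anisotropy
#'
#' Ratio of the spread of horizontal disparity to that of vertical
#' disparity pooled over the field — the joint-distribution aspect ratio
#' (about 20:1 in natural viewing). Default spread measure is the
#' interquartile range (robust); switchable to standard deviation.
#'
#' @param samples A `disparity_samples` data.frame (>= 2 defined samples).
#' @param method `"iqr"` or `"sd"`.
#' @return List: `ratio`, `h_spread`, `v_spread` (deg), `method`,
#'   `infinite` (TRUE when vertical spread is zero, ratio reported Inf).
#' @export
anisotropy_ratio <- function(samples, method = c("iqr", "sd")) {
  method <- match.arg(method)
  h <- samples$hdisp[samples$defined]
  v <- samples$vdisp[samples$defined]
  if (length(h) < 2L) stop("need at least 2 defined samples")
  spread <- function(x)
    if (method == "iqr") stats::IQR(x) else stats::sd(x)
  hs <- spread(h); vs <- spread(v)
  if (vs == 0)
    list(ratio = Inf, h_spread = hs, v_spread = 0, method = method,
         infinite = TRUE)
  else
    list(ratio = hs / vs, h_spread = hs, v_spread = vs, method = method,
         infinite = FALSE)
}

# ---- session-level pipeline -------------------------------------------------

#' Disparity samples for a whole session
#'
#' For each depth frame (optionally subsampled), pairs the frame with the
#' temporally nearest quality-controlled fixation sample, reconstructs the
#' scene, poses the eyes on the fixation point with L2 torsion, applies the
#' occlusion test and accumulates the retinal disparity field.
#'
#' @param frames List of [depth_frame()].
#' @param trace A [gaze_trace()].
#' @param iod Inter-ocular distance, cm.
#' @param listing_gain L2 gain.
#' @param every Use every k-th frame (default 1 = all).
#' @param v_threshold Saccade threshold passed to [fixation_samples()].
#' @return A `disparity_samples` data.frame pooled over the used frames.
#' @export
session_disparity_samples <- function(frames, trace, iod = 6.33,
                                      listing_gain = 0.8, every = 1L,
                                      v_threshold = 60) {
  fs <- fixation_samples(trace, v_threshold = v_threshold)
  fs <- fs[is.finite(fs$dist_m), , drop = FALSE]
  if (!nrow(fs)) stop("no usable fixation samples in trace")
  use <- seq(1L, length(frames), by = every)
  out <- vector("list", length(use))
  for (k in seq_along(use)) {
    fr <- frames[[use[k]]]
    i <- which.min(abs(fs$t - fr$timestamp))
    fixpt <- as.numeric(fs[i, c("fx", "fy", "fz")])
    pts <- backproject(fr)
    poses <- eye_poses(fixpt, iod = iod, listing_gain = listing_gain)
    masks <- occlusion_masks(pts, poses,
                             pitch_deg = fr$camera$hfov /
                               fr$camera$resolution[["width"]])
    out[[k]] <- disparity_field(pts, poses, masks)
  }
  res <- do.call(rbind, out)
  class(res) <- c("disparity_samples", "data.frame")
  res
}
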