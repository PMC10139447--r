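# From raw binocular traces to quality-controlled fixation samples:
# cyclopean angular speed, velocity-threshold saccade detection with
# 2%/98% amplitude trimming, saccade-gated sample selection, vergence
# triangulation, calibration QC, and fixation statistics.

# per-sample cyclopean direction: normalized mean of the two eyes' unit
# gaze vectors
cyclopean_dirs <- function(trace) {
  dL <- helm_dir(trace$laz, trace$lel)
  dR <- helm_dir(trace$raz, trace$rel)
  m <- dL + dR
  m / sqrt(rowSums(m^2))
}

#' Angular speed of the cyclopean gaze direction
#'
#' Central-difference angular speed (deg/s) of the cyclopean direction;
#' one-sided differences at the trace endpoints.
#'
#' @param trace A [gaze_trace()] with at least 2 samples.
#' @return Numeric vector, one speed per sample.
#' @export
angular_velocity <- function(trace) {
  n <- nrow(trace)
  if (n < 2L) stop("angular_velocity needs at least 2 samples")
  d <- cyclopean_dirs(trace)
  t <- trace$t
  v <- numeric(n)
  if (n > 2L) {
    i <- 2:(n - 1)
    v[i] <- angle_between(d[i - 1, , drop = FALSE], d[i + 1, , drop = FALSE]) /
      (t[i + 1] - t[i - 1])
  }
  v[1] <- angle_between(d[1, ], d[2, ]) / (t[2] - t[1])
  v[n] <- angle_between(d[n - 1, ], d[n, ]) / (t[n] - t[n - 1])
  v
}

# grow a supra-threshold core outward to the nearest local speed minima;
# returns c(a, b) sample indices of the movement window
movement_window <- function(speed, core) {
  a <- core[1]; b <- core[2]; n <- length(speed)
  while (a > 1L && speed[a - 1L] < speed[a]) a <- a - 1L
  while (b < n && speed[b + 1L] < speed[b]) b <- b + 1L
  c(a, b)
}

#' Detect saccades by velocity threshold with amplitude trimming
#'
#' A saccade core is a contiguous run of samples whose cyclopean angular
#' speed exceeds `v_threshold` (default 60 deg/s). Each core is grown
#' outward to the nearest local speed minima to delimit the movement, and
#' the reported interval spans from the sample where the movement's
#' cumulative amplitude crosses 2% to where it crosses 98% of the total.
#' Intervals shorter than `min_samples` are discarded as tracker noise;
#' overlapping intervals are merged.
#'
#' @param trace A [gaze_trace()].
#' @param v_threshold Speed threshold, deg/s (> 0).
#' @param min_samples Minimum interval length in samples (default 2).
#' @return data.frame with columns `i_start`, `i_end`, `t_start`, `t_end`,
#'   `amplitude` (deg); zero rows if no saccades.
#' @export
detect_saccades <- function(trace, v_threshold = 60, min_samples = 2L) {
  stopifnot(v_threshold > 0)
  speed <- angular_velocity(trace)
  supra <- speed > v_threshold
  empty <- data.frame(i_start = integer(0), i_end = integer(0),
                      t_start = numeric(0), t_end = numeric(0),
                      amplitude = numeric(0))
  if (!any(supra)) return(empty)
  r <- rle(supra)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cores <- cbind(starts[r$values], ends[r$values])
  d <- cyclopean_dirs(trace)
  out <- empty
  for (k in seq_len(nrow(cores))) {
    w <- movement_window(speed, cores[k, ])
    idx <- w[1]:w[2]
    if (length(idx) < 2L) next
    steps <- angle_between(d[idx[-length(idx)], , drop = FALSE],
                           d[idx[-1], , drop = FALSE])
    cum <- c(0, cumsum(steps))
    A <- cum[length(cum)]
    if (A <= 0) next
    i1 <- idx[which(cum >= 0.02 * A)[1]]
    i2 <- idx[which(cum >= 0.98 * A)[1]]
    if (i2 - i1 + 1L < min_samples) next
    out <- rbind(out, data.frame(i_start = i1, i_end = i2,
                                 t_start = trace$t[i1], t_end = trace$t[i2],
                                 amplitude = A))
  }
  if (nrow(out) < 2L) return(out)
  # merge overlaps, keep time order
  out <- out[order(out$i_start), ]
  keep <- out[1, ]
  for (k in 2:nrow(out)) {
    last <- nrow(keep)
    if (out$i_start[k] <= keep$i_end[last]) {
      keep$i_end[last] <- max(keep$i_end[last], out$i_end[k])
      keep$t_end[last] <- max(keep$t_end[last], out$t_end[k])
      keep$amplitude[last] <- max(keep$amplitude[last], out$amplitude[k])
    } else keep <- rbind(keep, out[k, ])
  }
  rownames(keep) <- NULL
  keep
}

#' Select samples usable for disparity statistics
#'
#' Returns the samples outside every saccade interval (disparity processing
#' is suppressed during saccades): the selected and in-saccade sets
#' partition the trace.
#'
#' @param trace A [gaze_trace()].
#' @param saccades Intervals from [detect_saccades()].
#' @return A [gaze_trace()] subset.
#' @export
select_fusion_samples <- function(trace, saccades) {
  keep <- rep(TRUE, nrow(trace))
  for (k in seq_len(nrow(saccades)))
    keep[saccades$i_start[k]:saccades$i_end[k]] <- FALSE
  gaze_trace(as.data.frame(trace)[keep, , drop = FALSE],
             sample_rate = attr(trace, "sample_rate"),
             iod = attr(trace, "iod"))
}

#' Triangulate binocular fixation geometry
#'
#' The binocular fixation point of two (possibly skew) gaze rays is the
#' midpoint of the shortest segment between them. Distance is measured from
#' the cyclopean point (midpoint of the eye centers); near-parallel rays map
#' to infinite distance (0 D), as do distances beyond `far_cap_m`.
#' Diverging rays (closest approach behind an eye) are flagged and excluded
#' from downstream statistics.
#'
#' @param l_origin,r_origin `n x 3` eye centers, cm.
#' @param l_dir,r_dir `n x 3` gaze directions (need not be unit).
#' @param far_cap_m Distances beyond this are treated as infinite (default
#'   100 m).
#' @return data.frame: `fx, fy, fz` (fixation point, cm), `dist_m`,
#'   `dist_D`, `az`, `el` (cyclopean direction, deg), `ok` (FALSE for
#'   diverging rays).
#' @examples
#' vergence_geometry(c(-3.165, 0, 0), c(3.165, 0, 100),
#'                   c(3.165, 0, 0), c(-3.165, 0, 100))
#' @export
vergence_geometry <- function(l_origin, l_dir, r_origin, r_dir,
                              far_cap_m = 100) {
  oL <- rbind3(l_origin); oR <- rbind3(r_origin)
  dL <- rbind3(l_dir); dR <- rbind3(r_dir)
  n <- max(nrow(oL), nrow(dL))
  expand <- function(m) if (nrow(m) == 1L) m[rep(1L, n), , drop = FALSE] else m
  oL <- expand(oL); oR <- expand(oR); dL <- expand(dL); dR <- expand(dR)
  dL <- dL / sqrt(rowSums(dL^2)); dR <- dR / sqrt(rowSums(dR^2))
  w0 <- oL - oR
  b <- rowSums(dL * dR)
  d <- rowSums(dL * w0); e <- rowSums(dR * w0)
  denom <- 1 - b^2
  par <- denom < 1e-12
  t1 <- ifelse(par, Inf, (b * e - d) / denom)
  t2 <- ifelse(par, Inf, (e - b * d) / denom)
  diverging <- !par & (t1 < 0 | t2 < 0)
  mid <- (oL + t1 * dL + oR + t2 * dR) / 2
  cyc <- (oL + oR) / 2
  rel <- mid - cyc
  dist_cm <- sqrt(rowSums(rel^2))
  dist_m <- dist_cm / 100
  far <- par | dist_m > far_cap_m
  dist_m[far] <- Inf
  dist_D <- ifelse(far, 0, 100 / dist_cm)
  dir <- ifelse(matrix(par, n, 3), (dL + dR) / 2, rel)
  ang <- helm_angles(dir)
  data.frame(fx = mid[, 1], fy = mid[, 2], fz = mid[, 3],
             dist_m = dist_m, dist_D = dist_D,
             az = ang$az, el = ang$el, ok = !diverging)
}

#' Fixation samples from a gaze trace
#'
#' End-to-end convenience: detect saccades, drop in-saccade and invalid
#' samples, triangulate the remaining binocular samples, and drop diverging
#' ones.
#'
#' @param trace A [gaze_trace()].
#' @param saccades Optional precomputed saccade intervals.
#' @param v_threshold Saccade velocity threshold, deg/s.
#' @param far_cap_m See [vergence_geometry()].
#' @return data.frame of class `fixation_samples`: `t`, `az`, `el`,
#'   `dist_m`, `dist_D`, `fx`, `fy`, `fz`.
#' @export
fixation_samples <- function(trace, saccades = NULL, v_threshold = 60,
                             far_cap_m = 100) {
  if (is.null(saccades)) saccades <- detect_saccades(trace, v_threshold)
  sel <- select_fusion_samples(trace, saccades)
  sel <- sel[sel$valid, , drop = FALSE]
  vg <- vergence_geometry(as.matrix(sel[, c("lx", "ly", "lz")]),
                          helm_dir(sel$laz, sel$lel),
                          as.matrix(sel[, c("rx", "ry", "rz")]),
                          helm_dir(sel$raz, sel$rel),
                          far_cap_m = far_cap_m)
  out <- cbind(t = sel$t, vg[c("az", "el", "dist_m", "dist_D",
                               "fx", "fy", "fz")])[vg$ok, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("fixation_samples", "data.frame")
  out
}

# ---- calibration QC ---------------------------------------------------------

#' Calibration quality control
#'
#' RMS angular error between known calibration-target directions and the
#' measured gaze directions (after an optional pre-estimated constant
#' azimuth/elevation offset is removed from the measurements). A pre-test
#' session is accepted iff RMS <= 0.8 deg (about the repeatability of the
#' tracker); the stage is recorded in the report.
#'
#' @param known,measured data.frames with columns `az`, `el` (deg), equal
#'   row counts (typically 10: five positions at each of two distances).
#' @param stage `"pre"` or `"post"`.
#' @param offset Optional constant `c(az, el)` offset (deg) subtracted from
#'   the measurements; the routine does not estimate one.
#' @param rms_limit Acceptance limit, deg (default 0.8).
#' @return A `calibration_report`: `errors` (per-target deg), `rms`,
#'   `stage`, `accepted`.
#' @export
calibration_qc <- function(known, measured, stage = c("pre", "post"),
                           offset = c(0, 0), rms_limit = 0.8) {
  stage <- match.arg(stage)
  if (nrow(known) != nrow(measured))
    stop("known and measured target counts differ (",
         nrow(known), " vs ", nrow(measured), ")")
  err <- angle_between(helm_dir(known$az, known$el),
                       helm_dir(measured$az - offset[1],
                                measured$el - offset[2]))
  rms <- sqrt(mean(err^2))
  structure(list(errors = err, rms = rms, stage = stage,
                 accepted = rms <= rms_limit, rms_limit = rms_limit),
            class = "calibration_report")
}

#' @export
print.calibration_report <- function(x, ...) {
  cat(sprintf("calibration_report (%s): rms %.3f deg (limit %.2f) -> %s\n",
              x$stage, x$rms, x$rms_limit,
              if (x$accepted) "accepted" else "rejected"))
  invisible(x)
}

#' Pre/post calibration drift check
#'
#' RMS angular difference between the pre-test and post-test measurements of
#' the same targets; headset slippage is flagged when it exceeds
#' `rms_limit` (default 1.0 deg), in which case the session is repeated.
#'
#' @param pre_measured,post_measured data.frames with `az`, `el` (deg).
#' @param rms_limit Acceptance limit, deg.
#' @return List with `rms` and `accepted`.
#' @export
calibration_drift <- function(pre_measured, post_measured, rms_limit = 1.0) {
  if (nrow(pre_measured) != nrow(post_measured))
    stop("pre and post target counts differ")
  err <- angle_between(helm_dir(pre_measured$az, pre_measured$el),
                       helm_dir(post_measured$az, post_measured$el))
  rms <- sqrt(mean(err^2))
  list(rms = rms, accepted = rms <= rms_limit)
}

# ---- fixation statistics ----------------------------------------------------

#' Direction and distance statistics of fixations
#'
#' Normalized 2-D histogram of fixation directions (default 1 deg cells over
#' +/-30 deg), normalized histogram of fixation distances in diopters
#' (default 0.1 D bins over 0-4 D), distance median and quartiles, and the
#' 50% highest-density direction region: the smallest set of direction cells
#' (grown in descending density order, ties broken by cell index) whose
#' probability mass reaches 0.5.
#'
#' @param samples A `fixation_samples` data.frame (needs `az`, `el`,
#'   `dist_D`).
#' @param dir_breaks Cell edges (deg) for both direction axes.
#' @param diopter_breaks Bin edges in diopters; distances outside are
#'   clamped to the end bins.
#' @return List: `direction_hist` (matrix, rows = elevation cells bottom to
#'   top, cols = azimuth), `distance_hist` (named vector), `median`, `q25`,
#'   `q75` (D), `hdr50` (logical matrix), plus the break vectors.
#' @export
fixation_statistics <- function(samples,
                                dir_breaks = seq(-30, 30, by = 1),
                                diopter_breaks = seq(0, 4, by = 0.1)) {
  if (nrow(samples) < 1L) stop("no fixation samples")
  ia <- findInterval(samples$az, dir_breaks, rightmost.closed = TRUE)
  ie <- findInterval(samples$el, dir_breaks, rightmost.closed = TRUE)
  ncell <- length(dir_breaks) - 1L
  ok <- ia >= 1L & ia <= ncell & ie >= 1L & ie <= ncell
  H <- matrix(0, ncell, ncell)  # rows: elevation, cols: azimuth
  if (any(ok)) {
    tab <- table(factor(ie[ok], levels = seq_len(ncell)),
                 factor(ia[ok], levels = seq_len(ncell)))
    H <- matrix(as.numeric(tab), ncell, ncell)
    H <- H / sum(H)
  }
  dclamp <- pmin(pmax(samples$dist_D, min(diopter_breaks)),
                 max(diopter_breaks))
  id <- findInterval(dclamp, diopter_breaks, rightmost.closed = TRUE)
  nd <- length(diopter_breaks) - 1L
  dh <- tabulate(id, nbins = nd)
  dh <- dh / sum(dh)
  names(dh) <- sprintf("%.2f-%.2f", diopter_breaks[-length(diopter_breaks)],
                       diopter_breaks[-1])
  qs <- stats::quantile(samples$dist_D, c(0.25, 0.5, 0.75), names = FALSE)
  list(direction_hist = H, distance_hist = dh,
       median = qs[2], q25 = qs[1], q75 = qs[3],
       hdr50 = hdr_region(H, 0.5),
       dir_breaks = dir_breaks, diopter_breaks = diopter_breaks)
}

#' Highest-density region of a probability histogram
#'
#' Greedy construction: cells are added in descending probability order
#' (ties broken by linear cell index) until the cumulative mass reaches
#' `mass`. For a histogram this greedy set is exactly the smallest such set.
#'
#' @param H Probability matrix (sums to 1).
#' @param mass Target mass (default 0.5).
#' @return Logical matrix marking member cells.
#' @export
hdr_region <- function(H, mass = 0.5) {
  ord <- order(-as.vector(H), seq_along(H))
  cum <- cumsum(H[ord])
  k <- which(cum >= mass - 1e-12)[1]
  sel <- logical(length(H))
  if (!is.na(k)) sel[ord[seq_len(k)]] <- TRUE
  matrix(sel, nrow(H), ncol(H))
}
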