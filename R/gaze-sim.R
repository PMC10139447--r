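#' Fixation-distance generative laws per game archetype
#'
#' The generator does not assert a single "true" distribution of fixation
#' distances during VR gaming; it exposes the sampling law as configuration.
#' The defaults emulate the observed pattern that three of the four game
#' archetypes (rhythm, shooter, action-rhythm) have fixation-distance
#' distributions in diopters with a mode near 0 D (far gaze) and a long near
#' tail, while the environmental (reach-space) archetype is confined to near
#' distances: the former use an exponential law in diopters (rate
#' 1.2 D^-1), the latter a lognormal in diopters with median 1.6 D. Laws are
#' always truncated to the archetype's object-distance range when sampling.
#'
#' @param archetype Archetype label (see [build_scene()]).
#' @return A list describing the law: `kind` (`"exponential"` or
#'   `"lognormal"`) plus its parameters, in diopters.
#' @export
fixation_distance_law <- function(archetype) {
  archetype <- match.arg(archetype, .archetypes)
  if (archetype == "environmental")
    list(kind = "lognormal", meanlog = log(1.6), sdlog = 0.35)
  else
    list(kind = "exponential", rate = 1.2)
}

law_cdf <- function(law, d) {
  switch(law$kind,
         exponential = stats::pexp(d, rate = law$rate),
         lognormal = stats::plnorm(d, meanlog = law$meanlog, sdlog = law$sdlog),
         stop("unknown law kind: ", law$kind))
}

law_quantile_raw <- function(law, p) {
  switch(law$kind,
         exponential = stats::qexp(p, rate = law$rate),
         lognormal = stats::qlnorm(p, meanlog = law$meanlog, sdlog = law$sdlog),
         stop("unknown law kind: ", law$kind))
}

#' Quantile of a (truncated) fixation-distance law, in diopters
#'
#' @param law A law from [fixation_distance_law()] or the same shape.
#' @param p Probability in (0, 1).
#' @param range_m Optional truncation range in meters `c(min, max)`; the law
#'   is truncated to diopters `[1/max, 1/min]`.
#' @return Quantile in diopters.
#' @export
fixation_law_quantile <- function(law, p, range_m = NULL) {
  if (is.null(range_m)) return(law_quantile_raw(law, p))
  lo <- 1 / range_m[2]; hi <- 1 / range_m[1]
  Fa <- law_cdf(law, lo); Fb <- law_cdf(law, hi)
  law_quantile_raw(law, Fa + p * (Fb - Fa))
}

#' Sample fixation distances from a law
#'
#' Inverse-CDF sampling in diopters, truncated to `range_m`, returned in
#' meters.
#'
#' @inheritParams fixation_law_quantile
#' @param n Number of distances.
#' @param seed Integer seed (ignored if `rng` is supplied).
#' @param rng Internal: an existing RNG stream.
#' @return Distances in meters.
#' @export
sample_fixation_distances <- function(n, law, seed = 1L, range_m = NULL,
                                      rng = NULL) {
  if (is.null(rng)) rng <- local_rng(seed)
  u <- rng$runif_n(n)
  1 / vapply(u, function(p) fixation_law_quantile(law, p, range_m), numeric(1))
}

#' Construct a gaze script
#'
#' A gaze script is the deterministic plan a simulated observer follows: a
#' sequence of fixation targets (head coordinates, cm) with dwell durations,
#' joined by saccades with a raised-cosine velocity profile reaching
#' `saccade_peak_velocity`. Tracker noise is isotropic Gaussian in
#' azimuth/elevation with standard deviation `tracker_noise_sd` per eye and
#' sample; the default 0.8 deg is the midpoint of the 0.5-1.1 deg accuracy
#' quoted for consumer HMD eye trackers.
#'
#' @param fixations data.frame with columns `x`, `y`, `z` (cm) and
#'   `duration` (s, all > 0).
#' @param saccade_peak_velocity Peak angular speed of saccades, deg/s.
#' @param tracker_noise_sd Per-sample angular noise sd, deg (>= 0).
#' @param sample_rate Samples per second (default 90 Hz).
#' @return An object of class `gaze_script`.
#' @export
gaze_script <- function(fixations, saccade_peak_velocity = 300,
                        tracker_noise_sd = 0.8, sample_rate = 90) {
  stopifnot(is.data.frame(fixations),
            all(c("x", "y", "z", "duration") %in% names(fixations)),
            nrow(fixations) >= 1,
            all(fixations$duration > 0),
            saccade_peak_velocity > 0, tracker_noise_sd >= 0, sample_rate > 0)
  structure(list(fixations = fixations,
                 saccade_peak_velocity = saccade_peak_velocity,
                 tracker_noise_sd = tracker_noise_sd,
                 sample_rate = sample_rate),
            class = "gaze_script")
}

#' Binocular gaze trace container
#'
#' Time series of per-eye gaze: for each sample, time (s), per-eye origin
#' (cm, head frame), per-eye Helmholtz gaze direction (deg) and a validity
#' flag. Timestamps must be strictly increasing.
#'
#' @param samples data.frame with columns `t`, `lx`, `ly`, `lz`, `rx`, `ry`,
#'   `rz`, `laz`, `lel`, `raz`, `rel`, `valid`.
#' @param sample_rate Nominal sampling rate, Hz.
#' @param iod Inter-ocular distance in cm.
#' @return Object of class `gaze_trace` (a data.frame).
#' @export
gaze_trace <- function(samples, sample_rate = 90, iod = 6.33) {
  need <- c("t", "lx", "ly", "lz", "rx", "ry", "rz",
            "laz", "lel", "raz", "rel", "valid")
  miss <- setdiff(need, names(samples))
  if (length(miss)) stop("gaze trace missing columns: ",
                         paste(miss, collapse = ", "))
  if (nrow(samples) && any(diff(samples$t) <= 0))
    stop("gaze trace timestamps must be strictly increasing (first violation at row ",
         which(diff(samples$t) <= 0)[1] + 1L, ")")
  ang <- unlist(samples[c("laz", "lel", "raz", "rel")])
  if (length(ang) && any(!is.finite(ang))) stop("non-finite gaze directions")
  structure(samples[need], class = c("gaze_trace", "data.frame"),
            sample_rate = sample_rate, iod = iod)
}

# raised-cosine progress curve: fraction of amplitude covered at phase u in
# [0,1]; velocity profile v(u) ~ (1 - cos(2 pi u))/2, peak at u = 1/2.
raised_cosine_progress <- function(u) u - sin(2 * pi * u) / (2 * pi)

#' Simulate a binocular gaze trace over a script
#'
#' Both eyes' rays converge on each fixation target (plus optional isotropic
#' angular tracker noise). Between consecutive fixations the binocular gaze
#' point travels along the straight segment between the targets with a
#' raised-cosine speed profile whose peak *angular* speed (of the cyclopean
#' direction) equals the script's `saccade_peak_velocity`. Bit-reproducible
#' for a fixed seed.
#'
#' @param scene A `scene_spec` (used only to validate that targets are in
#'   front of the eyes; the trace itself is scene-independent).
#' @param script A [gaze_script()].
#' @param seed Integer seed for the tracker noise.
#' @param iod Inter-ocular distance, cm.
#' @return A [gaze_trace()].
#' @export
simulate_gaze <- function(scene, script, seed = 1L, iod = 6.33) {
  fx <- script$fixations
  if (any(fx$z <= 0)) stop("fixation target behind the eyes")
  rng <- local_rng(seed)
  eL <- c(-iod / 2, 0, 0); eR <- c(iod / 2, 0, 0)
  dt <- 1 / script$sample_rate

  # piecewise timeline: fixation dwells joined by raised-cosine saccades
  pts <- as.matrix(fx[, c("x", "y", "z")])
  n_fix <- nrow(fx)
  seg_start <- numeric(0); seg_end <- numeric(0)
  seg_kind <- character(0); seg_idx <- integer(0)
  t0 <- 0
  for (i in seq_len(n_fix)) {
    seg_start <- c(seg_start, t0); seg_end <- c(seg_end, t0 + fx$duration[i])
    seg_kind <- c(seg_kind, "fix"); seg_idx <- c(seg_idx, i)
    t0 <- t0 + fx$duration[i]
    if (i < n_fix) {
      amp <- angle_between(pts[i, ], pts[i + 1, ])
      dur <- 2 * amp / script$saccade_peak_velocity
      if (dur > 0) {
        seg_start <- c(seg_start, t0); seg_end <- c(seg_end, t0 + dur)
        seg_kind <- c(seg_kind, "sac"); seg_idx <- c(seg_idx, i)
        t0 <- t0 + dur
      }
    }
  }
  # uniform sample grid over the whole timeline
  times <- seq(0, t0, by = dt)
  seg_of <- findInterval(times, seg_start)
  targets <- matrix(NA_real_, length(times), 3)
  for (s in seq_along(seg_start)) {
    in_s <- which(seg_of == s)
    if (!length(in_s)) next
    i <- seg_idx[s]
    if (seg_kind[s] == "fix") {
      targets[in_s, ] <- matrix(pts[i, ], length(in_s), 3, byrow = TRUE)
    } else {
      u <- (times[in_s] - seg_start[s]) / (seg_end[s] - seg_start[s])
      p <- raised_cosine_progress(pmin(u, 1))
      targets[in_s, ] <- outer(1 - p, pts[i, ]) + outer(p, pts[i + 1, ])
    }
  }

  dirL <- helm_angles(sweep(targets, 2, eL))
  dirR <- helm_angles(sweep(targets, 2, eR))
  n <- length(times)
  if (script$tracker_noise_sd > 0) {
    nz <- matrix(rng$norm(4 * n, sd = script$tracker_noise_sd), n, 4)
    dirL$az <- dirL$az + nz[, 1]; dirL$el <- dirL$el + nz[, 2]
    dirR$az <- dirR$az + nz[, 3]; dirR$el <- dirR$el + nz[, 4]
  }
  gaze_trace(data.frame(t = times,
                        lx = eL[1], ly = eL[2], lz = eL[3],
                        rx = eR[1], ry = eR[2], rz = eR[3],
                        laz = dirL$az, lel = dirL$el,
                        raz = dirR$az, rel = dirR$el,
                        valid = TRUE),
             sample_rate = script$sample_rate, iod = iod)
}

#' Build a gaze script over a scene's depth structure
#'
#' Draws `n_fixations` fixation targets whose distances follow the
#' archetype's fixation-distance law (truncated to the scene's depth range)
#' and whose directions are confined to the central +/-5 deg, matching the
#' narrow distribution of fixation directions observed in HMDs.
#'
#' @param scene A `scene_spec`.
#' @param n_fixations Number of fixations.
#' @param seed Integer seed.
#' @param dwell Mean fixation duration, s.
#' @param direction_sd Angular sd of fixation directions, deg.
#' @param ... Passed to [gaze_script()].
#' @return A [gaze_script()].
#' @export
build_gaze_script <- function(scene, n_fixations, seed = 1L, dwell = 0.4,
                              direction_sd = 2.5, ...) {
  rng <- local_rng(seed + 104729L)
  law <- fixation_distance_law(scene$archetype)
  d_cm <- 100 * sample_fixation_distances(n_fixations, law, rng = rng,
                                          range_m = scene$depth_range)
  az <- rng$norm(n_fixations, sd = direction_sd)
  el <- rng$norm(n_fixations, sd = direction_sd)
  dirs <- helm_dir(az, el)
  dur <- pmax(0.1, rng$norm(n_fixations, mean = dwell, sd = dwell / 4))
  gaze_script(data.frame(x = dirs[, 1] * d_cm, y = dirs[, 2] * d_cm,
                         z = dirs[, 3] * d_cm, duration = dur), ...)
}

#' Simulate a full synthetic session
#'
#' Convenience wrapper: builds a scene for the archetype, scripts
#' `duration` seconds of fixations over it, simulates the binocular trace,
#' and renders depth frames at `frame_rate`.
#'
#' @param archetype Archetype label.
#' @param duration Session length in seconds.
#' @param seed Integer seed.
#' @param camera A [camera_model()].
#' @param frame_rate Depth-frame rate, Hz (default 40).
#' @param ... Passed to [build_gaze_script()].
#' @return List with `scene`, `trace`, `frames` (list of [depth_frame()]).
#' @export
simulate_session <- function(archetype, duration = 2, seed = 1L,
                             camera = camera_model(), frame_rate = 40, ...) {
  scene <- build_scene(archetype, seed)
  n_fix <- max(2L, round(duration / 0.5))
  script <- build_gaze_script(scene, n_fix, seed = seed, ...)
  trace <- simulate_gaze(scene, script, seed = seed)
  frame_times <- seq(0, max(trace$t), by = 1 / frame_rate)
  frames <- lapply(frame_times, function(ft)
    render_depth(scene, camera, timestamp = ft))
  list(scene = scene, trace = trace, frames = frames)
}
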