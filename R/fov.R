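# Binocular and total field of view of per-eye HMD screens as a function of
# screen width, optical distance, horizontal (nasal/temporal) shift,
# inter-ocular distance and vergence. Single-point eye model: projection
# and rotation centers coincide; widths are computed in the horizontal
# plane only. The binocular field is the *retinal-overlap* region (imaged
# on corresponding regions in the two eyes), so each eye's screen span is
# expressed in that eye's rotated frame before intersecting.

#' Per-eye screen geometry of an HMD
#'
#' @param width Screen width, cm (default 117).
#' @param distance Optical distance from the eye to the screen, cm
#'   (default 65).
#' @param shift Horizontal screen shift per eye, cm: positive = nasal
#'   (toward the nose), negative = temporal.
#' @param iod Inter-ocular distance, cm (default 6.33).
#' @return Object of class `screen_geometry`.
#' @export
screen_geometry <- function(width = 117, distance = 65, shift = 0,
                            iod = 6.33) {
  stopifnot(width > 0, distance > 0, iod > 0)
  structure(list(width = width, distance = distance, shift = shift,
                 iod = iod),
            class = "screen_geometry")
}

#' @export
print.screen_geometry <- function(x, ...) {
  cat(sprintf("screen_geometry: %.0f cm wide at %.0f cm, shift %+.1f cm, iod %.2f cm\n",
              x$width, x$distance, x$shift, x$iod))
  invisible(x)
}

# head-frame azimuth interval [lo, hi] (deg, relative to the eye's
# straight-ahead) subtended by one eye's screen. Nasal direction is +x for
# the left eye, -x for the right.
eye_screen_span <- function(screen, eye = c("left", "right")) {
  eye <- match.arg(eye)
  s <- if (eye == "left") screen$shift else -screen$shift
  lo <- atan2(-screen$width / 2 + s, screen$distance)
  hi <- atan2(screen$width / 2 + s, screen$distance)
  rad2deg(c(lo, hi))
}

#' Monocular field-of-view limits of one eye's screen
#'
#' Arctangent limits of the screen edges from that eye's straight-ahead
#' direction, with the shift applied nasally/temporally.
#'
#' @param screen A [screen_geometry()].
#' @param eye `"left"` or `"right"`.
#' @return List: `nasal` and `temporal` extents (positive deg), `width`
#'   (their sum) and `span` (the signed head-frame azimuth interval).
#' @examples
#' monocular_limits(screen_geometry())$width   # ~84 deg
#' @export
monocular_limits <- function(screen, eye = c("left", "right")) {
  eye <- match.arg(eye)
  span <- eye_screen_span(screen, eye)
  # for the left eye nasal = +azimuth; for the right eye nasal = -azimuth
  if (eye == "left") list(nasal = span[2], temporal = -span[1],
                          width = span[2] - span[1], span = span)
  else list(nasal = -span[1], temporal = span[2],
            width = span[2] - span[1], span = span)
}

# vergence half-angle (deg) at a fixation distance in diopters
vergence_half_angle <- function(screen, fixation_D) {
  if (fixation_D <= 0) return(0)
  rad2deg(atan2(screen$iod / 2, 100 / fixation_D))
}

# both eyes' screen spans in *retinal* azimuth after converging at
# fixation_D: the left eye rotates nasally (rightward, +) by the half
# angle, the right eye by -, and retinal azimuth subtracts the eye rotation
retinal_spans <- function(screen, fixation_D) {
  eta <- vergence_half_angle(screen, fixation_D)
  list(left = eye_screen_span(screen, "left") - eta,
       right = eye_screen_span(screen, "right") + eta)
}

#' Binocular field-of-view width
#'
#' Width of the intersection of the two eyes' screen spans in retinal
#' coordinates, after each eye rotates nasally by the vergence half-angle
#' `atan(iod/2 / fixation distance)`. Zero if the spans are disjoint.
#'
#' @param screen A [screen_geometry()].
#' @param fixation_D Fixation (vergence) distance in diopters; 0 =
#'   infinity (parallel gaze).
#' @return Width in degrees.
#' @examples
#' binocular_width(screen_geometry(), 0)     # ~84 deg: full overlap
#' binocular_width(screen_geometry(), 0.7)   # narrower when converged
#' @export
binocular_width <- function(screen, fixation_D) {
  sp <- retinal_spans(screen, fixation_D)
  max(0, min(sp$left[2], sp$right[2]) - max(sp$left[1], sp$right[1]))
}

#' Total field-of-view width
#'
#' Width (measure) of the union of the two eyes' retinal screen spans: the
#' region seen by the left eye, the right eye, or both.
#'
#' @inheritParams binocular_width
#' @return Width in degrees.
#' @export
total_width <- function(screen, fixation_D) {
  sp <- retinal_spans(screen, fixation_D)
  hull <- max(sp$left[2], sp$right[2]) - min(sp$left[1], sp$right[1])
  gap <- max(0, max(sp$left[1], sp$right[1]) - min(sp$left[2], sp$right[2]))
  hull - gap
}

#' Binocular width implied by measured monocular limits
#'
#' Bookkeeping for device measurements: given each eye's monocular field
#' extending `temporal` deg temporally and `nasal` deg nasally from
#' straight ahead, the monocular width is their sum and the parallel-gaze
#' binocular field is the overlap `2 * nasal` (the nasal extents face each
#' other).
#'
#' @param temporal,nasal Monocular extents, deg.
#' @return List with `monocular` and `binocular` widths, deg.
#' @examples
#' fov_from_monocular_limits(temporal = 47, nasal = 36)  # 83 and 72 deg
#' @export
fov_from_monocular_limits <- function(temporal, nasal) {
  list(monocular = temporal + nasal, binocular = 2 * min(nasal, temporal))
}

#' Sweep binocular/total widths over shifts and fixation distances
#'
#' Full cross-product table, plus the shift maximizing the binocular width
#' at each fixation distance.
#'
#' @param screen Base [screen_geometry()] (its `shift` is ignored).
#' @param shifts Screen shifts to evaluate, cm.
#' @param distances Fixation distances, D.
#' @return data.frame `shift`, `fixation_D`, `binocular`, `total` with
#'   attribute `"best_shift"` (data.frame `fixation_D`, `shift`).
#' @export
fov_sweep <- function(screen, shifts, distances) {
  stopifnot(length(shifts) >= 1, length(distances) >= 1)
  tab <- expand.grid(shift = shifts, fixation_D = distances,
                     KEEP.OUT.ATTRS = FALSE)
  geom <- lapply(tab$shift, function(s)
    screen_geometry(screen$width, screen$distance, s, screen$iod))
  tab$binocular <- mapply(function(g, d) binocular_width(g, d),
                          geom, tab$fixation_D)
  tab$total <- mapply(function(g, d) total_width(g, d),
                      geom, tab$fixation_D)
  best <- do.call(rbind, lapply(split(tab, tab$fixation_D), function(s) {
    data.frame(fixation_D = s$fixation_D[1],
               shift = s$shift[which.max(s$binocular)])
  }))
  rownames(best) <- NULL
  attr(tab, "best_shift") <- best
  tab
}
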