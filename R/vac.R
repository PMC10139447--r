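# Vergence-accommodation conflict: in an HMD the eyes converge to the
# virtual object but must accommodate to the screen's optical distance;
# conflicts beyond about +/-0.5 D cause discomfort. All computations are
# dioptric (the comfort criterion is dioptric); convert lengths at the
# boundary.

#' Fraction of fixations with an uncomfortable conflict
#'
#' Percentage of fixation distances whose dioptric difference from the
#' screen exceeds the comfort tolerance; the boundary
#' `|d - screen| = tolerance` counts as comfortable.
#'
#' @param fixations_D Fixation distances in diopters (>= 0; 0 = infinity).
#' @param screen_D Screen optical distance, D.
#' @param tolerance Comfort tolerance, D (default 0.5).
#' @return Percent in \[0, 100\].
#' @examples
#' conflict_fraction(c(0, 1.54, 3), screen_D = 1.54)  # 66.67
#' @export
conflict_fraction <- function(fixations_D, screen_D, tolerance = 0.5) {
  stopifnot(tolerance > 0, all(fixations_D >= 0))
  if (!length(fixations_D)) stop("empty fixation set")
  100 * mean(abs(fixations_D - screen_D) > tolerance)
}

#' Conflict profile over candidate screen distances
#'
#' [conflict_fraction()] evaluated at every screen distance of a grid.
#'
#' @param fixations_D Fixation distances, D.
#' @param screen_grid Sorted screen-distance grid, D (default 0-3 D in
#'   0.01 D steps, covering plausible HMD screens at a resolution finer
#'   than the optimum's rounding).
#' @param tolerance Comfort tolerance, D.
#' @return data.frame of class `conflict_profile` with `screen_D` and
#'   `percent`.
#' @export
conflict_profile <- function(fixations_D, screen_grid = seq(0, 3, by = 0.01),
                             tolerance = 0.5) {
  stopifnot(length(screen_grid) >= 1, !is.unsorted(screen_grid))
  pct <- vapply(screen_grid, function(s)
    conflict_fraction(fixations_D, s, tolerance), numeric(1))
  structure(data.frame(screen_D = screen_grid, percent = pct),
            class = c("conflict_profile", "data.frame"),
            tolerance = tolerance)
}

#' Conflict-minimizing screen distance
#'
#' Grid point with the minimum conflict percentage; ties are broken toward
#' the smallest diopter value (the farthest screen).
#'
#' @param profile A [conflict_profile()].
#' @return Screen distance in diopters.
#' @export
optimal_screen_distance <- function(profile) {
  if (!nrow(profile)) stop("empty conflict profile")
  m <- min(profile$percent)
  min(profile$screen_D[profile$percent == m])
}
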