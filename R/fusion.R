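#' Fitted horopter surface
#'
#' Smooth surface fitted to empirical horopter measurements, expressed as
#' the horizontal disparity (deg) of the surface at Helmholtz field
#' position (X, Y):
#' `DH = -0.0485 Y - 0.0036 X^2 - 0.0017 Y^2`.
#' The surface passes through zero at the fovea, is pitched top-back
#' (disparity decreases with elevation: points above fixation must be
#' farther to fall on it) and curves away laterally (symmetric in X).
#'
#' @param X,Y Helmholtz azimuth and elevation, deg (vectorized).
#' @param coef Named coefficients `a_y`, `a_xx`, `a_yy` (deg, deg/deg^2).
#' @return Horizontal disparity of the horopter, deg.
#' @examples
#' horopter_disparity(0, -10)   # crossed (positive) below fixation
#' horopter_disparity(10, 0)    # uncrossed laterally
#' @export
horopter_disparity <- function(X, Y, coef = c(a_y = -0.0485,
                                              a_xx = -0.0036,
                                              a_yy = -0.0017)) {
  coef[["a_y"]] * Y + coef[["a_xx"]] * X^2 + coef[["a_yy"]] * Y^2
}

#' Half-width of the Panum fusional band
#'
#' The range of disparities fusable into a single percept grows with
#' retinal eccentricity. The fitted band half-width at eccentricity
#' `ecc` (deg) is `0.16 + 0.095 ecc + ecc^1.35` in its literal form. The
#' printed growth term rises far faster than classical foveal-to-parafoveal
#' Panum measurements at 10 deg eccentricity, so a scaled variant
#' `0.16 + 0.095 ecc + (ecc/ecc0)^1.35` is available as an opt-in
#' (`form = "scaled"`); the literal form is the default.
#'
#' @param ecc Eccentricity, deg (>= 0; absolute value is taken).
#' @param base Constant term, deg.
#' @param linear Linear coefficient, deg/deg.
#' @param exponent Power of the growth term.
#' @param form `"literal"` (printed equation) or `"scaled"`.
#' @param ecc0 Eccentricity scale (deg) for the scaled form.
#' @return Half-width in degrees, strictly positive and strictly
#'   increasing in `ecc`.
#' @export
panum_halfwidth <- function(ecc, base = 0.16, linear = 0.095,
                            exponent = 1.35, form = c("literal", "scaled"),
                            ecc0 = 10) {
  form <- match.arg(form)
  e <- abs(ecc)
  grow <- if (form == "literal") e^exponent else (e / ecc0)^exponent
  base + linear * e + grow
}

#' Fusable-disparity limits across the field
#'
#' The band of fusable disparities is centered on the horopter:
#' `limits = DH(X, Y) +/- w(ecc)` with `ecc = sqrt(X^2 + Y^2)`.
#'
#' @param X,Y Helmholtz field position, deg (vectorized).
#' @param ... Passed to [panum_halfwidth()].
#' @param horopter_coef Passed to [horopter_disparity()] as `coef`.
#' @return data.frame with `lower`, `upper`, `center` (deg).
#' @export
panum_band <- function(X, Y, ...,
                       horopter_coef = c(a_y = -0.0485, a_xx = -0.0036,
                                         a_yy = -0.0017)) {
  dh <- horopter_disparity(X, Y, coef = horopter_coef)
  w <- panum_halfwidth(sqrt(X^2 + Y^2), ...)
  data.frame(lower = dh - w, upper = dh + w, center = dh)
}

#' Probability of diplopia across the visual field
#'
#' Per field cell, the proportion of observed horizontal disparities that
#' fall strictly outside the fusable band evaluated at the cell center
#' (samples exactly on a band limit count as fused — the band is closed).
#' Cells without samples are empty, not zero.
#'
#' @param samples A `disparity_samples` data.frame.
#' @param grid A [field_grid()].
#' @param ... Band parameters passed to [panum_band()].
#' @return A `field_map` whose `median` slot holds the per-cell diplopia
#'   proportion in \[0, 1\] (`spread` is NA; `count` the cell sample count).
#' @export
diplopia_probability <- function(samples, grid = field_grid(), ...) {
  keep <- samples$defined & !is.na(samples$hdisp)
  az <- samples$az[keep]; el <- samples$el[keep]
  h <- samples$hdisp[keep]
  cell <- grid_cell(grid, az, el)
  in_grid <- !is.na(cell)
  cell <- cell[in_grid]; h <- h[in_grid]
  nb <- length(grid$breaks) - 1L
  prop <- matrix(NA_real_, nb, nb)
  cnt <- matrix(0L, nb, nb)
  if (length(cell)) {
    # band at each cell center: cells are el-major (rows el, cols az)
    ctr <- grid$centers
    band <- panum_band(X = rep(ctr, each = nb), Y = rep(ctr, times = nb), ...)
    sp <- split(h, cell)
    idx <- as.integer(names(sp))
    prop[idx] <- vapply(seq_along(sp), function(j) {
      i <- idx[j]
      mean(sp[[j]] < band$lower[i] | sp[[j]] > band$upper[i])
    }, numeric(1))
    cnt[idx] <- lengths(sp)
  }
  structure(list(median = prop, spread = matrix(NA_real_, nb, nb),
                 count = cnt, grid = grid, component = "diplopia",
                 samples = NULL),
            class = "field_map")
}
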