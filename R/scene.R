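#' Synthetic game-archetype scenes
#'
#' A scene is a list of geometric primitives (`ground_plane`, `wall`, `box`,
#' `sphere`) placed in head coordinates (cm). Scenes are parametric stand-ins
#' for the depth structure of four VR game archetypes — a rhythm game
#' (mid/near targets approaching the player), a first-person shooter
#' (near/mid/far), an environmental simulation (near/reach space only) and an
#' action-rhythm shooter (mid/far) — not replicas of any game's art. Each
#' archetype constrains the range of object distances; object distances are
#' drawn from the archetype's fixation-distance law (see
#' [fixation_distance_law()]) truncated to that range, so that scene depth
#' structure and fixation behaviour are statistically consistent.
#'
#' @name scene
NULL

.archetypes <- c("rhythm", "shooter", "environmental", "action_rhythm")

# default object-distance ranges in meters per archetype
.archetype_depth_range <- function(archetype) {
  switch(archetype,
         environmental = c(0.3, 3),
         rhythm        = c(0.5, 10),
         shooter       = c(0.5, 50),
         action_rhythm = c(0.5, 50))
}

prim <- function(kind, center, extents = NULL, radius = NULL) {
  list(kind = kind, center = center, extents = extents, radius = radius)
}

#' Construct a scene primitive
#'
#' @param kind One of `"ground_plane"` (infinite horizontal plane at height
#'   `center[2]`), `"wall"` (axis-aligned rectangle in the plane
#'   `z = center[3]`, `extents = c(width, height)`), `"box"` (axis-aligned,
#'   `extents` = full sizes) or `"sphere"` (`radius`).
#' @param center Position in head coordinates, cm.
#' @param extents,radius Sizes in cm, per kind.
#' @return A primitive list usable in [scene_spec()].
#' @export
scene_primitive <- function(kind = c("ground_plane", "wall", "box", "sphere"),
                            center, extents = NULL, radius = NULL) {
  kind <- match.arg(kind)
  if (kind == "wall" && (is.null(extents) || length(extents) != 2))
    stop("wall needs extents = c(width, height)")
  if (kind == "box" && (is.null(extents) || length(extents) != 3))
    stop("box needs extents = c(dx, dy, dz)")
  if (kind == "sphere" && (is.null(radius) || radius <= 0))
    stop("sphere needs a positive radius")
  prim(kind, center, extents, radius)
}

#' Assemble a custom scene
#'
#' @param primitives List of [scene_primitive()]s (at least one).
#' @param archetype Label (defaults to `"environmental"`; any of the four
#'   archetype labels is allowed — the label only selects default
#'   fixation-distance laws downstream).
#' @param depth_range Object-distance range in meters.
#' @return A `scene_spec`.
#' @export
scene_spec <- function(primitives, archetype = "environmental",
                       depth_range = c(0.3, 50)) {
  stopifnot(length(primitives) >= 1)
  archetype <- match.arg(archetype, .archetypes)
  structure(list(primitives = primitives, archetype = archetype,
                 depth_range = depth_range),
            class = "scene_spec")
}

#' Build a synthetic scene for a game archetype
#'
#' Deterministic given `seed`. The scene always contains a ground plane
#' (1.6 m below the eyes, clamped to the archetype's depth range), a back
#' wall at the far end of the range, and 4-8 foreground objects (boxes and
#' spheres) whose distances are drawn from the archetype's fixation-distance
#' law truncated to the range. One object is always placed within 5 deg of
#' straight ahead so the camera frustum is never empty.
#'
#' @param archetype One of `"rhythm"`, `"shooter"`, `"environmental"`,
#'   `"action_rhythm"`.
#' @param seed Integer seed; the same seed always yields the same scene.
#' @param depth_range Optional override `c(min, max)` of the object-distance
#'   range in meters.
#' @return An object of class `scene_spec` with elements `primitives`,
#'   `archetype`, `depth_range`.
#' @export
build_scene <- function(archetype, seed, depth_range = NULL) {
  archetype <- match.arg(archetype, .archetypes)
  if (is.null(depth_range)) depth_range <- .archetype_depth_range(archetype)
  stopifnot(length(depth_range) == 2, depth_range[1] > 0,
            depth_range[2] > depth_range[1])
  rng <- local_rng(seed)
  law <- fixation_distance_law(archetype)

  prims <- list()
  # ground plane 1.6 m below the eyes, but never nearer than the range allows
  ground_level <- -min(160, depth_range[2] * 100)
  prims[[1]] <- prim("ground_plane", center = c(0, ground_level, 0))
  # back wall closing the scene at the far end of the range
  far_cm <- depth_range[2] * 100
  prims[[2]] <- prim("wall", center = c(0, 0, far_cm),
                     extents = c(4 * far_cm, 4 * far_cm))

  n_obj <- 4L + rng$int(5L)  # 4..8 foreground objects
  d_m <- sample_fixation_distances(n_obj, law, rng = rng,
                                   range_m = depth_range)
  for (i in seq_len(n_obj)) {
    # first object guaranteed near the forward axis
    az <- if (i == 1L) rng$unif(-5, 5) else rng$unif(-25, 25)
    el <- if (i == 1L) rng$unif(-5, 5) else rng$unif(-15, 15)
    ctr <- helm_dir(az, el)[1, ] * d_m[i] * 100
    size <- rng$unif(0.05, 0.25) * d_m[i] * 100  # angular size roughly fixed
    prims[[length(prims) + 1L]] <-
      if (rng$unif(0, 1) < 0.5)
        prim("box", center = ctr, extents = rep(size, 3))
      else
        prim("sphere", center = ctr, radius = size / 2)
  }
  structure(list(primitives = prims, archetype = archetype,
                 depth_range = depth_range),
            class = "scene_spec")
}

#' @export
print.scene_spec <- function(x, ...) {
  kinds <- vapply(x$primitives, `[[`, "", "kind")
  cat(sprintf("scene_spec (%s): %d primitives [%s], depth range %.1f-%.1f m\n",
              x$archetype, length(kinds), paste(unique(kinds), collapse = ", "),
              x$depth_range[1], x$depth_range[2]))
  invisible(x)
}

#' Distances of scene primitives from the head origin
#'
#' For boxes, spheres and walls the distance to the primitive's center; for
#' the ground plane its perpendicular distance.
#'
#' @param scene A `scene_spec`.
#' @return Distances in meters.
#' @export
primitive_distances <- function(scene) {
  vapply(scene$primitives, function(p) {
    if (p$kind == "ground_plane") abs(p$center[2]) / 100
    else sqrt(sum(p$center^2)) / 100
  }, numeric(1))
}

# ---- ray casting ------------------------------------------------------------

# Cast n rays (origins, dirs: n x 3, cm, unit dirs) against every primitive;
# returns list(t = ray length in cm to nearest hit or Inf, prim = index or NA).
ray_cast <- function(scene, origins, dirs, eps = 1e-6) {
  origins <- rbind3(origins); dirs <- rbind3(dirs)
  n <- max(nrow(origins), nrow(dirs))
  if (nrow(origins) == 1L) origins <- origins[rep(1L, n), , drop = FALSE]
  if (nrow(dirs) == 1L) dirs <- dirs[rep(1L, n), , drop = FALSE]
  best_t <- rep(Inf, n); best_p <- rep(NA_integer_, n)
  for (i in seq_along(scene$primitives)) {
    t <- intersect_primitive(scene$primitives[[i]], origins, dirs, eps)
    better <- !is.na(t) & t < best_t
    best_t[better] <- t[better]; best_p[better] <- i
  }
  list(t = best_t, prim = best_p)
}

intersect_primitive <- function(p, o, d, eps) {
  switch(p$kind,
    ground_plane = {
      t <- (p$center[2] - o[, 2]) / d[, 2]
      t[!is.finite(t) | t <= eps] <- NA
      t
    },
    wall = {
      t <- (p$center[3] - o[, 3]) / d[, 3]
      px <- o[, 1] + t * d[, 1]; py <- o[, 2] + t * d[, 2]
      bad <- !is.finite(t) | t <= eps |
        abs(px - p$center[1]) > p$extents[1] / 2 |
        abs(py - p$center[2]) > p$extents[2] / 2
      t[bad] <- NA
      t
    },
    box = {
      lo <- p$center - p$extents / 2; hi <- p$center + p$extents / 2
      tmin <- rep(-Inf, nrow(o)); tmax <- rep(Inf, nrow(o))
      for (ax in 1:3) {
        invd <- 1 / d[, ax]
        t1 <- (lo[ax] - o[, ax]) * invd
        t2 <- (hi[ax] - o[, ax]) * invd
        tlo <- pmin(t1, t2); thi <- pmax(t1, t2)
        # rays parallel to the slab: inside-check via infinite bounds
        par <- abs(d[, ax]) < 1e-12
        inside <- o[, ax] >= lo[ax] & o[, ax] <= hi[ax]
        tlo[par] <- ifelse(inside[par], -Inf, Inf)
        thi[par] <- ifelse(inside[par], Inf, -Inf)
        tmin <- pmax(tmin, tlo); tmax <- pmin(tmax, thi)
      }
      t <- ifelse(tmax >= tmin & tmax > eps,
                  ifelse(tmin > eps, tmin, tmax), NA)
      t
    },
    sphere = {
      oc <- sweep(o, 2, p$center)
      b <- rowSums(oc * d)
      cc <- rowSums(oc^2) - p$radius^2
      disc <- b^2 - cc
      sq <- sqrt(pmax(disc, 0))
      t1 <- -b - sq; t2 <- -b + sq
      t <- ifelse(disc < 0, NA, ifelse(t1 > eps, t1, ifelse(t2 > eps, t2, NA)))
      t
    },
    stop("unknown primitive kind: ", p$kind))
}
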