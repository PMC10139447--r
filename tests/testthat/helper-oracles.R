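# Independent oracles and small fixtures shared across test files.

# quaternion algebra (independent of the package's rotation-matrix code)
quat_from_axis_angle <- function(axis, angle_deg) {
  axis <- axis / sqrt(sum(axis^2))
  half <- angle_deg * pi / 360
  c(cos(half), sin(half) * axis)
}

quat_mul <- function(p, q) {
  c(p[1] * q[1] - sum(p[-1] * q[-1]),
    p[1] * q[-1] + q[1] * p[-1] +
      c(p[3] * q[4] - p[4] * q[3],
        p[4] * q[2] - p[2] * q[4],
        p[2] * q[3] - p[3] * q[2]))
}

quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

# L2 pose via quaternions: yaw the primary direction, then the single
# rotation carrying it to the target direction
quat_l2_rotation <- function(center, fixation, primary_yaw_deg) {
  qp <- quat_from_axis_angle(c(0, 1, 0), primary_yaw_deg)
  p <- as.numeric(quat_to_matrix(qp) %*% c(0, 0, 1))
  v <- fixation - center
  v <- v / sqrt(sum(v^2))
  ax <- c(p[2] * v[3] - p[3] * v[2],
          p[3] * v[1] - p[1] * v[3],
          p[1] * v[2] - p[2] * v[1])
  s <- sqrt(sum(ax^2))
  ang <- atan2(s, sum(p * v)) * 180 / pi
  q <- if (s < 1e-14) qp else quat_mul(quat_from_axis_angle(ax, ang), qp)
  quat_to_matrix(q)
}

# simple fixed scenes
wall_scene <- function(z_m, width_m = 1000, height_m = 1000) {
  scene_spec(list(scene_primitive("wall", c(0, 0, z_m * 100),
                                  extents = c(width_m, height_m) * 100)))
}

ground_scene <- function(height_m = 1.6) {
  scene_spec(list(scene_primitive("ground_plane", c(0, -height_m * 100, 0))))
}

# noiseless trace fixating a list of 3-D points (cm)
noiseless_trace <- function(targets, duration = 0.3, peak_v = 300,
                            rate = 90, iod = 6.33, scene = wall_scene(60)) {
  script <- gaze_script(data.frame(x = targets[, 1], y = targets[, 2],
                                   z = targets[, 3], duration = duration),
                        saccade_peak_velocity = peak_v,
                        tracker_noise_sd = 0, sample_rate = rate)
  simulate_gaze(scene, script, seed = 7, iod = iod)
}

# point on the Vieth-Mueller circle through fixation (0, 0, z_f cm) at
# cyclopean azimuth alpha (deg), elevation 0
vm_circle_point <- function(z_f, alpha_deg, iod = 6.33) {
  a <- iod / 2
  zc <- (z_f^2 - a^2) / (2 * z_f)
  al <- alpha_deg * pi / 180
  t <- zc * cos(al) + sqrt(zc^2 * cos(al)^2 + a^2)
  c(t * sin(al), 0, t * cos(al))
}

expect_equal_tol <- function(object, expected, tol) {
  expect_true(max(abs(object - expected)) <= tol,
              label = sprintf("max|diff| = %.3g <= %.3g",
                              max(abs(object - expected)), tol))
}
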