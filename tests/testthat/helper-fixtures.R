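# shared generators for property-style tests; all randomness is drawn from
# the caller's RNG state (tests set their own seeds)

random_unit_quaternion <- function() {
  q <- stats::rnorm(4)
  q / sqrt(sum(q^2))
}

random_transform <- function(parent = "world", child = "tool", t_scale = 100) {
  pose_to_transform(random_unit_quaternion(), stats::rnorm(3, 0, t_scale),
                    tool_frame = child)
}

# uniform background with a darker disc; 0-based center (col, row)
disc_image <- function(shape = c(128, 128), center = c(64, 64), radius = 10,
                       background = 0.6, lesion = 0.1) {
  nr <- shape[1]; nc <- shape[2]
  cols <- rep(0:(nc - 1), each = nr)
  rows <- rep(0:(nr - 1), times = nc)
  inside <- (cols - center[1])^2 + (rows - center[2])^2 <= radius^2
  matrix(ifelse(inside, lesion, background), nr, nc)
}

# forward-construct probe-calibration observations from a known ground truth
probe_obs <- function(n = 8, spacing = c(0.08, 0.12),
                      sono_T_image = axis_rotation("x", pi / 6, c(5, -2, 7),
                                                   "sono", "image"),
                      world_sigma = 0) {
  px <- cbind(stats::runif(n, 0, 200), stats::runif(n, 0, 150))
  poses <- lapply(seq_len(n), function(i) random_transform(child = "sono"))
  w <- t(vapply(seq_len(n), function(i)
    transform_point(compose(poses[[i]], sono_T_image),
                    pixel_to_image_mm(spacing, px[i, ])) +
      stats::rnorm(3, 0, world_sigma),
    numeric(3)))
  data.frame(col = px[, 1], row = px[, 2],
             wx = w[, 1], wy = w[, 2], wz = w[, 3],
             world_T_sono = I(poses))
}

# poses pivoting about a fixed world point with a known tool-frame tip offset
pivot_poses <- function(n = 50, tip_offset = c(0, 0, 120),
                        pivot = c(10, -5, -1000), noise_sigma = 0) {
  lapply(seq_len(n), function(i) {
    R <- sononav:::quaternion_to_rotation(random_unit_quaternion())
    rigid_transform(R,
                    pivot - as.numeric(R %*% tip_offset) +
                      stats::rnorm(3, 0, noise_sigma),
                    "world", "needle")
  })
}

# constant-pose needle stream: identity rotation, given tool translation
constant_pose_stream <- function(translation, duration = 1, rate = 20) {
  n <- duration * rate
  data.frame(timestamp = (seq_len(n) - 1) / rate, tool_id = "needle",
             qw = 1, qx = 0, qy = 0, qz = 0,
             tx = translation[1], ty = translation[2], tz = translation[3])
}

default_cal <- function(spacing = c(0.1, 0.1)) {
  probe_calibration(spacing, rigid_transform(diag(3), c(0, 0, 0), "sono", "image"))
}
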