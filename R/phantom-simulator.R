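#' Build the evaluation phantom scene
#'
#' Synthetic counterpart of the physical accuracy phantom: a water-filled
#' hollow sphere of 16 mm inner diameter containing a concentric 8 mm
#' spherical lesion, with two surface notch markers (A and B) on a line
#' through the center, 19 mm apart. The marker midpoint defines the "true"
#' reference for accuracy evaluation.
#'
#' @param center numeric length-3 shell center, world mm.
#' @param axis unit length-3 vector along which the markers sit.
#' @param shell_inner_radius mm, default 8.
#' @param rf_radius lesion radius, mm, default 4; must be smaller than the
#'   shell radius.
#' @param lesion_contrast,background_level B-mode rendering intensities in
#'   `[0, 1]`.
#' @return A `phantom_scene`.
#' @export
build_eval_phantom <- function(center, axis = c(0, 1, 0),
                               shell_inner_radius = 8, rf_radius = 4,
                               lesion_contrast = 0.1, background_level = 0.6) {
  center <- as.numeric(center); axis <- as.numeric(axis)
  stopifnot(length(center) == 3, all(is.finite(center)), length(axis) == 3)
  if (abs(sqrt(sum(axis^2)) - 1) > 1e-9) stop("build_eval_phantom: axis must be a unit vector")
  if (!(rf_radius > 0 && rf_radius < shell_inner_radius))
    stop("build_eval_phantom: lesion must fit inside the shell")
  marker_gap <- 19
  scene <- structure(list(
    shell_center = center, shell_inner_radius = shell_inner_radius,
    rf_center = center, rf_radius = rf_radius,
    marker_a = center + axis * marker_gap / 2,
    marker_b = center - axis * marker_gap / 2,
    lesion_contrast = lesion_contrast, background_level = background_level),
    class = "phantom_scene")
  stopifnot(abs(sqrt(sum((scene$marker_a - scene$marker_b)^2)) - marker_gap) < 1e-9,
            max(abs((scene$marker_a + scene$marker_b) / 2 - center)) < 1e-9)
  scene
}

#' Build a neck-phantom-like scene
#'
#' Soft-tissue phantom analogue with a single spherical lesion of 8-10 mm
#' diameter at a given position; no surface markers, so it supports
#' navigation exercises but not marker-referenced accuracy evaluation.
#'
#' @param rf_center numeric length-3, world mm.
#' @param rf_diameter lesion diameter, mm in `[8, 10]` by default range.
#' @inheritParams build_eval_phantom
#' @return A `phantom_scene` without markers (`marker_a`/`marker_b` are `NA`).
#' @export
build_neck_phantom <- function(rf_center, rf_diameter = 8,
                               lesion_contrast = 0.1, background_level = 0.6) {
  rf_center <- as.numeric(rf_center)
  stopifnot(length(rf_center) == 3, rf_diameter > 0)
  structure(list(
    shell_center = rf_center, shell_inner_radius = Inf,
    rf_center = rf_center, rf_radius = rf_diameter / 2,
    marker_a = rep(NA_real_, 3), marker_b = rep(NA_real_, 3),
    lesion_contrast = lesion_contrast, background_level = background_level),
    class = "phantom_scene")
}

#' Tracking and speckle noise model
#'
#' @param tracking_sigma per-axis standard deviation of the optical tracker's
#'   translation noise, mm (default 0.25, the tracker's quoted intrinsic
#'   error).
#' @param speckle_sigma log-scale standard deviation of the multiplicative,
#'   unit-mean log-normal speckle (default 0.3).
#' @param seed integer RNG seed; all stochastic simulator output is
#'   reproducible from `(seed, parameters)` alone.
#' @return A `noise_model`.
#' @export
noise_model <- function(tracking_sigma = 0.25, speckle_sigma = 0.3, seed = 1L) {
  stopifnot(tracking_sigma >= 0, speckle_sigma >= 0)
  structure(list(tracking_sigma = tracking_sigma, speckle_sigma = speckle_sigma,
                 seed = as.integer(seed)),
            class = "noise_model")
}

#' Simulate a tracked pose stream
#'
#' Samples a pose trajectory at a fixed rate and perturbs the translations
#' with independent zero-mean Gaussian noise of `tracking_sigma` per axis
#' (rotations are left exact by default, matching a scalar tracker error
#' figure).
#'
#' @param trajectory function of time (s) returning a list with `quaternion`
#'   (unit, `(w, x, y, z)`) and `translation` (mm).
#' @param duration seconds, >= 0.
#' @param rate sampling rate, Hz.
#' @param noise a `noise_model`.
#' @param tool_id label stored in the stream (default `"needle"`).
#' @return data.frame pose log (`timestamp,tool_id,qw,...,tz`) with
#'   `duration * rate` samples at `t = 0, 1/rate, ...`.
#' @export
simulate_pose_stream <- function(trajectory, duration, rate = 20,
                                 noise = noise_model(), tool_id = "needle") {
  stopifnot(is.function(trajectory), rate > 0)
  if (duration < 0) stop("simulate_pose_stream: negative duration")
  n <- round(duration * rate)
  ts <- (seq_len(n) - 1) / rate
  q <- matrix(0, n, 4)
  tr <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    p <- trajectory(ts[i])
    q[i, ] <- p$quaternion / sqrt(sum(p$quaternion^2))
    tr[i, ] <- p$translation
  }
  if (noise$tracking_sigma > 0 && n > 0)
    tr <- tr + withr_seed(noise$seed,
                          matrix(stats::rnorm(3 * n, 0, noise$tracking_sigma), n, 3))
  data.frame(timestamp = ts, tool_id = rep(tool_id, n),
             qw = q[, 1], qx = q[, 2], qy = q[, 3], qz = q[, 4],
             tx = tr[, 1], ty = tr[, 2], tz = tr[, 3])
}

# evaluate expr under a local RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

#' Render a B-mode-like frame of a phantom scene
#'
#' The image plane is the set of world points reached from pixels through the
#' calibrated chain world <- sono <- image. Pixels whose world point falls
#' inside the lesion sphere take the lesion intensity, all others the
#' background level; unit-mean multiplicative log-normal speckle is applied
#' on top. The analytic ground truth is the pixel projection of the in-plane
#' disc center (the sphere center's orthogonal projection onto the plane), or
#' `NULL` when the plane misses the lesion.
#'
#' @param scene a `phantom_scene`.
#' @param world_T_sono `rigid_transform`, the probe pose.
#' @param cal a `probe_calibration`.
#' @param image_shape integer length-2 `(rows, cols)`.
#' @param noise a `noise_model`; `speckle_sigma = 0` renders noiseless.
#' @return list with `image` (matrix in `[0, 1]`), `ground_truth_px`
#'   (0-based `(col, row)` or `NULL`) and `disc_radius_px` (axial-spacing
#'   equivalent, or `NULL`).
#' @export
render_bmode <- function(scene, world_T_sono, cal, image_shape = c(128, 128),
                         noise = noise_model(speckle_sigma = 0)) {
  stopifnot(inherits(scene, "phantom_scene"), inherits(cal, "probe_calibration"),
            inherits(world_T_sono, "rigid_transform"))
  nr <- image_shape[1]; nc <- image_shape[2]
  world_T_image <- compose(world_T_sono, cal$sono_T_image)

  # lesion center in image-frame mm; z is the signed plane-to-center distance
  q <- transform_point(invert_transform(world_T_image), scene$rf_center)

  cols <- rep(0:(nc - 1), each = nr)
  rows <- rep(0:(nr - 1), times = nc)
  x <- cols * cal$spacing[1]
  y <- rows * cal$spacing[2]
  # inclusive boundary with a small relative tolerance: pixel lattice points
  # can fall exactly on the sphere, and round-off from the pose chain must not
  # flip them asymmetrically
  r2 <- scene$rf_radius^2
  inside <- (x - q[1])^2 + (y - q[2])^2 + q[3]^2 <= r2 + 1e-9 * max(r2, 1)
  img <- matrix(ifelse(inside, scene$lesion_contrast, scene$background_level),
                nrow = nr, ncol = nc)

  if (noise$speckle_sigma > 0) {
    img <- withr_seed(noise$seed, {
      s <- noise$speckle_sigma
      img * matrix(exp(stats::rnorm(nr * nc, -s^2 / 2, s)), nr, nc)
    })
    img <- pmin(pmax(img, 0), 1)
  }

  hit <- abs(q[3]) <= scene$rf_radius
  list(image = img,
       ground_truth_px = if (hit) c(col = q[1] / cal$spacing[1],
                                    row = q[2] / cal$spacing[2]) else NULL,
       disc_radius_px = if (hit) sqrt(scene$rf_radius^2 - q[3]^2) / mean(cal$spacing)
                        else NULL)
}

#' Simulate one accuracy-measurement trial
#'
#' One end-to-end pass of the target-marking workflow on the simulated
#' phantom: render a frame from the true probe pose, perturb the tracked pose
#' with tracking noise, segment the lesion, register its centroid into the
#' world frame through the noisy pose, and record the euclidean deviation
#' from the true lesion center.
#'
#' @param scene a `phantom_scene`.
#' @param world_T_sono true probe pose (`rigid_transform`); its image plane
#'   must intersect the lesion.
#' @param cal a `probe_calibration`.
#' @param noise a `noise_model`.
#' @param image_shape passed to [render_bmode()].
#' @param seed overrides `noise$seed` when given.
#' @return A `trial_record`: list with `measured` (world mm), `deviation`
#'   (mm), `target` (the registered `target_sphere`) and `seed`.
#' @export
simulate_trial <- function(scene, world_T_sono, cal, noise = noise_model(),
                           image_shape = c(128, 128), seed = NULL) {
  if (!is.null(seed)) noise$seed <- as.integer(seed)
  frame <- render_bmode(scene, world_T_sono, cal, image_shape, noise)
  if (is.null(frame$ground_truth_px))
    stop("simulate_trial: probe plane does not intersect the lesion")
  seg <- detect_lesion(frame$image)

  tracked <- if (noise$tracking_sigma > 0) {
    withr_seed(noise$seed + 1L, rigid_transform(
      world_T_sono$rotation,
      world_T_sono$translation + stats::rnorm(3, 0, noise$tracking_sigma),
      world_T_sono$parent_frame, world_T_sono$child_frame))
  } else world_T_sono

  target <- register_target(seg, cal, tracked)
  structure(list(measured = target$m,
                 deviation = sqrt(sum((target$m - scene$rf_center)^2)),
                 target = target, seed = noise$seed),
            class = "trial_record")
}

#' Probe pose whose image plane passes through a world point
#'
#' Places the image-frame origin so that a given pixel maps to `point`, with
#' the plane orientation set by `world_T_image_rotation`. Helper for
#' constructing simulation scenes with known ground truth.
#'
#' @param point world point the plane must contain, mm.
#' @param cal a `probe_calibration`.
#' @param at_pixel 0-based `(col, row)` that should map to `point`.
#' @param world_R_image 3x3 rotation of the image frame in world coordinates
#'   (default identity).
#' @param plane_offset signed out-of-plane shift along the image normal, mm.
#' @return `rigid_transform` world <- sono consistent with `cal`.
#' @export
probe_pose_through <- function(point, cal, at_pixel = c(64, 64),
                               world_R_image = diag(3), plane_offset = 0) {
  stopifnot(inherits(cal, "probe_calibration"))
  p_img <- pixel_to_image_mm(cal$spacing, at_pixel)
  normal <- world_R_image[, 3]
  world_T_image <- rigid_transform(
    world_R_image,
    as.numeric(point) + plane_offset * normal - as.numeric(world_R_image %*% p_img),
    "world", "image")
  compose(world_T_image, invert_transform(cal$sono_T_image))
}
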