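test_that("target registration maps the centroid through the calibrated chain", {
  cal <- default_cal(c(0.1, 0.1))
  seg <- structure(list(mask = matrix(TRUE, 1, 1),
                        centroid = c(col = 100, row = 50),
                        equivalent_diameter_px = 80),
                   class = "segmentation_result")
  id <- rigid_transform(diag(3), c(0, 0, 0), "world", "sono")
  tg <- register_target(seg, cal, id)
  expect_equal(tg$m, c(10, 5, 0))
  expect_equal(tg$r, 4.0)

  shifted <- rigid_transform(diag(3), c(0, 0, -1000), "world", "sono")
  expect_equal(register_target(seg, cal, shifted)$m, c(10, 5, -1000))

  # anisotropic spacing: radius uses the mean of the two spacings
  cal2 <- default_cal(c(0.08, 0.12))
  expect_equal(register_target(seg, cal2, id)$r, 80 * 0.1 / 2)
})

test_that("registration is equivariant under a rigid world transform", {
  set.seed(41)
  cal <- default_cal()
  seg <- structure(list(mask = matrix(TRUE, 1, 1),
                        centroid = c(col = 80, row = 40),
                        equivalent_diameter_px = 60),
                   class = "segmentation_result")
  for (i in 1:10) {
    w_T_s <- random_transform(child = "sono")
    G <- random_transform(child = "world")
    m0 <- register_target(seg, cal, w_T_s)$m
    moved <- compose(rigid_transform(G$rotation, G$translation, "world", "world"),
                     w_T_s)
    expect_equal(register_target(seg, cal, moved)$m, transform_point(G, m0),
                 tolerance = 1e-9)
  }
})

test_that("alignment tiers follow the line-to-center distance with ray semantics", {
  tg <- target_sphere(c(0, 0, 0), 4)
  hit <- classify_alignment(needle_line(c(0, 0, 10), c(0, 0, -1)), tg)
  expect_identical(hit$return_value, 2L)
  expect_equal(hit$line_distance, 0)
  expect_true(hit$forward)

  miss <- classify_alignment(needle_line(c(10, 0, 10), c(0, 0, -1)), tg,
                             near_factor = 2)
  expect_identical(miss$return_value, 0L)
  expect_equal(miss$line_distance, 10)

  near <- classify_alignment(needle_line(c(6, 0, 10), c(0, 0, -1)), tg,
                             near_factor = 2)
  expect_identical(near$return_value, 1L)
  expect_equal(near$line_distance, 6)

  # boundaries are inclusive: tangent at r counts as hit, at near_factor*r as near
  expect_identical(classify_alignment(needle_line(c(4, 0, 10), c(0, 0, -1)),
                                      tg)$return_value, 2L)
  expect_identical(classify_alignment(needle_line(c(8, 0, 10), c(0, 0, -1)),
                                      tg, 2)$return_value, 1L)

  # pointing away from the target is never a hit
  away <- classify_alignment(needle_line(c(0, 0, 10), c(0, 0, 1)), tg)
  expect_identical(away$return_value, 0L)
  expect_false(away$forward)
  expect_error(needle_line(c(0, 0, 0), c(0, 0, 0)), "zero direction")
})

test_that("return value is non-increasing in line distance", {
  tg <- target_sphere(c(0, 0, 0), 4)
  offsets <- seq(0, 12, by = 0.25)
  rv <- vapply(offsets, function(x)
    classify_alignment(needle_line(c(x, 0, 10), c(0, 0, -1)), tg, 2)$return_value,
    integer(1))
  expect_true(all(diff(rv) <= 0))
})

test_that("hit classification agrees with a dense line-sampling oracle", {
  set.seed(42)
  n_checked <- 0
  while (n_checked < 1000) {
    tip <- runif(3, -50, 50)
    m <- runif(3, -50, 50)
    r <- runif(1, 1, 10)
    d <- rnorm(3); d <- d / sqrt(sum(d^2))
    if (sqrt(sum((tip - m)^2)) <= r + 0.1) next  # tip inside target: degenerate
    a <- classify_alignment(needle_line(tip, d), target_sphere(m, r))
    if (abs(a$line_distance - r) < 0.05) next   # sampling cannot resolve tangency
    # brute force: march along the forward ray and test sphere membership
    ts <- seq(0, 300, length.out = 4001)
    pts <- outer(ts, d) + matrix(tip, length(ts), 3, byrow = TRUE)
    inside <- rowSums(sweep(pts, 2, m)^2) <= r^2
    expect_identical(a$return_value == 2L, any(inside))
    n_checked <- n_checked + 1
  }
})

test_that("insertion depth reports closest approach and proximal surface", {
  tg <- target_sphere(c(0, 0, 0), 4)
  d1 <- insertion_depth(needle_line(c(0, 0, 10), c(0, 0, -1)), tg)
  expect_equal(d1$depth, 10)
  expect_equal(d1$surface_distance, 6)

  d2 <- insertion_depth(needle_line(c(3, 0, 10), c(0, 0, -1)), tg)
  expect_equal(d2$depth, 10)
  expect_equal(d2$line_distance, 3)
  expect_equal(d2$surface_distance, 10 - sqrt(7))

  # near (tier 1) alignment has no pierce point, so no surface distance
  d3 <- insertion_depth(needle_line(c(6, 0, 10), c(0, 0, -1)), tg)
  expect_true(is.na(d3$surface_distance))

  expect_error(insertion_depth(needle_line(c(0, 0, 10), c(0, 0, 1)), tg),
               class = "target_behind_tip")
})

test_that("depth is non-negative whenever the target is forward", {
  set.seed(43)
  for (i in 1:200) {
    tip <- runif(3, -50, 50); m <- runif(3, -50, 50)
    d <- rnorm(3); d <- d / sqrt(sum(d^2))
    a <- classify_alignment(needle_line(tip, d), target_sphere(m, runif(1, 1, 8)))
    if (a$forward) expect_gte(a$depth, 0)
  }
})

test_that("tone mapping is the fixed three-tier frequency table", {
  expect_equal(tone_for(0), 200)
  expect_equal(tone_for(1), 350)
  expect_equal(tone_for(2), 440)
  expect_error(tone_for(3), "0, 1 or 2")
  expect_error(tone_for(-1), "0, 1 or 2")
})

test_that("session replay ticks at the update rate with continuous tones", {
  tip_cal <- structure(list(tip_offset = c(0, 0, 120), pivot_point = c(0, 0, 0),
                            residual_rms = 0), class = "tip_calibration")
  tg <- target_sphere(c(0, 0, 50), 4)
  # tool at (0,0,-110): tip at (0,0,10), shaft axis +z aims at the target
  stream <- constant_pose_stream(c(0, 0, -110), duration = 1, rate = 20)
  log <- run_session(stream, tip_cal, tg, rate = 20)
  expect_equal(nrow(log), 20)
  expect_true(all(log$return_value == 2L))
  expect_true(all(log$frequency_hz == 440))
  expect_equal(log$depth, rep(40, 20))
  expect_equal(log$transition, c(TRUE, rep(FALSE, 19)))
})

test_that("a sweep across the target walks the tiers 0 -> 1 -> 2", {
  tip_cal <- rigid_transform(diag(3), c(0, 0, 120), "needle", "tip")
  tg <- target_sphere(c(0, 0, 50), 4)
  n <- 41
  xs <- seq(20, 0, length.out = n)   # lateral offset = line distance
  stream <- data.frame(timestamp = (seq_len(n) - 1) / 20, tool_id = "needle",
                       qw = 1, qx = 0, qy = 0, qz = 0,
                       tx = xs, ty = 0, tz = -110)
  log <- run_session(stream, tip_cal, tg, rate = 20, near_factor = 2)
  rv <- rle(log$return_value)$values
  expect_equal(rv, c(0L, 1L, 2L))
  freq <- rle(log$frequency_hz)$values
  expect_equal(freq, c(200, 350, 440))
  expect_equal(sum(log$transition), 3)   # initial state plus two tier changes

  expect_equal(nrow(run_session(stream[0, ], tip_cal, tg)), 0)
  unsorted <- stream[c(2, 1, 3:n), ]
  expect_error(run_session(unsorted, tip_cal, tg), "sorted")
})

test_that("tone rendering produces a bounded sine stream and a WAV file", {
  tip_cal <- rigid_transform(diag(3), c(0, 0, 120), "needle", "tip")
  tg <- target_sphere(c(0, 0, 50), 4)
  log <- run_session(constant_pose_stream(c(0, 0, -110), 0.25, 20), tip_cal, tg)
  wave <- render_tones(log, tick_duration = 0.05, sample_rate = 8000)
  expect_length(wave, nrow(log) * 400)
  expect_lte(max(abs(wave)), 1)
  wav <- tempfile(fileext = ".wav")
  render_tones(log, tick_duration = 0.05, sample_rate = 8000, path = wav)
  bytes <- readBin(wav, "raw", 64)
  expect_identical(rawToChar(bytes[1:4]), "RIFF")
  expect_identical(rawToChar(bytes[9:16]), "WAVEfmt ")
})
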