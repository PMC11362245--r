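#' Spherical target in world coordinates
#'
#' The registered lesion is modelled as a sphere with center `m` and radius
#' `r`; a needle line hits the target when it intersects the sphere
#' `(x - m_x)^2 + (y - m_y)^2 + (z - m_z)^2 = r^2` ahead of the tip.
#'
#' @param m numeric length-3 center, world mm.
#' @param r radius, mm, > 0.
#' @return A `target_sphere`.
#' @export
target_sphere <- function(m, r) {
  m <- as.numeric(m)
  stopifnot(length(m) == 3, all(is.finite(m)), is.finite(r), r > 0)
  structure(list(m = m, r = r), class = "target_sphere")
}

#' Tracked needle as a ray
#'
#' @param tip numeric length-3 tip position, world mm.
#' @param direction numeric length-3 shaft direction (tip-to-target sense);
#'   normalized internally, must be non-zero.
#' @return A `needle_line` with unit `direction`.
#' @export
needle_line <- function(tip, direction) {
  tip <- as.numeric(tip); direction <- as.numeric(direction)
  stopifnot(length(tip) == 3, length(direction) == 3, all(is.finite(c(tip, direction))))
  n <- sqrt(sum(direction^2))
  if (n < 1e-12) stop("needle_line: zero direction vector")
  structure(list(tip = tip, direction = direction / n), class = "needle_line")
}

#' Register the segmented lesion into the world frame
#'
#' Maps the lesion's pixel centroid through the calibrated chain
#' world <- sono <- image: the centroid is embedded in the metric image plane
#' via the pixel spacing and pushed through
#' `compose(world_T_sono, sono_T_image)`. The target radius is taken from the
#' segmentation's equivalent diameter, converted with the mean of the two
#' pixel spacings (anisotropy beyond that is ignored for the sphere model).
#'
#' @param segmentation a `segmentation_result`, or a numeric image matrix
#'   (then [detect_lesion()] is run with default settings).
#' @param cal a `probe_calibration`.
#' @param world_T_sono `rigid_transform` world <- sono, the probe pose
#'   captured at the same instant as the frame.
#' @return A `target_sphere` in world coordinates.
#' @export
register_target <- function(segmentation, cal, world_T_sono) {
  stopifnot(inherits(cal, "probe_calibration"),
            inherits(world_T_sono, "rigid_transform"))
  if (is.matrix(segmentation)) segmentation <- detect_lesion(segmentation)
  stopifnot(inherits(segmentation, "segmentation_result"))
  world_T_image <- compose(world_T_sono, cal$sono_T_image)
  m <- transform_point(world_T_image,
                       pixel_to_image_mm(cal$spacing, segmentation$centroid))
  target_sphere(m, segmentation$equivalent_diameter_px * mean(cal$spacing) / 2)
}

#' Classify needle alignment against the target sphere
#'
#' Three-tier classifier on the perpendicular distance from the extended
#' needle line to the sphere center, with ray (forward) semantics: a line
#' that would only cross the sphere behind the tip cannot be a hit.
#'
#' * return value 2 (hit): line distance <= r and the target lies ahead;
#' * return value 1 (near): r < line distance <= near_factor * r, ahead;
#' * return value 0 (miss): otherwise.
#'
#' Boundaries are inclusive (a tangent line counts as a hit).
#'
#' @param line a `needle_line`.
#' @param target a `target_sphere`.
#' @param near_factor multiple of `r` bounding the "approaching" band,
#'   > 1 (default 2).
#' @return An `alignment_result`: list with `return_value` (0/1/2),
#'   `line_distance` (mm), `depth` (mm along the shaft to the closest
#'   approach to the center; `NA` when the target is behind the tip) and
#'   `forward` (logical).
#' @export
classify_alignment <- function(line, target, near_factor = 2) {
  stopifnot(inherits(line, "needle_line"), inherits(target, "target_sphere"),
            near_factor > 1)
  v <- target$m - line$tip
  along <- sum(v * line$direction)        # signed depth to closest approach
  perp2 <- sum(v^2) - along^2             # squared line distance
  line_distance <- sqrt(max(perp2, 0))
  forward <- along > 0
  return_value <- if (forward && line_distance <= target$r) 2L
                  else if (forward && line_distance <= near_factor * target$r) 1L
                  else 0L
  structure(list(return_value = return_value,
                 line_distance = line_distance,
                 depth = if (forward) along else NA_real_,
                 forward = forward),
            class = "alignment_result")
}

#' Insertion depth along the needle axis
#'
#' Depth is the along-axis distance from the tip to the point of closest
#' approach to the sphere center. When the needle line actually pierces the
#' sphere (alignment return value 2), the distance to the proximal sphere
#' surface, `depth - sqrt(r^2 - line_distance^2)`, is reported as well.
#'
#' @param line a `needle_line`.
#' @param target a `target_sphere`.
#' @param near_factor passed to [classify_alignment()].
#' @return list with `depth` (mm), `surface_distance` (mm or `NA` when not a
#'   hit), `line_distance` and `return_value`.
#' @export
insertion_depth <- function(line, target, near_factor = 2) {
  a <- classify_alignment(line, target, near_factor)
  if (!a$forward)
    stop(errorCondition("insertion_depth: target lies behind the needle tip",
                        class = c("target_behind_tip", "error", "condition")))
  surface <- if (a$return_value == 2L)
    a$depth - sqrt(max(target$r^2 - a$line_distance^2, 0)) else NA_real_
  list(depth = a$depth, surface_distance = surface,
       line_distance = a$line_distance, return_value = a$return_value)
}

#' Acoustic feedback frequency for an alignment return value
#'
#' Fixed mapping: 0 (miss) -> 200 Hz low tone, 1 (approaching) -> 350 Hz,
#' 2 (optimal insertion angle) -> 440 Hz high tone.
#'
#' @param return_value integer 0, 1 or 2.
#' @return frequency in Hz.
#' @export
tone_for <- function(return_value) {
  if (length(return_value) != 1 || !return_value %in% c(0, 1, 2))
    stop("tone_for: return value must be 0, 1 or 2")
  c(`0` = 200, `1` = 350, `2` = 440)[[as.character(as.integer(return_value))]]
}

#' Replay a tracked needle stream against a registered target
#'
#' Evaluates alignment feedback at a fixed update rate (default 20 Hz, the
#' cadence at which depth and tone are recomputed during navigation). Ticks
#' run from the first pose timestamp to the last; at each tick the most
#' recent pose at or before the tick is evaluated, one alignment result and
#' one tone event per tick, with transition markers where the return value
#' changes.
#'
#' @param poses data.frame of needle pose samples with columns
#'   `timestamp,qw,qx,qy,qz,tx,ty,tz`, sorted by timestamp.
#' @param tip_cal a `tip_calibration` (or `rigid_transform` needle <- tip).
#' @param target a `target_sphere`.
#' @param rate update rate, Hz (default 20).
#' @param near_factor passed to [classify_alignment()].
#' @param shaft_axis needle shaft direction in the tool frame, default
#'   `c(0, 0, 1)`.
#' @return data.frame with one row per tick: `timestamp`, `return_value`,
#'   `line_distance`, `depth`, `forward`, `frequency_hz`, `transition`.
#' @export
run_session <- function(poses, tip_cal, target, rate = 20, near_factor = 2,
                        shaft_axis = c(0, 0, 1)) {
  stopifnot(inherits(target, "target_sphere"), rate > 0)
  needle_T_tip <- if (inherits(tip_cal, "tip_calibration")) tip_transform(tip_cal)
                  else tip_cal
  stopifnot(inherits(needle_T_tip, "rigid_transform"))
  empty <- data.frame(timestamp = numeric(0), return_value = integer(0),
                      line_distance = numeric(0), depth = numeric(0),
                      forward = logical(0), frequency_hz = numeric(0),
                      transition = logical(0))
  if (is.null(poses) || nrow(poses) == 0) return(empty)
  if (is.unsorted(poses$timestamp)) stop("run_session: pose stream must be sorted by timestamp")

  t0 <- poses$timestamp[1]
  tn <- poses$timestamp[nrow(poses)]
  ticks <- t0 + (0:floor((tn - t0) * rate + 1e-9)) / rate
  prev <- NA_integer_
  rows <- lapply(ticks, function(tk) {
    i <- findInterval(tk + 1e-12, poses$timestamp)   # nearest pose at/before tick
    w_T_n <- pose_to_transform(c(poses$qw[i], poses$qx[i], poses$qy[i], poses$qz[i]),
                               c(poses$tx[i], poses$ty[i], poses$tz[i]), "needle")
    tip <- needle_tip_world(w_T_n, needle_T_tip)
    dir <- as.numeric(w_T_n$rotation %*% shaft_axis)
    a <- classify_alignment(needle_line(tip, dir), target, near_factor)
    data.frame(timestamp = tk, return_value = a$return_value,
               line_distance = a$line_distance,
               depth = if (is.na(a$depth)) NA_real_ else a$depth,
               forward = a$forward, frequency_hz = tone_for(a$return_value))
  })
  log <- do.call(rbind, rows)
  log$transition <- c(TRUE, diff(log$return_value) != 0)
  log
}

#' Render a tone-event log as a WAV-style sine waveform
#'
#' Convenience only: returns the sample vector (and optionally writes a
#' minimal PCM WAV file) for the per-tick tone frequencies of
#' [run_session()].
#'
#' @param events data.frame from [run_session()].
#' @param tick_duration seconds per tick (default 1/20).
#' @param sample_rate audio sample rate, Hz (default 44100).
#' @param path optional output WAV path.
#' @return numeric sample vector in `[-1, 1]`, invisibly when `path` given.
#' @export
render_tones <- function(events, tick_duration = 0.05, sample_rate = 44100,
                         path = NULL) {
  n <- round(tick_duration * sample_rate)
  wave <- unlist(lapply(events$frequency_hz, function(f)
    sin(2 * pi * f * seq_len(n) / sample_rate)))
  if (is.null(wave)) wave <- numeric(0)
  if (!is.null(path)) {
    write_wav_pcm16(wave, sample_rate, path)
    return(invisible(wave))
  }
  wave
}

# minimal 16-bit mono PCM WAV writer
write_wav_pcm16 <- function(samples, sample_rate, path) {
  pcm <- as.integer(pmax(pmin(samples, 1), -1) * 32767)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * length(pcm)), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(as.integer(16), con, size = 4, endian = "little")  # fmt chunk size
  writeBin(as.integer(1), con, size = 2, endian = "little")   # PCM
  writeBin(as.integer(1), con, size = 2, endian = "little")   # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2), con, size = 4, endian = "little")
  writeBin(as.integer(2), con, size = 2, endian = "little")
  writeBin(as.integer(16), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * length(pcm)), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
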