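#' Reference center from the surface markers
#'
#' The two surface notches of the evaluation phantom lie on a line through
#' the shell center, so their needle-probed midpoint defines the "true"
#' reference position for accuracy evaluation.
#'
#' @param marker_a,marker_b numeric length-3 world points, mm.
#' @return numeric length-3 component-wise midpoint, mm.
#' @export
reference_center <- function(marker_a, marker_b) {
  marker_a <- as.numeric(marker_a); marker_b <- as.numeric(marker_b)
  stopifnot(length(marker_a) == 3, length(marker_b) == 3,
            all(is.finite(c(marker_a, marker_b))))
  (marker_a + marker_b) / 2
}

#' Euclidean deviation between a measured point and the reference
#'
#' @param p,ref numeric length-3 world points, mm.
#' @return distance in mm (tables report it at 4 decimals).
#' @export
deviation <- function(p, ref) {
  p <- as.numeric(p); ref <- as.numeric(ref)
  stopifnot(length(p) == 3, length(ref) == 3, all(is.finite(c(p, ref))))
  sqrt(sum((p - ref)^2))
}

#' Component-wise mean position with half-away-from-zero rounding
#'
#' The mean measured position E is conventionally reported rounded; rounding
#' is half-away-from-zero (so e.g. a mean component of 91.073 prints as 91.1
#' at one decimal), not banker's rounding.
#'
#' @param points numeric matrix (n x 3) or list of length-3 points, mm.
#' @param decimals decimal places for the report; `NULL` leaves the mean
#'   unrounded.
#' @return numeric length-3 mean position, mm.
#' @export
mean_position <- function(points, decimals = 1) {
  pts <- as_point_matrix(points)
  if (nrow(pts) == 0) stop("mean_position: empty point list")
  m <- unname(colMeans(pts))
  if (is.null(decimals)) m else round_half_away(m, decimals)
}

round_half_away <- function(x, digits) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

as_point_matrix <- function(points) {
  if (is.list(points) && !is.data.frame(points))
    points <- do.call(rbind, lapply(points, as.numeric))
  pts <- as.matrix(points)
  storage.mode(pts) <- "double"
  stopifnot(ncol(pts) == 3, all(is.finite(pts)))
  pts
}

#' Maximum surgical deviation
#'
#' Operationally defined as the euclidean distance between the mean measured
#' position, rounded to `decimals` places (default 1), and the reference
#' center. `decimals = NULL` gives the unrounded alternative.
#'
#' @param points measured world positions (matrix or list), mm.
#' @param ref reference world point, mm.
#' @param decimals rounding applied to the mean before taking the distance.
#' @return distance in mm.
#' @export
max_surgical_deviation <- function(points, ref, decimals = 1) {
  deviation(mean_position(points, decimals), ref)
}

#' Count measured positions inside the target
#'
#' A trial is a hit when its measured position deviates from the reference by
#' at most the target radius (center containment of the measured point in the
#' lesion sphere).
#'
#' @param points measured world positions, mm.
#' @param ref reference world point, mm.
#' @param radius hit radius, mm (> 0); 4 mm for the 8 mm lesion.
#' @return integer hit count.
#' @export
hit_count <- function(points, ref, radius) {
  stopifnot(radius > 0)
  pts <- as_point_matrix(points)
  sum(sqrt(rowSums(sweep(pts, 2, as.numeric(ref))^2)) <= radius)
}

#' Evaluate a trial table against the phantom markers
#'
#' Full accuracy analysis: per-trial euclidean deviations from the
#' marker-midpoint reference, mean position E (rounded for reporting),
#' maximum surgical deviation, and the hit count within the lesion radius.
#'
#' @param trials data.frame with columns `trial_id,x,y,z` (world mm).
#' @param marker_a,marker_b phantom surface markers, world mm.
#' @param hit_radius mm, default 4 (8 mm lesion).
#' @param decimals rounding of the reported mean position, default 1.
#' @param reference_decimals precision at which the marker-midpoint reference
#'   is recorded before deviations are taken, default 2 (tracked positions
#'   are logged at 0.01 mm); `NULL` uses the exact midpoint.
#' @return An `evaluation_report`: list with `reference`, `trials` (input
#'   plus a `deviation_mm` column), `mean_position`, `mean_position_raw`,
#'   `max_surgical_deviation`, `hit_count`, `hit_radius`.
#' @export
evaluate_table <- function(trials, marker_a, marker_b, hit_radius = 4,
                           decimals = 1, reference_decimals = 2) {
  trials <- as.data.frame(trials)
  if (nrow(trials) == 0) stop("evaluate_table: no trials")
  stopifnot(all(c("x", "y", "z") %in% names(trials)), hit_radius > 0)
  ref <- reference_center(marker_a, marker_b)
  if (!is.null(reference_decimals)) ref <- round_half_away(ref, reference_decimals)
  pts <- as.matrix(trials[, c("x", "y", "z")])
  trials$deviation_mm <- apply(pts, 1, deviation, ref = ref)
  structure(list(
    reference = ref,
    trials = trials,
    mean_position = mean_position(pts, decimals),
    mean_position_raw = mean_position(pts, NULL),
    max_surgical_deviation = max_surgical_deviation(pts, ref, decimals),
    hit_count = hit_count(pts, ref, hit_radius),
    hit_radius = hit_radius),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Surgical accuracy evaluation\n")
  cat(sprintf("  reference center (mm): %s\n", paste(format(x$reference), collapse = ", ")))
  cat(sprintf("  trials: %d\n", nrow(x$trials)))
  cat(sprintf("  mean position E (mm): %s\n", paste(format(x$mean_position), collapse = ", ")))
  cat(sprintf("  max surgical deviation (mm): %.4f\n", x$max_surgical_deviation))
  cat(sprintf("  hits within %.1f mm: %d of %d\n", x$hit_radius, x$hit_count, nrow(x$trials)))
  invisible(x)
}

#' Globe-model export of an evaluation report
#'
#' JSON-ready representation of the 3-D visualization: hollow shell, lesion
#' sphere, reference point and measured points.
#'
#' @param report an `evaluation_report`.
#' @param shell_radius shell inner radius, mm (default 8).
#' @return list suitable for `jsonlite::write_json()`.
#' @export
globe_model <- function(report, shell_radius = 8) {
  stopifnot(inherits(report, "evaluation_report"))
  list(shell = list(center = report$reference, radius = shell_radius),
       lesion = list(center = report$reference, radius = report$hit_radius),
       reference = report$reference,
       measured = unname(split(as.matrix(report$trials[, c("x", "y", "z")]),
                               seq_len(nrow(report$trials)))),
       deviations_mm = report$trials$deviation_mm,
       mean_position = report$mean_position,
       max_surgical_deviation_mm = report$max_surgical_deviation,
       hit_count = report$hit_count)
}

#' Packaged evaluation-phantom trial table
#'
#' Ten navigated target positions measured on the evaluation phantom,
#' together with their reconstructed deviation column; the deviation of every
#' row equals the recomputed euclidean distance to the marker-midpoint
#' reference to 4 decimals, which validates the reconstruction.
#'
#' @return data.frame `trial_id,x,y,z,deviation_mm`.
#' @export
eval_phantom_trials <- function() {
  utils::read.csv(system.file("extdata", "eval_phantom_trials.csv",
                              package = "sononav"))
}

#' Packaged evaluation-phantom marker positions
#'
#' Needle-probed world positions of the two surface notches (markers A and
#' B) of the evaluation phantom.
#'
#' @return list with `a` and `b`, numeric length-3 world points (mm).
#' @export
eval_phantom_markers <- function() {
  df <- utils::read.csv(system.file("extdata", "eval_phantom_markers.csv",
                                    package = "sononav"))
  list(a = as.numeric(df[df$marker == "A", c("x", "y", "z")]),
       b = as.numeric(df[df$marker == "B", c("x", "y", "z")]))
}

#' Read a trial table from CSV
#'
#' @param path CSV with header `trial_id,x,y,z`.
#' @return data.frame.
#' @export
read_trials <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("trial_id", "x", "y", "z") %in% names(df)))
    stop("trials CSV must provide columns: trial_id,x,y,z")
  df
}
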