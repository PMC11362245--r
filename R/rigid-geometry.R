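#' Frame-labelled rigid transforms
#'
#' A `rigid_transform` is a proper rigid map between two named coordinate
#' frames, stored as a 3x3 rotation matrix and a translation vector in mm.
#' The column-vector convention is used throughout: a point `p` expressed in
#' the child frame maps to `R %*% p + t` in the parent frame. Frame labels are
#' carried on every transform and checked at composition time, so an
#' inconsistent chain (e.g. composing a world-from-probe map with a
#' world-from-needle map) fails loudly instead of silently producing garbage
#' coordinates.
#'
#' @param rotation 3x3 proper rotation matrix (orthonormal, det +1).
#' @param translation numeric length-3 translation, mm.
#' @param parent_frame,child_frame frame labels (single strings).
#' @return An object of class `rigid_transform`.
#' @examples
#' w_T_s <- rigid_transform(diag(3), c(0, 0, -1000), "world", "sono")
#' transform_point(w_T_s, c(1, 2, 3))
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            parent_frame = "world", child_frame = "world") {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(identical(dim(rotation), c(3L, 3L)), length(translation) == 3)
  if (!all(is.finite(rotation)) || !all(is.finite(translation)))
    stop("rigid_transform: non-finite rotation or translation")
  err <- orthonormality_error(rotation)
  if (err > 1e-6)
    stop(sprintf("rigid_transform: rotation is not orthonormal with det +1 (error %.3g)", err))
  if (err > 1e-9) rotation <- nearest_rotation(rotation)
  structure(
    list(rotation = rotation, translation = translation,
         parent_frame = as.character(parent_frame)[1],
         child_frame = as.character(child_frame)[1]),
    class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform %s <- %s>\n", x$parent_frame, x$child_frame))
  cat("rotation:\n")
  print(round(x$rotation, 6))
  cat("translation (mm):", format(x$translation), "\n")
  invisible(x)
}

# deviation of R from the rotation group: max of |R'R - I| and |det(R) - 1|
orthonormality_error <- function(R) {
  max(max(abs(crossprod(R) - diag(3))), abs(det(R) - 1))
}

# nearest rotation in the Frobenius sense (polar decomposition via SVD);
# used to re-orthonormalize after long composition chains
nearest_rotation <- function(R) {
  s <- svd(R)
  U <- s$u
  V <- s$v
  D <- diag(c(1, 1, sign(det(U %*% t(V)))))
  U %*% D %*% t(V)
}

#' Compose two rigid transforms
#'
#' Returns the chained map `a o b`: for frames `X <- Y` (a) and `Y <- Z` (b)
#' the result maps `X <- Z`. The inner frame labels must agree.
#'
#' @param a,b `rigid_transform` objects with `a$child_frame == b$parent_frame`.
#' @return A `rigid_transform` from `b$child_frame` to `a$parent_frame`.
#' @export
compose <- function(a, b) {
  stopifnot(inherits(a, "rigid_transform"), inherits(b, "rigid_transform"))
  if (!identical(a$child_frame, b$parent_frame))
    stop(sprintf("frame mismatch: cannot compose [%s <- %s] with [%s <- %s]",
                 a$parent_frame, a$child_frame, b$parent_frame, b$child_frame))
  R <- a$rotation %*% b$rotation
  if (orthonormality_error(R) > 1e-9) R <- nearest_rotation(R)
  rigid_transform(R, as.numeric(a$rotation %*% b$translation) + a$translation,
                  a$parent_frame, b$child_frame)
}

#' Invert a rigid transform
#'
#' @param t a `rigid_transform` mapping `parent <- child`.
#' @return The `rigid_transform` mapping `child <- parent`.
#' @export
invert_transform <- function(t) {
  stopifnot(inherits(t, "rigid_transform"))
  Rt <- t(t$rotation)
  rigid_transform(Rt, as.numeric(-Rt %*% t$translation),
                  t$child_frame, t$parent_frame)
}

#' Map a point from the child frame to the parent frame
#'
#' @param t a `rigid_transform`.
#' @param p numeric length-3 point in `t$child_frame`, mm.
#' @return numeric length-3 point in `t$parent_frame`, mm.
#' @export
transform_point <- function(t, p) {
  stopifnot(inherits(t, "rigid_transform"))
  p <- as.numeric(p)
  stopifnot(length(p) == 3, all(is.finite(p)))
  as.numeric(t$rotation %*% p) + t$translation
}

#' Convert a tracked pose sample to a world-from-tool transform
#'
#' Tracking systems report tool poses as unit quaternion plus translation.
#' The quaternion convention is `(w, x, y, z)`; pose logs must state it in
#' their header. Quaternions off the unit sphere by more than 1e-6 are
#' rejected; smaller drift is normalized away.
#'
#' @param quaternion numeric length-4, `(w, x, y, z)` order, unit norm.
#' @param translation numeric length-3, mm.
#' @param tool_frame child frame label (e.g. `"sono"`, `"needle"`).
#' @return A `rigid_transform` from `tool_frame` to `"world"`.
#' @export
pose_to_transform <- function(quaternion, translation, tool_frame = "tool") {
  q <- as.numeric(quaternion)
  stopifnot(length(q) == 4)
  n <- sqrt(sum(q^2))
  if (!is.finite(n) || abs(n - 1) > 1e-6)
    stop(sprintf("pose_to_transform: quaternion norm %.8f is not 1 (tolerance 1e-6)", n))
  q <- q / n
  rigid_transform(quaternion_to_rotation(q), translation, "world", tool_frame)
}

# standard unit-quaternion rotation matrix, (w, x, y, z) order
quaternion_to_rotation <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Convert pixel coordinates to metric image-plane coordinates
#'
#' The ultrasound image frame is 0-based with origin at the top-left corner:
#' `col` increases laterally, `row` increases with depth. The metric image
#' plane has z = 0 by construction.
#'
#' @param spacing numeric length-2 `(lateral mm/px, axial mm/px)`, both > 0.
#' @param pixel numeric length-2 `(col, row)`, 0-based, may be sub-pixel.
#' @return numeric length-3 point `(x, y, 0)` in mm in the image frame.
#' @export
pixel_to_image_mm <- function(spacing, pixel) {
  spacing <- as.numeric(spacing); pixel <- as.numeric(pixel)
  stopifnot(length(spacing) == 2, length(pixel) == 2)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("pixel_to_image_mm: spacing components must be positive")
  if (any(pixel < 0)) stop("pixel_to_image_mm: pixel indices must be >= 0")
  c(pixel[1] * spacing[1], pixel[2] * spacing[2], 0)
}

#' Needle tip position in the world frame
#'
#' Chains the tracked needle-tool pose with the tip calibration:
#' the world-from-tip transform is the product of world-from-needle and
#' needle-from-tip, and the tip position is its translation.
#'
#' @param world_T_needle `rigid_transform` world <- needle tool.
#' @param needle_T_tip `rigid_transform` needle tool <- tip (pure translation
#'   from pivot calibration).
#' @return numeric length-3 world point, mm.
#' @export
needle_tip_world <- function(world_T_needle, needle_T_tip) {
  compose(world_T_needle, needle_T_tip)$translation
}

#' Read a tracked pose log
#'
#' Accepts CSV with header `timestamp,tool_id,qw,qx,qy,qz,tx,ty,tz` or a
#' JSON-lines dialect with the same keys. Quaternions are `(w, x, y, z)`.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"csv"` or `"jsonl"`.
#' @return data.frame with the nine log columns, sorted as stored.
#' @export
read_pose_log <- function(path, format = c("auto", "csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.jsonl?$", path, ignore.case = TRUE)) "jsonl" else "csv"
  cols <- c("timestamp", "tool_id", "qw", "qx", "qy", "qz", "tx", "ty", "tz")
  df <- if (format == "csv") {
    utils::read.csv(path, stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    do.call(rbind, lapply(lines, function(l)
      as.data.frame(jsonlite::fromJSON(l), stringsAsFactors = FALSE)))
  }
  if (!all(cols %in% names(df)))
    stop("pose log must provide columns: ", paste(cols, collapse = ","))
  df[, cols]
}

#' Pose-log rows as rigid transforms
#'
#' @param log data.frame from [read_pose_log()] (or equivalent).
#' @param tool_id optional filter on the `tool_id` column.
#' @param tool_frame child frame label for the resulting transforms.
#' @return list of `rigid_transform`, one per (filtered) row, with a
#'   `timestamp` attribute on each element.
#' @export
pose_log_transforms <- function(log, tool_id = NULL, tool_frame = tool_id %||% "tool") {
  if (!is.null(tool_id)) log <- log[log$tool_id == tool_id, , drop = FALSE]
  lapply(seq_len(nrow(log)), function(i) {
    t <- pose_to_transform(c(log$qw[i], log$qx[i], log$qy[i], log$qz[i]),
                           c(log$tx[i], log$ty[i], log$tz[i]), tool_frame)
    attr(t, "timestamp") <- log$timestamp[i]
    t
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# rotation by angle (radians) about a coordinate axis; test and simulation helper
#' Axis-aligned rotation transform
#'
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param angle radians.
#' @param translation numeric length-3, mm.
#' @param parent_frame,child_frame frame labels.
#' @return A `rigid_transform`.
#' @export
axis_rotation <- function(axis = c("z", "x", "y"), angle, translation = c(0, 0, 0),
                          parent_frame = "world", child_frame = "world") {
  axis <- match.arg(axis)
  c_ <- cos(angle); s_ <- sin(angle)
  R <- switch(axis,
    x = matrix(c(1, 0, 0, 0, c_, -s_, 0, s_, c_), 3, byrow = TRUE),
    y = matrix(c(c_, 0, s_, 0, 1, 0, -s_, 0, c_), 3, byrow = TRUE),
    z = matrix(c(c_, -s_, 0, s_, c_, 0, 0, 0, 1), 3, byrow = TRUE))
  rigid_transform(R, translation, parent_frame, child_frame)
}
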