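#' Probe (image-to-tool) calibration from tracked fiducials
#'
#' Estimates the pixel spacing and the rigid transform from the metric image
#' plane to the probe tracking-tool frame ("sono") from captures of fiducials
#' with known world coordinates. Each observation pairs a fiducial's pixel
#' position in the ultrasound frame with its world position and the probe
#' pose at capture time. The fit proceeds in two closed-form stages:
#'
#' 1. Anisotropic pixel spacings are estimated from all pairwise distances.
#'    A rigid map preserves distances, so for fiducials i, j in the tool frame
#'    `d_ij^2 = sx^2 dcol_ij^2 + sy^2 drow_ij^2`, linear in `(sx^2, sy^2)`.
#' 2. With pixels scaled to mm, the rigid transform is the absolute-orientation
#'    (Kabsch/SVD) solution between the metric pixel points and the fiducials
#'    mapped into the tool frame via the inverse probe pose.
#'
#' The residual RMS is the fiducial registration error: the RMS distance
#' between calibrated pixel fiducials and their tool-frame references.
#'
#' @param observations data.frame with one row per fiducial capture and
#'   columns `col,row` (0-based pixel), `wx,wy,wz` (world mm) and either
#'   `qw,qx,qy,qz,tx,ty,tz` (probe pose at capture) or a list-column
#'   `world_T_sono` of `rigid_transform`s.
#' @return A `probe_calibration`: list with `spacing` (lateral, axial mm/px),
#'   `sono_T_image` (`rigid_transform` sono <- image) and `residual_rms` (mm).
#' @export
calibrate_probe <- function(observations) {
  obs <- as.data.frame(observations)
  n <- nrow(obs)
  if (n < 3) stop("calibrate_probe: need at least 3 fiducial observations")
  px <- cbind(obs$col, obs$row)
  if (any(px < 0)) stop("calibrate_probe: pixel coordinates must be >= 0")

  # world fiducials expressed in the probe tool frame at each capture
  sono_pts <- t(vapply(seq_len(n), function(i) {
    w_T_s <- if (!is.null(obs$world_T_sono)) obs$world_T_sono[[i]]
             else pose_to_transform(c(obs$qw[i], obs$qx[i], obs$qy[i], obs$qz[i]),
                                    c(obs$tx[i], obs$ty[i], obs$tz[i]), "sono")
    transform_point(invert_transform(w_T_s), c(obs$wx[i], obs$wy[i], obs$wz[i]))
  }, numeric(3)))

  # collinearity guard on the pixel configuration
  if (qr(sweep(px, 2, colMeans(px)))$rank < 2)
    stop("calibrate_probe: fiducial pixels are collinear; configuration is degenerate")

  # stage 1: spacings from pairwise squared distances
  ij <- utils::combn(n, 2)
  dc2 <- (px[ij[1, ], 1] - px[ij[2, ], 1])^2
  dr2 <- (px[ij[1, ], 2] - px[ij[2, ], 2])^2
  d2 <- rowSums((sono_pts[ij[1, ], , drop = FALSE] - sono_pts[ij[2, ], , drop = FALSE])^2)
  A <- cbind(dc2, dr2)
  s2 <- tryCatch(qr.solve(A, d2), error = function(e)
    stop("calibrate_probe: degenerate configuration, cannot resolve spacings"))
  if (any(!is.finite(s2)) || any(s2 <= 0))
    stop("calibrate_probe: degenerate configuration, non-positive spacing estimate")
  spacing <- sqrt(s2)

  # stage 2: rigid fit (absolute orientation) metric-pixel -> tool frame
  img_pts <- cbind(px[, 1] * spacing[1], px[, 2] * spacing[2], 0)
  fit <- kabsch_fit(img_pts, sono_pts)

  structure(list(spacing = as.numeric(spacing),
                 sono_T_image = rigid_transform(fit$R, fit$t, "sono", "image"),
                 residual_rms = fit$rms),
            class = "probe_calibration")
}

# absolute orientation: rigid R, t minimizing ||R a_i + t - b_i|| (Kabsch/SVD,
# with the determinant correction that keeps R proper for planar point sets)
kabsch_fit <- function(a, b) {
  ca <- colMeans(a); cb <- colMeans(b)
  H <- crossprod(sweep(a, 2, ca), sweep(b, 2, cb))
  s <- svd(H)
  D <- diag(c(1, 1, sign(det(s$v %*% t(s$u)))))
  R <- s$v %*% D %*% t(s$u)
  t <- cb - as.numeric(R %*% ca)
  res <- sweep(tcrossprod(a, R), 2, t, "+") - b
  list(R = R, t = t, rms = sqrt(mean(rowSums(res^2))))
}

#' Pivot calibration of the needle tip
#'
#' With the needle tip held on a fixed point and the tool pivoted, every pose
#' satisfies `R_i p + t_i = w` for the unknown tool-frame tip offset `p` and
#' the fixed world pivot `w`. All poses are stacked into one linear
#' least-squares system `[R_i | -I] (p, w) = -t_i` and solved in closed form.
#' Observability requires rotational diversity: the smallest singular value
#' of the stacked design matrix must exceed `sv_tol`.
#'
#' @param poses list of `rigid_transform` (world <- needle), length >= 3.
#' @param sv_tol smallest-singular-value threshold for observability
#'   (default 1e-6).
#' @return A `tip_calibration`: list with `tip_offset` (mm, needle-tool
#'   frame), `pivot_point` (world mm) and `residual_rms` (mm).
#' @export
pivot_calibrate_needle <- function(poses, sv_tol = 1e-6) {
  if (length(poses) < 3) stop("pivot_calibrate_needle: need at least 3 poses")
  stopifnot(all(vapply(poses, inherits, logical(1), "rigid_transform")))
  A <- do.call(rbind, lapply(poses, function(t) cbind(t$rotation, -diag(3))))
  y <- -as.numeric(vapply(poses, `[[`, numeric(3), "translation"))
  sv <- svd(A, nu = 0, nv = 0)$d
  if (min(sv) < sv_tol)
    stop("pivot_calibrate_needle: insufficient rotation diversity, tip offset unobservable")
  x <- qr.solve(A, y)
  res <- matrix(A %*% x - y, ncol = 3, byrow = TRUE)
  structure(list(tip_offset = x[1:3], pivot_point = x[4:6],
                 residual_rms = sqrt(mean(rowSums(res^2)))),
            class = "tip_calibration")
}

#' Needle-from-tip transform of a tip calibration
#'
#' The tip is modelled as a pure translation in the needle-tool frame; a point
#' target needs no tip orientation.
#'
#' @param tip_cal a `tip_calibration`.
#' @return A `rigid_transform` needle <- tip with identity rotation.
#' @export
tip_transform <- function(tip_cal) {
  stopifnot(inherits(tip_cal, "tip_calibration"))
  rigid_transform(diag(3), tip_cal$tip_offset, "needle", "tip")
}

#' Summarize a calibration as a serializable record
#'
#' @param cal a `probe_calibration` or `tip_calibration`.
#' @return A plain list (JSON-ready) with parameters and residual.
#' @export
calibration_report <- function(cal) {
  if (inherits(cal, "probe_calibration")) {
    list(kind = "probe",
         spacing_mm_per_px = cal$spacing,
         sono_T_image = list(rotation = cal$sono_T_image$rotation,
                             translation_mm = cal$sono_T_image$translation),
         residual_rms_mm = cal$residual_rms)
  } else if (inherits(cal, "tip_calibration")) {
    list(kind = "tip",
         tip_offset_mm = cal$tip_offset,
         pivot_point_mm = cal$pivot_point,
         residual_rms_mm = cal$residual_rms)
  } else stop("calibration_report: not a calibration object")
}

#' Read fiducial observations for probe calibration
#'
#' CSV with header `col,row,wx,wy,wz,qw,qx,qy,qz,tx,ty,tz`, one line per
#' fiducial capture.
#'
#' @param path file path.
#' @return data.frame suitable for [calibrate_probe()].
#' @export
read_fiducial_observations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("col", "row", "wx", "wy", "wz", "qw", "qx", "qy", "qz", "tx", "ty", "tz")
  if (!all(need %in% names(df)))
    stop("fiducial file must provide columns: ", paste(need, collapse = ","))
  df
}

#' Manually constructed probe calibration
#'
#' Convenience constructor for simulation and tests where the calibration is
#' known exactly rather than estimated.
#'
#' @param spacing numeric length-2 `(lateral, axial)` mm/px, > 0.
#' @param sono_T_image `rigid_transform` sono <- image.
#' @param residual_rms mm, default 0.
#' @return A `probe_calibration`.
#' @export
probe_calibration <- function(spacing, sono_T_image, residual_rms = 0) {
  spacing <- as.numeric(spacing)
  stopifnot(length(spacing) == 2, all(spacing > 0),
            inherits(sono_T_image, "rigid_transform"), residual_rms >= 0)
  structure(list(spacing = spacing, sono_T_image = sono_T_image,
                 residual_rms = residual_rms),
            class = "probe_calibration")
}
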