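#' Detect a hypoechoic lesion in a B-mode frame
#'
#' Classical intensity/blob detector that stands in for a trained
#' segmentation network behind the same interface (binary mask + center), so
#' a learned backend can drop in later. In B-mode, a fluid-filled lesion is
#' hypoechoic: darker than the speckled background. The pipeline is Gaussian
#' smoothing, dark-region thresholding at a fraction of the background
#' median, connected components, filtering by area and circularity, then
#' selection of the highest-contrast component. The reported centroid is the
#' component's area centroid (sub-pixel), and the equivalent diameter is that
#' of the circle with the component's area.
#'
#' Images are numeric matrices with intensities in `[0, 1]`; matrix rows run
#' with depth (axial) and columns laterally, matching the 0-based
#' `(col, row)` pixel convention of [pixel_to_image_mm()].
#'
#' @param image numeric matrix, intensities in `[0, 1]`.
#' @param sigma Gaussian smoothing standard deviation, px (default 2).
#' @param threshold_frac dark threshold as a fraction of the background
#'   (image) median intensity (default 0.5).
#' @param area_bounds admissible component area, px^2 (default `c(50, 5000)`).
#' @param min_circularity minimum `4*pi*A/P^2` (default 0.6).
#' @return A `segmentation_result`: list with `mask` (logical matrix),
#'   `centroid` (0-based `(col, row)`, sub-pixel) and
#'   `equivalent_diameter_px`.
#' @export
detect_lesion <- function(image, sigma = 2, threshold_frac = 0.5,
                          area_bounds = c(50, 5000), min_circularity = 0.6) {
  check_gray_image(image)
  stopifnot(sigma > 0, threshold_frac > 0, length(area_bounds) == 2,
            area_bounds[1] > 0, min_circularity >= 0)
  smooth <- EBImage::gblur(image, sigma = sigma)
  bg <- stats::median(smooth)
  dark <- smooth < threshold_frac * bg
  if (!any(dark)) stop_no_lesion("no pixels below the dark threshold")

  labels <- EBImage::bwlabel(dark)
  shp <- EBImage::computeFeatures.shape(labels)
  if (is.null(dim(shp))) shp <- matrix(shp, nrow = 1, dimnames = list(NULL, names(shp)))
  area <- shp[, "s.area"]
  per <- pmax(shp[, "s.perimeter"], 1)
  circ <- 4 * pi * area / per^2
  keep <- which(area >= area_bounds[1] & area <= area_bounds[2] &
                circ >= min_circularity)
  if (length(keep) == 0) stop_no_lesion("no component passes area/circularity filters")

  contrast <- vapply(keep, function(k) bg - mean(smooth[labels == k]), numeric(1))
  best <- keep[which.max(contrast)]
  smooth_mask <- labels == best

  # detection runs on the smoothed image, but the smoothed contour sits where
  # blur coverage equals the threshold fraction and biases the area; measure
  # on the raw image instead: keep the raw-threshold component that overlaps
  # the detected one the most
  raw_labels <- EBImage::bwlabel(image < threshold_frac * bg)
  overlap <- tabulate(raw_labels[smooth_mask & raw_labels > 0])
  if (length(overlap) && max(overlap) > 0)
    mask_to_result(raw_labels == which.max(overlap))
  else
    mask_to_result(smooth_mask)
}

#' Wrap an externally produced binary mask as a segmentation result
#'
#' Accepts masks from any source (e.g. a deep network run elsewhere) and
#' computes the same centroid and equivalent diameter as [detect_lesion()].
#'
#' @param mask logical or 0/1 numeric matrix with at least one foreground
#'   pixel.
#' @return A `segmentation_result`.
#' @export
load_mask_as_result <- function(mask) {
  if (is.numeric(mask)) mask <- mask > 0
  stopifnot(is.matrix(mask), is.logical(mask))
  if (!any(mask)) stop("load_mask_as_result: mask has no foreground pixels")
  mask_to_result(mask)
}

mask_to_result <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  # matrix [r, c] (1-based) -> pixel (col, row) = (c-1, r-1)
  centroid <- c(col = mean(idx[, 2]) - 1, row = mean(idx[, 1]) - 1)
  structure(list(mask = mask,
                 centroid = centroid,
                 equivalent_diameter_px = 2 * sqrt(nrow(idx) / pi)),
            class = "segmentation_result")
}

check_gray_image <- function(image) {
  if (!is.matrix(image) || !is.numeric(image) || length(image) == 0)
    stop("image must be a non-empty numeric matrix")
  if (anyNA(image) || min(image) < 0 || max(image) > 1)
    stop("image intensities must lie in [0, 1]")
  invisible(TRUE)
}

stop_no_lesion <- function(detail) {
  stop(errorCondition(paste0("NoLesionFound: ", detail),
                      class = c("no_lesion_found", "error", "condition")))
}

#' Read a grayscale image or 0/255 mask from PNG
#'
#' @param path PNG file path.
#' @param as_mask if `TRUE`, binarize at 0.5.
#' @return numeric matrix in `[0, 1]`, or logical matrix when `as_mask`.
#' @export
read_gray_png <- function(path, as_mask = FALSE) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) a <- a[, , 1]
  if (as_mask) a > 0.5 else a
}

#' Serialize a segmentation result (without the mask) to a list
#'
#' @param res a `segmentation_result`.
#' @return JSON-ready list with centroid and equivalent diameter.
#' @export
segmentation_report <- function(res) {
  stopifnot(inherits(res, "segmentation_result"))
  list(centroid_px = list(col = unname(res$centroid[1]), row = unname(res$centroid[2])),
       equivalent_diameter_px = res$equivalent_diameter_px,
       area_px = sum(res$mask))
}
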