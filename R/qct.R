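#' Three-class bone-mass labeling from subject-level BMD
#'
#' Applies the guideline QCT thresholds: BMD above 120 mg/cm3 is normal,
#' 80 to 120 mg/cm3 inclusive is osteopenia, below 80 mg/cm3 is
#' osteoporosis.
#'
#' @param bmd_individual subject-level BMD in mg/cm3 (vectorised); must be
#'   positive and finite.
#' @return character vector of labels from [bmd_classes].
#' @export
classify_bmd <- function(bmd_individual) {
  if (any(!is.finite(bmd_individual)) || any(bmd_individual <= 0)) {
    stop("bmd_individual must be positive and finite")
  }
  ifelse(bmd_individual > 120, "normal",
         ifelse(bmd_individual >= 80, "osteopenia", "osteoporosis"))
}

#' Subject-level BMD from per-vertebra measurements
#'
#' The arithmetic mean of the available L1/L2 values; with a single value
#' present (the L1-only workflow) that value is returned.
#'
#' @param bmd_l1,bmd_l2 per-vertebra BMD in mg/cm3; either may be `NULL`
#'   or `NA`, but not both.
#' @return subject BMD in mg/cm3.
#' @export
subject_bmd <- function(bmd_l1, bmd_l2 = NULL) {
  vals <- c(bmd_l1, bmd_l2)
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) stop("at least one vertebral BMD must be present")
  mean(vals)
}

#' ROI specification for BMD measurement
#'
#' The central-cancellous ROI is the segmentation mask eroded by
#' `erosion_margin` pixels (quoted at a 512-pixel matrix and scaled with
#' the image size) to stay clear of cortical bone, restricted to the
#' `target_area_fraction` of pixels nearest the mask centroid. With
#' `vessel_exclusion`, pixels more than 3 SD below the ROI median are
#' dropped in one pass, mimicking manual avoidance of the basivertebral
#' vessel.
#'
#' @param erosion_margin pixels (at 512) shaved off the mask boundary.
#' @param target_area_fraction central fraction of the eroded mask kept.
#' @param vessel_exclusion drop low-intensity outlier pixels.
#' @return an object of class `roi_spec`.
#' @export
roi_spec <- function(erosion_margin = 3, target_area_fraction = 0.6,
                     vessel_exclusion = TRUE) {
  if (erosion_margin < 0) stop("erosion_margin must be >= 0")
  if (target_area_fraction <= 0 || target_area_fraction > 1) {
    stop("target_area_fraction must be in (0, 1]")
  }
  structure(list(erosion_margin = erosion_margin,
                 target_area_fraction = target_area_fraction,
                 vessel_exclusion = isTRUE(vessel_exclusion)),
            class = "roi_spec")
}

# k-step binary erosion with the 3x3 structuring element
erode_mask <- function(mask, k) {
  m <- mask != 0
  H <- nrow(m); W <- ncol(m)
  for (it in seq_len(k)) {
    p <- matrix(FALSE, H + 2, W + 2)
    p[2:(H + 1), 2:(W + 1)] <- m
    m <- p[2:(H + 1), 2:(W + 1)]
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      m <- m & p[2:(H + 1) + dr, 2:(W + 1) + dc]
    }
  }
  m
}

#' Measure BMD in the central cancellous ROI of a segmented slice
#'
#' @param slice intensity matrix.
#' @param mask binary vertebral-body mask (same shape).
#' @param roi an [roi_spec()].
#' @param calibration named vector with `slope` and `intercept` mapping BMD
#'   to intensity; the measurement inverts it.
#' @return list with `bmd` (mg/cm3) and `roi_pixel_count`.
#' @export
measure_roi_bmd <- function(slice, mask, roi = roi_spec(),
                            calibration = c(slope = 1, intercept = 0)) {
  if (!identical(dim(slice), dim(mask))) stop("slice and mask shapes differ")
  n <- nrow(mask)
  margin <- if (roi$erosion_margin > 0) {
    max(1L, as.integer(round(roi$erosion_margin * n / 512)))
  } else 0L
  m <- erode_mask(mask, margin)
  if (!any(m)) {
    stop("ROI empty after eroding ", margin, " px from a mask of ",
         sum(mask != 0), " px")
  }
  idx <- which(m, arr.ind = TRUE)
  if (roi$target_area_fraction < 1) {
    ctr <- colMeans(idx)
    d2 <- (idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2
    thr <- stats::quantile(d2, roi$target_area_fraction, type = 1)
    idx <- idx[d2 <= thr, , drop = FALSE]
  }
  vals <- slice[idx]
  if (roi$vessel_exclusion) {
    s <- stats::sd(vals)
    if (is.finite(s) && s > 0) {
      vals <- vals[vals >= stats::median(vals) - 3 * s]
    }
  }
  slope <- calibration[["slope"]]
  intercept <- calibration[["intercept"]]
  list(bmd = (mean(vals) - intercept) / slope,
       roi_pixel_count = length(vals))
}

#' Subject-level QCT measurement from segmented slices
#'
#' Measures both vertebrae with [measure_roi_bmd()], averages them into
#' the subject-level BMD and applies the threshold labeling.
#'
#' @param l1_slice,l1_mask,l2_slice,l2_mask slices and masks; the L2 pair
#'   may be `NULL` for the single-vertebra workflow.
#' @param roi an [roi_spec()].
#' @param calibration as in [measure_roi_bmd()].
#' @return an object of class `bmd_result`: list with `bmd_l1`, `bmd_l2`,
#'   `bmd_individual`, `label`, `roi_pixel_count`.
#' @export
measure_subject <- function(l1_slice, l1_mask, l2_slice = NULL,
                            l2_mask = NULL, roi = roi_spec(),
                            calibration = c(slope = 1, intercept = 0)) {
  m1 <- measure_roi_bmd(l1_slice, l1_mask, roi, calibration)
  if (!is.null(l2_slice)) {
    m2 <- measure_roi_bmd(l2_slice, l2_mask, roi, calibration)
    bmd2 <- m2$bmd
    npix <- m1$roi_pixel_count + m2$roi_pixel_count
  } else {
    bmd2 <- NA_real_
    npix <- m1$roi_pixel_count
  }
  bi <- subject_bmd(m1$bmd, bmd2)
  structure(list(bmd_l1 = m1$bmd, bmd_l2 = bmd2, bmd_individual = bi,
                 label = classify_bmd(bi), roi_pixel_count = npix),
            class = "bmd_result")
}

#' @export
print.bmd_result <- function(x, ...) {
  cat(sprintf("BMD L1 %.1f, L2 %s -> individual %.1f mg/cm3 [%s]\n",
              x$bmd_l1,
              if (is.na(x$bmd_l2)) "absent" else sprintf("%.1f", x$bmd_l2),
              x$bmd_individual, x$label))
  invisible(x)
}
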