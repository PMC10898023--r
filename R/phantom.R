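#' Synthetic vertebral CT slice specification
#'
#' Geometry and intensity model for a synthetic axial slice through a
#' vertebral body: an elliptical body with a bright cortical rim, a
#' textured trabecular interior whose mean intensity encodes the bone
#' mineral density through a linear calibration, soft-tissue background,
#' and an optional low-intensity basivertebral vessel to be avoided by ROI
#' placement. Intensities are in calibrated units; with the default
#' identity calibration the trabecular mean numerically equals BMD in
#' mg/cm3.
#'
#' @param image_size pixels per side (>= 32). 512 mirrors the clinical
#'   matrix; 96 is the desk-scale default used by the shipped benchmarks.
#' @param vertebra_axes semi-axes of the vertebral ellipse as fractions of
#'   `image_size`.
#' @param cortical_thickness rim thickness in pixels.
#' @param cortical_intensity rim intensity; must exceed the trabecular mean
#'   for any BMD up to 295.1 mg/cm3 (the largest density the generator is
#'   calibrated for).
#' @param trabecular_noise_sd per-pixel trabecular texture SD. Smooth
#'   low-frequency blobs with amplitude `low_freq_frac * trabecular_noise_sd`
#'   are added on top, so `trabecular_noise_sd = 0` gives an exactly uniform
#'   interior.
#' @param low_freq_frac amplitude of the low-frequency texture relative to
#'   `trabecular_noise_sd`.
#' @param vessel_probability probability that a slice carries the vessel.
#' @param vessel_radius_frac vessel radius as a fraction of `image_size`.
#' @param background_level,background_noise_sd soft-tissue background.
#' @param calibration_slope,calibration_intercept linear map from BMD to
#'   mean trabecular intensity.
#' @param center_jitter centre jitter as a fraction of `image_size`.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = 512L, vertebra_axes = c(0.28, 0.20),
                         cortical_thickness = 4, cortical_intensity = 420,
                         trabecular_noise_sd = 20, low_freq_frac = 0.15,
                         vessel_probability = 0.5, vessel_radius_frac = 0.03,
                         background_level = 60, background_noise_sd = 10,
                         calibration_slope = 1, calibration_intercept = 0,
                         center_jitter = 0.02) {
  image_size <- as.integer(image_size)
  if (image_size < 32L) stop("image_size must be at least 32")
  if (calibration_slope <= 0) stop("calibration_slope must be positive")
  if (vessel_probability < 0 || vessel_probability > 1) {
    stop("vessel_probability must be in [0, 1]")
  }
  reach <- max(vertebra_axes) + cortical_thickness / image_size +
    center_jitter
  if (reach >= 0.5) {
    stop("vertebral ellipse (axes + rim + jitter) does not fit in the image")
  }
  top <- calibration_slope * 295.1 + calibration_intercept
  if (cortical_intensity <= top) {
    stop("cortical_intensity must exceed the trabecular mean over the ",
         "calibrated BMD range (needs > ", round(top, 1), ")")
  }
  structure(list(image_size = image_size, vertebra_axes = vertebra_axes,
                 cortical_thickness = cortical_thickness,
                 cortical_intensity = cortical_intensity,
                 trabecular_noise_sd = trabecular_noise_sd,
                 low_freq_frac = low_freq_frac,
                 vessel_probability = vessel_probability,
                 vessel_radius_frac = vessel_radius_frac,
                 background_level = background_level,
                 background_noise_sd = background_noise_sd,
                 calibration_slope = calibration_slope,
                 calibration_intercept = calibration_intercept,
                 center_jitter = center_jitter),
            class = "phantom_spec")
}

#' Desk-scale phantom specification
#'
#' 96-pixel slices with a 2-pixel rim; all intensity parameters as in
#' [phantom_spec()].
#'
#' @param ... overrides passed to [phantom_spec()].
#' @export
desk_phantom_spec <- function(...) {
  args <- list(image_size = 96L, cortical_thickness = 2, ...)
  do.call(phantom_spec, args[!duplicated(names(args), fromLast = TRUE)])
}

render_slice <- function(spec, bmd) {
  n <- spec$image_size
  ctr <- (n + 1) / 2
  cx <- ctr + stats::runif(1, -1, 1) * spec$center_jitter * n
  cy <- ctr + stats::runif(1, -1, 1) * spec$center_jitter * n
  a <- spec$vertebra_axes[1] * n
  b <- spec$vertebra_axes[2] * n
  th <- spec$cortical_thickness
  r <- rep(seq_len(n), times = n)
  c_ <- rep(seq_len(n), each = n)
  q_in <- ((r - cx) / a)^2 + ((c_ - cy) / b)^2
  q_out <- ((r - cx) / (a + th))^2 + ((c_ - cy) / (b + th))^2
  interior <- q_in < 1
  rim <- q_out < 1 & !interior
  img <- spec$background_level +
    stats::rnorm(n * n, 0, spec$background_noise_sd)
  mu <- spec$calibration_slope * bmd + spec$calibration_intercept
  tex <- stats::rnorm(n * n, 0, spec$trabecular_noise_sd)
  blob_amp <- spec$low_freq_frac * spec$trabecular_noise_sd
  if (blob_amp > 0) {
    for (k in 1:3) {
      bx <- cx + stats::runif(1, -0.6, 0.6) * a
      by <- cy + stats::runif(1, -0.6, 0.6) * b
      sig <- stats::runif(1, 0.04, 0.1) * n
      amp <- stats::rnorm(1, 0, blob_amp)
      tex <- tex + amp * exp(-((r - bx)^2 + (c_ - by)^2) / (2 * sig^2))
    }
  }
  img[interior] <- mu + tex[interior]
  img[rim] <- spec$cortical_intensity
  has_vessel <- stats::runif(1) < spec$vessel_probability
  if (has_vessel) {
    vx <- cx
    vy <- cy + 0.55 * b  # posterior third of the body
    vr <- spec$vessel_radius_frac * n
    vessel <- (r - vx)^2 + (c_ - vy)^2 < vr^2 & interior
    img[vessel] <- spec$background_level
  }
  img <- pmax(img, 0)
  dim(img) <- c(n, n)
  mask <- interior * 1
  dim(mask) <- c(n, n)
  list(slice = img, mask = mask)
}

#' Generate one synthetic subject (two slices)
#'
#' Renders the central L1 and L2 axial slices and ground-truth masks for a
#' subject with the given per-vertebra densities. Deterministic for a fixed
#' `(spec, bmd, seed)`.
#'
#' @param spec a [phantom_spec()].
#' @param bmd_l1,bmd_l2 per-vertebra BMD in mg/cm3, within `[1, 400]`.
#' @param seed integer seed.
#' @param subject_id identifier stored with the subject.
#' @param sex,age optional demographics.
#' @return an object of class `phantom_subject` with slices, masks, true
#'   densities and the threshold-rule label of the subject mean.
#' @export
generate_subject <- function(spec, bmd_l1, bmd_l2, seed = 1L,
                             subject_id = "S1", sex = NA_character_,
                             age = NA_real_) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (any(!is.finite(c(bmd_l1, bmd_l2))) ||
      any(c(bmd_l1, bmd_l2) < 1) || any(c(bmd_l1, bmd_l2) > 400)) {
    stop("BMD values must lie in [1, 400] mg/cm3")
  }
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  l1 <- render_slice(spec, bmd_l1)
  l2 <- render_slice(spec, bmd_l2)
  structure(list(subject_id = subject_id,
                 l1_slice = l1$slice, l2_slice = l2$slice,
                 l1_mask = l1$mask, l2_mask = l2$mask,
                 true_bmd_l1 = bmd_l1, true_bmd_l2 = bmd_l2,
                 true_label = classify_bmd(mean(c(bmd_l1, bmd_l2))),
                 sex = sex, age = age),
            class = "phantom_subject")
}

# truncated-normal moments for parent (mu, sigma) on (a, b)
truncnorm_moments <- function(mu, sigma, a, b) {
  al <- (a - mu) / sigma
  be <- (b - mu) / sigma
  Z <- stats::pnorm(be) - stats::pnorm(al)
  pa <- stats::dnorm(al)
  pb <- stats::dnorm(be)
  m <- mu + sigma * (pa - pb) / Z
  v <- sigma^2 * (1 + (al * pa - be * pb) / Z - ((pa - pb) / Z)^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

# parent parameters whose truncation to (a, b) has the target mean and sd
match_truncnorm <- function(target_mean, target_sd, a, b) {
  obj <- function(p) {
    mm <- truncnorm_moments(p[1], exp(p[2]), a, b)
    (mm[1] - target_mean)^2 + (mm[2] - target_sd)^2
  }
  fit <- stats::optim(c(target_mean, log(target_sd)), obj,
                      control = list(reltol = 1e-14, maxit = 2000))
  c(mu = fit$par[1], sigma = exp(fit$par[2]))
}

rtruncnorm_inv <- function(n, mu, sigma, a, b) {
  pa <- stats::pnorm(a, mu, sigma)
  pb <- stats::pnorm(b, mu, sigma)
  if (pb - pa <= 0) stop("infeasible truncation window")
  stats::qnorm(pa + stats::runif(n) * (pb - pa), mu, sigma)
}

default_bmd_params <- function() {
  data.frame(class = bmd_classes,
             mean = c(168.33, 99.35, 60.32),
             sd = c(23.12, 10.91, 16.48),
             lower = c(120, 80, 5.7),
             upper = c(295.1, 120, 80))
}

# printed age-decade x sex counts used for the optional demographics
default_demographics <- function() {
  data.frame(
    age_group = rep(c("<30", "30-39", "40-49", "50-59", "60-69", "70-79",
                      "80-89", ">=90"), 2),
    age_low = rep(c(20, 30, 40, 50, 60, 70, 80, 90), 2),
    age_high = rep(c(29, 39, 49, 59, 69, 79, 89, 92), 2),
    sex = rep(c("male", "female"), each = 8),
    count = c(40, 85, 157, 207, 57, 41, 17, 1,
              20, 80, 99, 115, 60, 45, 23, 1))
}

#' Cohort specification
#'
#' Class mix, per-class BMD distributions and within-subject structure for
#' a synthetic cohort. Per-class densities are drawn from truncated normal
#' distributions whose bounds respect the label thresholds (normal > 120,
#' osteopenia in `[80, 120]`, osteoporosis < 80 mg/cm3); by default the
#' parent parameters are moment-matched so the truncated distribution
#' itself has the requested class mean and SD. Each subject's L1 and L2
#' densities are `bmd +/- d` with `d ~ N(0, jitter_sd)`, so their mean is
#' exactly the subject-level draw and the label stays consistent.
#'
#' @param n_subjects cohort size.
#' @param class_counts counts for (normal, osteopenia, osteoporosis);
#'   must sum to `n_subjects`. Defaults to the 621/296/131 mix scaled to
#'   `n_subjects` by largest remainder.
#' @param bmd_params data frame with columns `class`, `mean`, `sd`,
#'   `lower`, `upper`.
#' @param jitter_sd SD of the within-subject L1/L2 half-difference
#'   (mg/cm3).
#' @param match_moments match the truncated distribution's moments to the
#'   requested mean/SD (default) instead of using them as parent
#'   parameters.
#' @param demographics sample age/sex from the built-in age-decade x sex
#'   table (used only by the statistics reports, never by the models).
#' @param seed integer seed.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 1048L, class_counts = NULL,
                        bmd_params = default_bmd_params(), jitter_sd = 6,
                        match_moments = TRUE, demographics = TRUE,
                        seed = 1L) {
  n_subjects <- as.integer(n_subjects)
  if (is.null(class_counts)) {
    q <- n_subjects * c(621, 296, 131) / 1048
    class_counts <- floor(q)
    left <- n_subjects - sum(class_counts)
    if (left > 0) {
      extra <- order(q - class_counts, decreasing = TRUE)[seq_len(left)]
      class_counts[extra] <- class_counts[extra] + 1
    }
  }
  class_counts <- as.integer(class_counts)
  if (length(class_counts) != 3L || any(class_counts < 0)) {
    stop("class_counts must be three non-negative counts")
  }
  if (sum(class_counts) != n_subjects) {
    stop("class_counts must sum to n_subjects")
  }
  for (i in seq_len(nrow(bmd_params))) {
    if (bmd_params$mean[i] < bmd_params$lower[i] ||
        bmd_params$mean[i] > bmd_params$upper[i]) {
      stop("class '", bmd_params$class[i], "': mean ", bmd_params$mean[i],
           " lies outside its truncation bounds [", bmd_params$lower[i],
           ", ", bmd_params$upper[i], "]")
    }
  }
  # label bounds must be respected by the supports
  lb <- c(120, 80, -Inf); ub <- c(Inf, 120, 80)
  for (i in 1:3) {
    j <- match(bmd_classes[i], bmd_params$class)
    if (bmd_params$lower[j] < lb[i] - 1e-9 || bmd_params$upper[j] > ub[i] + 1e-9) {
      stop("class '", bmd_classes[i], "': truncation bounds violate the ",
           "label thresholds")
    }
  }
  structure(list(n_subjects = n_subjects, class_counts = class_counts,
                 bmd_params = bmd_params, jitter_sd = jitter_sd,
                 match_moments = isTRUE(match_moments),
                 demographics = isTRUE(demographics),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort
#'
#' Draws per-subject densities from the per-class truncated normals,
#' renders two slices per subject, and assembles a metadata table. With
#' `dir` set, slices and masks are also written to disk (16-bit PNG or
#' NIfTI) together with `metadata.csv`.
#'
#' @param cohort a [cohort_spec()].
#' @param spec a [phantom_spec()].
#' @param dir optional output directory.
#' @param format `"nifti"` (lossless, the default) or `"png"` (8-bit
#'   preview; intensities are quantised to steps of `PNG_SCALE / 255`,
#'   about 4 units, masks are exact).
#' @return an object of class `phantom_cohort`: list with `subjects` (list
#'   of [generate_subject()] results) and `metadata` (data frame).
#' @export
generate_cohort <- function(cohort, spec, dir = NULL,
                            format = c("nifti", "png")) {
  stopifnot(inherits(cohort, "cohort_spec"), inherits(spec, "phantom_spec"))
  format <- match.arg(format)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(cohort$seed)
  n <- cohort$n_subjects
  labels <- sample(rep(bmd_classes, times = cohort$class_counts))
  pars <- cohort$bmd_params
  parent <- lapply(seq_len(nrow(pars)), function(i) {
    if (cohort$match_moments) {
      p <- match_truncnorm(pars$mean[i], pars$sd[i], pars$lower[i],
                           pars$upper[i])
      list(mu = p[["mu"]], sigma = p[["sigma"]], a = pars$lower[i],
           b = pars$upper[i])
    } else {
      list(mu = pars$mean[i], sigma = pars$sd[i], a = pars$lower[i],
           b = pars$upper[i])
    }
  })
  names(parent) <- pars$class
  bmd <- numeric(n)
  for (cl in bmd_classes) {
    ii <- which(labels == cl)
    pp <- parent[[cl]]
    bmd[ii] <- rtruncnorm_inv(length(ii), pp$mu, pp$sigma, pp$a, pp$b)
  }
  d <- stats::rnorm(n, 0, cohort$jitter_sd)
  l1 <- bmd + d
  l2 <- bmd - d
  bad <- l1 < 1 | l1 > 400 | l2 < 1 | l2 > 400
  l1[bad] <- bmd[bad]
  l2[bad] <- bmd[bad]
  demo <- NULL
  if (cohort$demographics) {
    tab <- default_demographics()
    cell <- sample.int(nrow(tab), n, replace = TRUE, prob = tab$count)
    demo <- data.frame(
      sex = tab$sex[cell],
      age = tab$age_low[cell] +
        floor(stats::runif(n) * (tab$age_high[cell] - tab$age_low[cell] + 1)))
  }
  seeds <- (cohort$seed + 7919 * seq_len(n)) %% 2147483647L
  subjects <- vector("list", n)
  ids <- sprintf("S%04d", seq_len(n))
  for (i in seq_len(n)) {
    subjects[[i]] <- generate_subject(
      spec, l1[i], l2[i], seed = seeds[i], subject_id = ids[i],
      sex = if (is.null(demo)) NA_character_ else demo$sex[i],
      age = if (is.null(demo)) NA_real_ else demo$age[i])
  }
  metadata <- data.frame(
    subject_id = ids,
    age = if (is.null(demo)) NA_real_ else demo$age,
    sex = if (is.null(demo)) NA_character_ else demo$sex,
    bmd_l1 = l1, bmd_l2 = l2, bmd_individual = bmd,
    label = labels, stringsAsFactors = FALSE)
  out <- structure(list(subjects = subjects, metadata = metadata,
                        spec = spec, cohort = cohort),
                   class = "phantom_cohort")
  if (!is.null(dir)) {
    write_cohort(out, dir, format = format)
    out$metadata <- utils::read.csv(file.path(dir, "metadata.csv"),
                                    stringsAsFactors = FALSE)
  }
  out
}

#' @export
print.phantom_cohort <- function(x, ...) {
  tab <- table(factor(x$metadata$label, levels = bmd_classes))
  cat("Synthetic phantom cohort:", nrow(x$metadata), "subjects (",
      paste(names(tab), as.integer(tab), sep = " = ", collapse = ", "),
      ")\n")
  cat("  image size:", x$spec$image_size, "px;",
      "L1/L2 jitter sd:", x$cohort$jitter_sd, "mg/cm3\n")
  invisible(x)
}

# PNG intensity scale: stored value = intensity / PNG_SCALE (8-bit)
PNG_SCALE <- 1024

write_slice_png <- function(img, path) {
  png::writePNG(pmin(pmax(t(img) / PNG_SCALE, 0), 1), path)
}

read_slice_png <- function(path) {
  t(png::readPNG(path)) * PNG_SCALE
}

write_mask_png <- function(mask, path) {
  png::writePNG(t(mask * 1), path)
}

read_mask_png <- function(path) {
  (t(png::readPNG(path)) > 0.5) * 1
}

#' Write a cohort's images, masks and metadata to disk
#'
#' @param x a `phantom_cohort`.
#' @param dir output directory (created if missing).
#' @param format `"nifti"` or `"png"`.
#' @return the metadata data frame with path columns, invisibly.
#' @export
write_cohort <- function(x, dir, format = c("nifti", "png")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (format == "png") ".png" else ".nii.gz"
  md <- x$metadata
  cols <- c("l1_path", "l2_path", "l1_mask_path", "l2_mask_path")
  for (cc in cols) md[[cc]] <- NA_character_
  for (i in seq_along(x$subjects)) {
    s <- x$subjects[[i]]
    paths <- file.path(dir, paste0(s$subject_id,
                                   c("_l1", "_l2", "_l1_mask", "_l2_mask"),
                                   ext))
    if (format == "png") {
      write_slice_png(s$l1_slice, paths[1])
      write_slice_png(s$l2_slice, paths[2])
      write_mask_png(s$l1_mask, paths[3])
      write_mask_png(s$l2_mask, paths[4])
    } else {
      RNifti::writeNifti(s$l1_slice, paths[1])
      RNifti::writeNifti(s$l2_slice, paths[2])
      RNifti::writeNifti(s$l1_mask, paths[3])
      RNifti::writeNifti(s$l2_mask, paths[4])
    }
    md[i, cols] <- paths
  }
  utils::write.csv(md, file.path(dir, "metadata.csv"), row.names = FALSE)
  invisible(md)
}

#' Read a slice or mask written by [write_cohort()]
#'
#' @param path file path (`.png` or `.nii`/`.nii.gz`).
#' @param mask logical: binarise as a mask.
#' @return a numeric matrix.
#' @export
read_slice <- function(path, mask = FALSE) {
  if (grepl("\\.png$", path)) {
    if (mask) read_mask_png(path) else read_slice_png(path)
  } else {
    img <- as.matrix(RNifti::readNifti(path))
    if (mask) (img > 0.5) * 1 else img
  }
}
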