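test_that("subject generation is deterministic and respects preconditions", {
  spec <- desk_phantom_spec()
  a <- generate_subject(spec, 150, 140, seed = 3)
  b <- generate_subject(spec, 150, 140, seed = 3)
  expect_identical(a$l1_slice, b$l1_slice)
  expect_identical(a$l2_slice, b$l2_slice)
  expect_identical(a$l1_mask, b$l1_mask)
  d <- generate_subject(spec, 150, 140, seed = 4)
  expect_false(identical(a$l1_slice, d$l1_slice))
  expect_error(generate_subject(spec, 0.5, 140), "1, 400")
  expect_error(generate_subject(spec, 150, 500), "1, 400")
  expect_gt(sum(a$l1_mask), 0)
  expect_identical(dim(a$l1_mask), dim(a$l1_slice))
})

test_that("noise-free slices recover the calibration exactly", {
  spec <- desk_phantom_spec(trabecular_noise_sd = 0, vessel_probability = 0,
                            background_noise_sd = 0)
  s <- generate_subject(spec, 150, 150, seed = 5)
  er <- s$l1_mask
  vals <- s$l1_slice[erode_mask(er, 2)]
  expect_equal(unique(vals), 150)
  # non-identity calibration
  spec2 <- desk_phantom_spec(trabecular_noise_sd = 0, vessel_probability = 0,
                             background_noise_sd = 0, calibration_slope = 1.2,
                             calibration_intercept = -30,
                             cortical_intensity = 500)
  s2 <- generate_subject(spec2, 200, 200, seed = 5)
  expect_equal(unique(s2$l1_slice[erode_mask(s2$l1_mask, 2)]), 1.2 * 200 - 30)
})

test_that("mask equals the per-pixel ellipse-equation oracle", {
  spec <- desk_phantom_spec()
  # reproduce the centre draws, then check each pixel independently
  set.seed(99)
  n <- spec$image_size
  ctr <- (n + 1) / 2
  cx <- ctr + runif(1, -1, 1) * spec$center_jitter * n
  cy <- ctr + runif(1, -1, 1) * spec$center_jitter * n
  s <- generate_subject(spec, 120, 120, seed = 99)
  a <- spec$vertebra_axes[1] * n
  b <- spec$vertebra_axes[2] * n
  oracle <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      oracle[i, j] <- as.numeric(((i - cx) / a)^2 + ((j - cy) / b)^2 < 1)
    }
  }
  expect_identical(oracle, s$l1_mask)
  # single connected component: flood fill from the centroid reaches all
  lab <- s$l1_mask
  reached <- matrix(FALSE, n, n)
  seedpt <- round(c(cx, cy))
  stack <- list(seedpt)
  while (length(stack) > 0) {
    p <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (p[1] < 1 || p[1] > n || p[2] < 1 || p[2] > n) next
    if (reached[p[1], p[2]] || lab[p[1], p[2]] == 0) next
    reached[p[1], p[2]] <- TRUE
    stack <- c(stack, list(p + c(1, 0), p - c(1, 0), p + c(0, 1),
                           p - c(0, 1)))
  }
  expect_equal(sum(reached), sum(lab))
})

test_that("configuration errors are caught", {
  expect_error(phantom_spec(vertebra_axes = c(0.48, 0.2)), "fit")
  expect_error(phantom_spec(cortical_intensity = 200), "cortical_intensity")
  expect_error(phantom_spec(image_size = 16), "at least 32")
  expect_error(cohort_spec(n_subjects = 10, class_counts = c(5, 3, 1)),
               "sum")
  # normal-class mean below its truncation bound is infeasible
  bp <- default_bmd_params()
  bp$mean[1] <- 110
  expect_error(cohort_spec(bmd_params = bp), "outside its truncation bounds")
  # supports must respect the label thresholds
  bp2 <- default_bmd_params()
  bp2$lower[1] <- 100
  bp2$mean[1] <- 150
  expect_error(cohort_spec(bmd_params = bp2), "label thresholds")
})

test_that("cohorts honour class counts, labels and the threshold rule", {
  co <- small_cohort()
  md <- co$metadata
  expect_equal(nrow(md), 24)
  expect_equal(unname(table(factor(md$label, levels = bmd_classes))[1:3]),
               cohort_spec(n_subjects = 24)$class_counts,
               ignore_attr = TRUE)
  for (i in seq_len(nrow(md))) {
    s <- co$subjects[[i]]
    expect_equal(s$true_label,
                 classify_bmd(mean(c(s$true_bmd_l1, s$true_bmd_l2))))
    expect_equal(s$true_label, md$label[i])
    expect_equal(mean(c(md$bmd_l1[i], md$bmd_l2[i])), md$bmd_individual[i])
  }
  # single-class cohort
  co1 <- generate_cohort(cohort_spec(n_subjects = 10,
                                     class_counts = c(10, 0, 0), seed = 2),
                         desk_phantom_spec())
  expect_true(all(co1$metadata$label == "normal"))
  expect_true(all(co1$metadata$bmd_individual > 120))
})

test_that("per-class sample means track the printed cohort statistics", {
  co <- generate_cohort(cohort_spec(n_subjects = 1048, seed = 11),
                        phantom_spec(image_size = 32L,
                                     vertebra_axes = c(0.3, 0.22),
                                     cortical_thickness = 1,
                                     center_jitter = 0.01))
  md <- co$metadata
  expect_equal(unname(table(factor(md$label, levels = bmd_classes))),
               c(621, 296, 131), ignore_attr = TRUE)
  pars <- default_bmd_params()
  for (i in seq_len(3)) {
    cl <- pars$class[i]
    x <- md$bmd_individual[md$label == cl]
    se <- pars$sd[i] / sqrt(length(x))
    expect_lt(abs(mean(x) - pars$mean[i]), 3 * se,
              label = paste(cl, "sample mean within 3 SE"))
  }
})

test_that("calibration linearity holds across a noise-free cohort", {
  spec <- phantom_spec(image_size = 64L, cortical_thickness = 2,
                       trabecular_noise_sd = 0, vessel_probability = 0,
                       background_noise_sd = 0, calibration_slope = 1.5,
                       calibration_intercept = 10, cortical_intensity = 600)
  bmds <- seq(20, 280, length.out = 12)
  ints <- vapply(seq_along(bmds), function(i) {
    s <- generate_subject(spec, bmds[i], bmds[i], seed = i)
    mean(s$l1_slice[erode_mask(s$l1_mask, 2)])
  }, 1.0)
  fit <- stats::lm(ints ~ bmds)
  expect_equal(unname(coef(fit)[2]), 1.5, tolerance = 1e-12)
  expect_equal(unname(coef(fit)[1]), 10, tolerance = 1e-9)
})

test_that("cohort images round-trip through PNG and NIfTI", {
  co <- generate_cohort(cohort_spec(n_subjects = 2, seed = 3,
                                    class_counts = c(1, 1, 0)),
                        desk_phantom_spec())
  for (fmt in c("png", "nifti")) {
    dir <- withr::local_tempdir()
    md <- write_cohort(co, dir, format = fmt)
    expect_true(file.exists(file.path(dir, "metadata.csv")))
    img <- read_slice(md$l1_path[1])
    msk <- read_slice(md$l1_mask_path[1], mask = TRUE)
    expect_identical(dim(img), dim(co$subjects[[1]]$l1_slice))
    expect_identical(msk, co$subjects[[1]]$l1_mask)
    tol <- if (fmt == "png") 1024 / 255 / 2 + 1e-9 else 1e-6  # 8-bit step
    expect_lt(max(abs(img - co$subjects[[1]]$l1_slice)), tol)
  }
})
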