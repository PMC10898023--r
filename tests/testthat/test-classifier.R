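test_that("feature fusion stacks L1 and L2 in a fixed order", {
  a <- matrix(1:12, 3, 4)
  b <- matrix(13:24, 3, 4)
  f <- fuse_features(a, b)
  expect_equal(dim(f), c(3, 4, 2))
  expect_equal(f[, , 1], a)
  expect_equal(f[, , 2], b)
  # fuse(a, a): both channels identical
  faa <- fuse_features(a, a)
  expect_equal(faa[, , 1], faa[, , 2])
  # channel swap of fuse(a, b) equals fuse(b, a)
  fba <- fuse_features(b, a)
  expect_equal(f[, , 2:1], fba)
  expect_error(fuse_features(a, matrix(0, 2, 2)), "differ")
  big <- fuse_features(array(1, c(4, 4, 3)), array(2, c(4, 4, 3)))
  expect_equal(dim(big), c(4, 4, 2, 3))
})

test_that("classifier forward pass meets the shape and probability contracts", {
  cfg <- clf_desk_profile(in_channels = 1L)$model
  net <- build_classifier(cfg, seed = 1)
  x <- array(rnorm(96 * 96), c(96, 96, 1, 1))
  fw <- clf_forward(net$params, net$bn, cfg, x, training = FALSE)
  expect_equal(dim(fw$logits$val), c(1, 1, 3, 1))
  p <- softmax_probs(fw$logits$val)
  expect_equal(sum(p), 1, tolerance = 1e-6)
  expect_true(all(p > 0))
  # two-channel variant accepts fused input
  cfg2 <- clf_desk_profile(in_channels = 2L)$model
  net2 <- build_classifier(cfg2, seed = 1)
  x2 <- array(rnorm(96 * 96 * 2 * 3), c(96, 96, 2, 3))
  fw2 <- clf_forward(net2$params, net2$bn, cfg2, x2, training = FALSE)
  expect_equal(dim(fw2$logits$val), c(1, 1, 3, 3))
  expect_error(clf_model_config(in_channels = 3), "1 or 2")
  expect_error(clf_model_config(stage_units = c(1, 2)), "four")
  expect_equal(clf_model_config(variant = "resnet101")$stage_units,
               c(3L, 4L, 23L, 3L))
})

test_that("model-1 and model-2 builders differ only in the stem", {
  n1 <- build_classifier(clf_desk_profile(in_channels = 2L)$model, seed = 1)
  n2 <- build_classifier(clf_desk_profile(in_channels = 1L)$model, seed = 1)
  p1 <- vapply(n1$params, length, 1L)
  p2 <- vapply(n2$params, length, 1L)
  expect_identical(names(p1), names(p2))
  differing <- names(p1)[p1 != p2]
  expect_identical(differing, "stem.W")
  expect_equal(p1[["stem.W"]] - p2[["stem.W"]], 7 * 7 * 8)
})

test_that("classifier training contracts hold on a tiny problem", {
  set.seed(20)
  mk <- function(n, seed0) {
    imgs <- vector("list", n)
    labs <- character(n)
    bm <- c(160, 100, 50)
    for (i in seq_len(n)) {
      k <- (i - 1L) %% 3L + 1L
      s <- generate_subject(phantom_spec(image_size = 32L,
                                         cortical_thickness = 1,
                                         vertebra_axes = c(0.3, 0.22),
                                         center_jitter = 0.01),
                            bm[k], bm[k], seed = seed0 + i)
      imgs[[i]] <- s$l1_slice * s$l1_mask
      labs[i] <- s$true_label
    }
    list(images = imgs, labels = labs)
  }
  train <- mk(18, 100)
  val <- mk(6, 900)
  mcfg <- clf_model_config(in_channels = 1L, stage_units = c(1, 1, 1, 1),
                           base_channels = 4L, input_size = 32L)
  tcfg <- clf_train_config(epochs = 2, batch_size = 6, seed = 5)
  f1 <- train_classifier(train, val, mcfg, tcfg)
  f2 <- train_classifier(train, val, mcfg, tcfg)
  expect_identical(f1$history, f2$history)  # determinism
  p <- predict(f1, val$images, type = "prob")
  expect_equal(dim(p), c(6, 3))
  expect_equal(rowSums(p), rep(1, 6), tolerance = 1e-6)
  cl <- predict(f1, val$images, type = "class")
  expect_true(all(cl %in% bmd_classes))
  # single-class training set is refused
  one <- train
  one$labels <- rep("normal", 18)
  expect_error(train_classifier(one, val, mcfg, tcfg), "all three")
  expect_error(train_classifier(list(images = train$images,
                                     labels = rep("x", 18)), val,
                                mcfg, tcfg), "labels")
})

test_that("predict_proba enforces the variant contracts", {
  mcfg1 <- clf_model_config(in_channels = 2L, stage_units = c(1, 1, 1, 1),
                            base_channels = 4L, input_size = 32L)
  mcfg2 <- clf_model_config(in_channels = 1L, stage_units = c(1, 1, 1, 1),
                            base_channels = 4L, input_size = 32L)
  n1 <- build_classifier(mcfg1, seed = 2)
  n2 <- build_classifier(mcfg2, seed = 2)
  l1 <- matrix(rnorm(32 * 32), 32, 32)
  l2 <- matrix(rnorm(32 * 32), 32, 32)
  p <- predict_proba(n1, l1, l2, variant = "model1")
  expect_equal(dim(p), c(1, 3))
  expect_equal(sum(p), 1, tolerance = 1e-6)
  expect_error(predict_proba(n1, l1, variant = "model1"), "requires both")
  expect_error(predict_proba(n1, l1, variant = "model2"), "in_channels")
  # model 2 ignores the L2 slice entirely
  pa <- predict_proba(n2, l1, l2, variant = "model2")
  pb <- predict_proba(n2, l1, matrix(rnorm(32 * 32), 32, 32),
                      variant = "model2")
  expect_identical(pa, pb)
})

test_that("masked inputs make predictions invariant to the background", {
  mcfg <- clf_model_config(in_channels = 1L, stage_units = c(1, 1, 1, 1),
                           base_channels = 4L, input_size = 32L)
  net <- build_classifier(mcfg, seed = 3)
  s <- generate_subject(phantom_spec(image_size = 32L, cortical_thickness = 1,
                                     vertebra_axes = c(0.3, 0.22),
                                     center_jitter = 0.01),
                        120, 120, seed = 77)
  bg1 <- s$l1_slice
  bg2 <- s$l1_slice + 300 * (1 - s$l1_mask)  # different background
  p1 <- predict(net, list(bg1 * s$l1_mask))
  p2 <- predict(net, list(bg2 * s$l1_mask))
  expect_identical(p1, p2)
})
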