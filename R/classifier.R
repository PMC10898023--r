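#' Bone-mass class labels in severity order
#'
#' `c("normal", "osteopenia", "osteoporosis")` — the fixed label set and
#' column/row ordering used across the package.
#' @export
bmd_classes <- c("normal", "osteopenia", "osteoporosis")

#' Classifier model configuration
#'
#' The three-class bone-mass classifier is a residual network: a 7x7
#' stride-2 stem convolution, 3x3 stride-2 max-pooling, four residual
#' stages, global average pooling and a fully connected layer to three
#' logits. Each residual unit applies two 3x3 convolutions and one 1x1
#' convolution around an identity skip ("Block"); the first unit of every
#' stage after the first downsamples and carries a 1x1 projection
#' convolution on the skip path so dimensions match ("DBlock"). The default
#' unit counts per stage are (3, 4, 6, 3) as described in the source
#' architecture prose; `variant = "resnet101"` switches to the canonical
#' (3, 4, 23, 3).
#'
#' @param in_channels 1 (L1-only "model 2") or 2 (L1+L2 fusion "model 1").
#' @param stage_units residual units per stage; overrides `variant`.
#' @param base_channels stem output channels; stage s uses
#'   `base_channels * 2^(s-1)`.
#' @param input_size expected square input size in pixels.
#' @param variant `"described"` for (3, 4, 6, 3), `"resnet101"` for
#'   (3, 4, 23, 3).
#' @param input_scale intensity normalisation factor.
#' @return an object of class `clf_model_config`.
#' @export
clf_model_config <- function(in_channels = 2L, stage_units = NULL,
                             base_channels = 32L, input_size = 512L,
                             variant = c("described", "resnet101"),
                             input_scale = 1 / 200) {
  variant <- match.arg(variant)
  if (!in_channels %in% c(1L, 2L)) stop("in_channels must be 1 or 2")
  if (is.null(stage_units)) {
    stage_units <- if (variant == "resnet101") c(3L, 4L, 23L, 3L) else
      c(3L, 4L, 6L, 3L)
  }
  stage_units <- as.integer(stage_units)
  if (length(stage_units) != 4L || any(stage_units < 1L)) {
    stop("stage_units must be four positive counts")
  }
  structure(list(in_channels = as.integer(in_channels),
                 stage_units = stage_units,
                 base_channels = as.integer(base_channels),
                 n_classes = 3L, input_size = as.integer(input_size),
                 variant = variant, input_scale = input_scale),
            class = "clf_model_config")
}

#' Classifier training configuration
#'
#' @param epochs,batch_size,learning_rate,momentum SGD hyperparameters.
#' @param class_weights `"inverse"` for inverse-frequency weights (the
#'   cohort is roughly 6:3:1 imbalanced), `"none"` for unweighted loss.
#' @param seed integer seed.
#' @param select `"best"` validation macro-AUC checkpoint or `"last"`.
#' @return an object of class `clf_train_config`.
#' @export
clf_train_config <- function(epochs = 30L, batch_size = 16L,
                             learning_rate = 0.001, momentum = 0.9,
                             class_weights = c("inverse", "none"),
                             seed = 1L, select = c("best", "last")) {
  epochs <- as.integer(epochs)
  if (is.na(epochs) || epochs < 1L) stop("epochs must be >= 1")
  if (learning_rate <= 0 || batch_size < 1L) stop("invalid hyperparameters")
  structure(list(epochs = epochs, batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, momentum = momentum,
                 class_weights = match.arg(class_weights),
                 seed = as.integer(seed), select = match.arg(select)),
            class = "clf_train_config")
}

#' Desk-scale classifier profile
#'
#' Reduced width/depth profile used by the shipped benchmarks: 96-pixel
#' inputs, 8 stem channels, one residual unit per stage.
#'
#' @param in_channels 1 or 2.
#' @param epochs training epochs.
#' @param seed seed for the train config.
#' @return list with elements `model` and `train`.
#' @export
clf_desk_profile <- function(in_channels = 1L, epochs = 30L, seed = 1L) {
  list(model = clf_model_config(in_channels = in_channels,
                                stage_units = c(1L, 1L, 1L, 1L),
                                base_channels = 8L, input_size = 96L),
       train = clf_train_config(epochs = epochs, seed = seed))
}

#' Stack L1 and L2 vertebral images into a two-channel fusion image
#'
#' @param l1_roi,l2_roi matrices (or `(H, W, N)` arrays) of equal size.
#' @return an `(H, W, 2)` (or `(H, W, 2, N)`) array, channel 1 = L1,
#'   channel 2 = L2.
#' @export
fuse_features <- function(l1_roi, l2_roi) {
  d1 <- dim(l1_roi); d2 <- dim(l2_roi)
  if (!identical(d1, d2)) stop("L1 and L2 images differ in size")
  if (length(d1) == 2L) {
    out <- array(0, c(d1, 2L))
    out[, , 1] <- l1_roi
    out[, , 2] <- l2_roi
  } else if (length(d1) == 3L) {
    out <- array(0, c(d1[1], d1[2], 2L, d1[3]))
    out[, , 1, ] <- l1_roi
    out[, , 2, ] <- l2_roi
  } else {
    stop("expected matrices or (H, W, N) arrays")
  }
  out
}

#' Build an (untrained) bone-mass classifier
#'
#' @param config a [clf_model_config()].
#' @param seed seed for weight initialisation.
#' @return an object of class `oppscreen_classifier`.
#' @export
build_classifier <- function(config = clf_model_config(), seed = 1L) {
  stopifnot(inherits(config, "clf_model_config"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  st <- new_param_store()
  cb <- config$base_channels
  reg_conv(st, "stem", 7, 7, config$in_channels, cb)
  cin <- cb
  for (s in 1:4) {
    cs <- cb * 2L^(s - 1L)
    for (u in seq_len(config$stage_units[s])) {
      nm <- paste0("s", s, ".u", u)
      cu_in <- if (u == 1L) cin else cs
      reg_conv(st, paste0(nm, ".c1"), 3, 3, cu_in, cs)
      reg_conv(st, paste0(nm, ".c2"), 3, 3, cs, cs)
      reg_conv(st, paste0(nm, ".c3"), 1, 1, cs, cs)
      if (u == 1L && (s > 1L || cu_in != cs)) {
        reg_conv(st, paste0(nm, ".proj"), 1, 1, cu_in, cs)
      }
    }
    cin <- cs
  }
  reg_conv(st, "fc", 1, 1, cin, config$n_classes, bn = FALSE)
  structure(list(config = config, params = st$params, bn = st$bn,
                 seed = as.integer(seed), trained = FALSE, history = NULL,
                 classes = bmd_classes),
            class = "oppscreen_classifier")
}

clf_forward <- function(params, bn, config, x, training) {
  cx <- fw_ctx(params, bn, training)
  xs <- x * config$input_scale
  dim(xs) <- dim(x)
  t <- ag_leaf(cx$tape, xs)
  t <- layer_conv(cx, t, "stem", 7, stride = 2L, pad = 3L)
  t <- ag_maxpool(cx$tape, t, 3L, 2L, 1L)
  for (s in 1:4) {
    for (u in seq_len(config$stage_units[s])) {
      nm <- paste0("s", s, ".u", u)
      stride <- if (u == 1L && s > 1L) 2L else 1L
      sk <- t
      t <- layer_conv(cx, t, paste0(nm, ".c1"), 3, stride = stride, pad = 1L)
      t <- layer_conv(cx, t, paste0(nm, ".c2"), 3, pad = 1L)
      t <- layer_conv(cx, t, paste0(nm, ".c3"), 1, act = "none")
      if (!is.null(params[[paste0(nm, ".proj.W")]])) {
        sk <- layer_conv(cx, sk, paste0(nm, ".proj"), 1, stride = stride,
                         act = "none")
      }
      t <- ag_relu(cx$tape, ag_add(cx$tape, t, sk))
    }
  }
  g <- ag_gap(cx$tape, t)
  logits <- layer_conv(cx, g, "fc", 1, bn = FALSE, act = "none")
  list(cx = cx, logits = logits)
}

as_clf_tensor <- function(images, in_channels) {
  if (is.list(images)) {
    d <- dim(images[[1]])
    if (length(d) == 2L) d <- c(d, 1L)
    out <- array(0, c(d[1], d[2], d[3], length(images)))
    for (i in seq_along(images)) out[, , , i] <- images[[i]]
  } else {
    d <- dim(images)
    out <- images
    if (length(d) == 2L) dim(out) <- c(d, 1L, 1L)
    if (length(d) == 3L) {
      # (H, W, C) single fused image vs (H, W, N) stack of 1-channel images
      if (d[3] == in_channels && in_channels > 1L) {
        dim(out) <- c(d, 1L)
      } else {
        dim(out) <- c(d[1], d[2], 1L, d[3])
      }
    }
  }
  if (dim(out)[3] != in_channels) {
    stop("images have ", dim(out)[3], " channels; model expects ", in_channels)
  }
  out
}

clf_eval_probs <- function(params, bn, config, x, batch = 16L) {
  n <- dim(x)[4]
  out <- matrix(0, n, config$n_classes)
  for (s in seq(1L, n, by = batch)) {
    ii <- s:min(s + batch - 1L, n)
    fw <- clf_forward(params, bn, config, x[, , , ii, drop = FALSE],
                      training = FALSE)
    out[ii, ] <- softmax_probs(fw$logits$val)
  }
  colnames(out) <- bmd_classes
  out
}

macro_auc <- function(probs, labels) {
  mean(vapply(bmd_classes, function(cl) {
    y <- as.integer(labels == cl)
    if (length(unique(y)) < 2L) return(NA_real_)
    roc_auc(probs[, cl], y)
  }, 1.0), na.rm = TRUE)
}

#' Train the bone-mass classifier
#'
#' Seeded SGD training with weighted cross-entropy; keeps the checkpoint
#' with the best validation macro (one-vs-rest) AUC.
#'
#' @param train,validation lists with `images` (list of `(H, W)` matrices or
#'   `(H, W, C)` arrays, or a 4-d tensor) and `labels` (values in
#'   `c("normal", "osteopenia", "osteoporosis")`).
#' @param model a [clf_model_config()].
#' @param config a [clf_train_config()].
#' @return an `oppscreen_classifier` with `$history` and `$trained = TRUE`.
#' @export
train_classifier <- function(train, validation, model = clf_model_config(),
                             config = clf_train_config()) {
  stopifnot(inherits(config, "clf_train_config"))
  xtr <- as_clf_tensor(train$images, model$in_channels)
  ytr <- match(as.character(train$labels), bmd_classes)
  if (anyNA(ytr)) stop("labels must be normal / osteopenia / osteoporosis")
  if (length(unique(ytr)) < 3L) {
    stop("all three bone-mass classes must be present in the training set")
  }
  xva <- as_clf_tensor(validation$images, model$in_channels)
  yva <- as.character(validation$labels)
  n <- dim(xtr)[4]
  cw <- if (config$class_weights == "inverse") {
    w <- n / (3 * tabulate(ytr, 3L))
    w / mean(w)
  } else {
    rep(1, 3)
  }
  net <- build_classifier(model, seed = config$seed)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(config$seed + 1L)
  opt <- new_sgd(momentum = config$momentum)
  params <- net$params
  hist <- data.frame(epoch = integer(), loss = numeric(),
                     val_macro_auc = numeric())
  best <- list(auc = -Inf, params = NULL, bn = NULL)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; nb <- 0L
    for (s in seq(1L, n, by = config$batch_size)) {
      ii <- ord[s:min(s + config$batch_size - 1L, n)]
      fw <- clf_forward(params, net$bn, net$config,
                        xtr[, , , ii, drop = FALSE], training = TRUE)
      loss <- ag_softmax_ce(fw$cx$tape, fw$logits, ytr[ii], cw)
      if (!is.finite(loss$val)) {
        stop("training diverged: non-finite loss at epoch ", ep)
      }
      ag_backward(fw$cx$tape, loss)
      params <- sgd_step(opt, params, collect_grads(fw$cx),
                         config$learning_rate)
      ep_loss <- ep_loss + loss$val
      nb <- nb + 1L
    }
    pv <- clf_eval_probs(params, net$bn, net$config, xva, config$batch_size)
    va <- macro_auc(pv, yva)
    hist <- rbind(hist, data.frame(epoch = ep, loss = ep_loss / nb,
                                   val_macro_auc = va))
    if (!is.na(va) && va > best$auc) {
      best <- list(auc = va, params = params, bn = copy_bn(net$bn))
    }
  }
  if (config$select == "best" && !is.null(best$params)) {
    net$params <- best$params
    net$bn <- best$bn
  } else {
    net$params <- params
  }
  net$history <- hist
  net$trained <- TRUE
  net$train_config <- config
  net
}

#' Predict class probabilities or labels
#'
#' @param object a trained `oppscreen_classifier`.
#' @param images images as accepted by [train_classifier()].
#' @param type `"prob"` for an N x 3 probability matrix, `"class"` for
#'   arg-max labels.
#' @param batch_size evaluation batch size.
#' @param ... unused.
#' @export
predict.oppscreen_classifier <- function(object, images,
                                         type = c("prob", "class"),
                                         batch_size = 16L, ...) {
  type <- match.arg(type)
  x <- as_clf_tensor(images, object$config$in_channels)
  p <- clf_eval_probs(object$params, object$bn, object$config, x, batch_size)
  if (type == "class") bmd_classes[max.col(p)] else p
}

#' Subject-level class probabilities for the two model variants
#'
#' Model 1 consumes the channel-fused L1+L2 image and requires both slices;
#' model 2 consumes L1 alone and ignores `l2`.
#'
#' @param model a trained `oppscreen_classifier`.
#' @param l1,l2 vertebral images: matrices or `(H, W, N)` arrays.
#' @param variant `"model1"` or `"model2"`.
#' @return an N x 3 matrix of class probabilities (rows sum to 1).
#' @export
predict_proba <- function(model, l1, l2 = NULL,
                          variant = c("model1", "model2")) {
  variant <- match.arg(variant)
  if (variant == "model1") {
    if (is.null(l2)) stop("model 1 requires both the L1 and L2 slice")
    if (model$config$in_channels != 2L) {
      stop("model was built with in_channels = 1; use variant = 'model2'")
    }
    x <- fuse_features(l1, l2)
  } else {
    if (model$config$in_channels != 1L) {
      stop("model was built with in_channels = 2; use variant = 'model1'")
    }
    x <- l1
  }
  predict(model, x, type = "prob")
}

#' @export
print.oppscreen_classifier <- function(x, ...) {
  cfg <- x$config
  cat("Residual bone-mass classifier (", cfg$in_channels, "-channel input)\n",
      sep = "")
  cat("  stages:", paste(cfg$stage_units, collapse = "-"),
      " stem channels:", cfg$base_channels, "\n")
  cat("  parameters:", format(sum(vapply(x$params, length, 1L)),
                              big.mark = ","), "\n")
  if (x$trained) {
    cat("  trained:", nrow(x$history), "epochs; best validation macro AUC",
        sprintf("%.4f", max(x$history$val_macro_auc, na.rm = TRUE)), "\n")
  } else {
    cat("  untrained\n")
  }
  invisible(x)
}

#' @export
plot.oppscreen_classifier <- function(x, ...) {
  if (is.null(x$history)) stop("model has no training history")
  h <- x$history
  graphics::plot(h$epoch, h$val_macro_auc, type = "b", xlab = "epoch",
                 ylab = "validation macro AUC", ylim = c(0, 1), ...)
  invisible(x)
}
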