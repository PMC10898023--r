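#' Segmentation model configuration
#'
#' Describes the encoder-decoder vertebral-body segmenter. The encoder has
#' `depth` layers: layers 1 to `depth - 2` each apply a 1x1 convolution
#' (channel mixing / extra nonlinearity) followed by a 3x3 residual block,
#' with a stride-2 2x2 convolution between layers doing the downsampling;
#' the last two encoder layers are stride-2 2x2 convolutions only. The
#' decoder mirrors this with stride-2 2x2 transposed convolutions. At the
#' deepest skip (layer `depth - 1`) the skip features are fused by channel
#' attention: the concatenated maps are globally average-pooled, passed
#' through two 1x1 convolutions (ReLU then sigmoid), and the resulting
#' per-channel weights are multiplied onto the skip (low-level) map before
#' adding it to the upsampled (high-level) map. Upper skips use plain
#' concatenation followed by a 3x3 convolution. A final 1x1 convolution
#' produces the foreground logit. All convolutions are followed by batch
#' normalization and ReLU unless noted.
#'
#' Channel widths are `base_channels * channel_growth^(i-1)` for layer i,
#' capped from layer `depth - 2` on, so the two deepest layers reuse the
#' widest width.
#'
#' @param depth number of encoder layers (default 7). The input spatial size
#'   must be divisible by `2^(depth-1)`.
#' @param base_channels channels at the first layer.
#' @param channel_growth per-layer channel multiplier.
#' @param attention_reduction channel reduction inside the attention block.
#' @param in_channels,out_channels input/output channel counts.
#' @param use_attention set `FALSE` for the plain-concatenation baseline
#'   (a conventional U-Net-style skip at every level).
#' @param input_scale multiplicative intensity normalisation applied to
#'   images before the first convolution.
#' @return an object of class `seg_model_config`.
#' @export
seg_model_config <- function(depth = 7L, base_channels = 16L,
                             channel_growth = 2, attention_reduction = 4L,
                             in_channels = 1L, out_channels = 1L,
                             use_attention = TRUE, input_scale = 1 / 200) {
  depth <- as.integer(depth)
  if (depth < 3L) stop("depth must be at least 3")
  if (base_channels < 1L || channel_growth < 1) stop("invalid channel scheme")
  ch <- as.integer(round(base_channels * channel_growth ^
                           (pmin(seq_len(depth), depth - 2L) - 1L)))
  structure(list(depth = depth, base_channels = as.integer(base_channels),
                 channel_growth = channel_growth,
                 attention_reduction = as.integer(attention_reduction),
                 in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 use_attention = isTRUE(use_attention),
                 input_scale = input_scale, channels = ch),
            class = "seg_model_config")
}

#' Segmentation training configuration
#'
#' @param epochs training epochs (>= 1).
#' @param batch_size minibatch size.
#' @param learning_rate SGD learning rate.
#' @param momentum SGD momentum.
#' @param augmentation named logical list enabling random flipping,
#'   rotation (+/- 15 degrees), left-right mirroring and random cropping
#'   (90-100\% of the field, rescaled back).
#' @param loss `"dice_bce"` (soft-Dice plus binary cross-entropy, the
#'   default), `"dice"` or `"bce"`.
#' @param seed integer seed controlling initialisation, shuffling and
#'   augmentation.
#' @param select checkpoint selection: `"best"` tuning-set mean DSC or
#'   `"last"` epoch.
#' @return an object of class `seg_train_config`.
#' @export
seg_train_config <- function(epochs = 25L, batch_size = 8L,
                             learning_rate = 0.001, momentum = 0.98,
                             augmentation = list(flip = TRUE, rotation = TRUE,
                                                 mirror = TRUE, crop = TRUE),
                             loss = c("dice_bce", "dice", "bce"),
                             seed = 1L, select = c("best", "last")) {
  epochs <- as.integer(epochs)
  if (is.na(epochs) || epochs < 1L) stop("epochs must be >= 1")
  if (learning_rate <= 0) stop("learning_rate must be positive")
  structure(list(epochs = epochs, batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, momentum = momentum,
                 augmentation = augmentation, loss = match.arg(loss),
                 seed = as.integer(seed), select = match.arg(select)),
            class = "seg_train_config")
}

#' Desk-scale and full-scale segmentation profiles
#'
#' `seg_desk_profile()` is the configuration pair exercised by the test
#' suite and the shipped benchmarks: 96-pixel phantoms, a depth-5 encoder
#' with 8 base channels, and a short SGD schedule. `seg_paper_profile()`
#' is the full-scale counterpart (512-pixel inputs, depth 7, 500 epochs,
#' batch 64) and is provided for completeness; it is far too heavy for a
#' single-CPU test run.
#'
#' @param epochs number of epochs for the desk profile.
#' @param seed seed passed to the train config.
#' @return list with elements `model` and `train`.
#' @export
seg_desk_profile <- function(epochs = 20L, seed = 1L) {
  list(model = seg_model_config(depth = 5L, base_channels = 8L),
       train = seg_train_config(epochs = epochs, batch_size = 4L, seed = seed))
}

#' @rdname seg_desk_profile
#' @export
seg_paper_profile <- function(seed = 1L) {
  list(model = seg_model_config(depth = 7L, base_channels = 16L),
       train = seg_train_config(epochs = 500L, batch_size = 64L, seed = seed))
}

att_channels <- function(c2, reduction) max(4L, as.integer(c2 %/% reduction))

reg_convt <- function(st, name, k, cin, cout) {
  st$params[[paste0(name, ".W")]] <- init_conv_w(k, k, cout, cin)
  st$params[[paste0(name, ".b")]] <- numeric(cout)
  st$params[[paste0(name, ".g")]] <- rep(1, cout)
  st$params[[paste0(name, ".be")]] <- numeric(cout)
  rs <- new.env(parent = emptyenv())
  rs$mean <- numeric(cout)
  rs$var <- rep(1, cout)
  st$bn[[name]] <- rs
  invisible(st)
}

#' Build an (untrained) segmentation model
#'
#' Instantiates all parameters of the encoder-decoder from a
#' [seg_model_config()] with He-normal initialisation.
#'
#' @param config a [seg_model_config()].
#' @param seed seed for weight initialisation.
#' @return an object of class `oppscreen_segnet`.
#' @export
build_segmentation_model <- function(config = seg_model_config(), seed = 1L) {
  stopifnot(inherits(config, "seg_model_config"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  st <- new_param_store()
  D <- config$depth
  ch <- config$channels
  reg_conv(st, "e1.pre", 1, 1, config$in_channels, ch[1])
  reg_conv(st, "e1.ra", 3, 3, ch[1], ch[1])
  reg_conv(st, "e1.rb", 3, 3, ch[1], ch[1])
  for (i in seq_len(max(0L, D - 3L)) + 1L) {
    reg_conv(st, paste0("e", i, ".down"), 2, 2, ch[i - 1], ch[i])
    reg_conv(st, paste0("e", i, ".pre"), 1, 1, ch[i], ch[i])
    reg_conv(st, paste0("e", i, ".ra"), 3, 3, ch[i], ch[i])
    reg_conv(st, paste0("e", i, ".rb"), 3, 3, ch[i], ch[i])
  }
  reg_conv(st, paste0("e", D - 1, ".down"), 2, 2, ch[D - 2], ch[D - 1])
  reg_conv(st, paste0("e", D, ".down"), 2, 2, ch[D - 1], ch[D])
  reg_convt(st, paste0("u", D - 1, ".up"), 2, ch[D], ch[D - 1])
  if (config$use_attention) {
    ca <- att_channels(2L * ch[D - 1], config$attention_reduction)
    reg_conv(st, "att.a", 1, 1, 2L * ch[D - 1], ca, bn = FALSE)
    reg_conv(st, "att.b", 1, 1, ca, ch[D - 1], bn = FALSE)
  } else {
    reg_conv(st, paste0("u", D - 1, ".mix"), 3, 3, 2L * ch[D - 1], ch[D - 1])
  }
  for (i in (D - 2):1) {
    reg_convt(st, paste0("u", i, ".up"), 2, ch[i + 1], ch[i])
    reg_conv(st, paste0("u", i, ".mix"), 3, 3, 2L * ch[i], ch[i])
  }
  reg_conv(st, "out", 1, 1, ch[1], config$out_channels, bn = FALSE)
  structure(list(config = config, params = st$params, bn = st$bn,
                 seed = as.integer(seed), trained = FALSE, history = NULL),
            class = "oppscreen_segnet")
}

res_block <- function(cx, x, name) {
  u <- layer_conv(cx, x, paste0(name, ".ra"), 3, pad = 1L)
  u <- layer_conv(cx, u, paste0(name, ".rb"), 3, pad = 1L, act = "none")
  ag_relu(cx$tape, ag_add(cx$tape, u, x))
}

attention_fuse_nodes <- function(cx, low, high, prefix = "att") {
  cat_n <- ag_concat(cx$tape, low, high)
  g <- ag_gap(cx$tape, cat_n)
  a <- layer_conv(cx, g, paste0(prefix, ".a"), 1, bn = FALSE, act = "relu")
  w <- layer_conv(cx, a, paste0(prefix, ".b"), 1, bn = FALSE, act = "sigmoid")
  ag_add(cx$tape, ag_cmul(cx$tape, low, w), high)
}

segnet_forward <- function(params, bn, config, x, training) {
  d <- dim(x)
  D <- config$depth
  if (d[1] %% 2^(D - 1) || d[2] %% 2^(D - 1)) {
    stop("input spatial size must be divisible by 2^(depth-1) = ", 2^(D - 1))
  }
  cx <- fw_ctx(params, bn, training)
  xs <- x * config$input_scale
  dim(xs) <- d
  t <- ag_leaf(cx$tape, xs)
  skips <- vector("list", D - 1L)
  t <- layer_conv(cx, t, "e1.pre", 1)
  t <- res_block(cx, t, "e1")
  skips[[1]] <- t
  for (i in seq_len(max(0L, D - 3L)) + 1L) {
    t <- layer_conv(cx, t, paste0("e", i, ".down"), 2, stride = 2L)
    t <- layer_conv(cx, t, paste0("e", i, ".pre"), 1)
    t <- res_block(cx, t, paste0("e", i))
    skips[[i]] <- t
  }
  t <- layer_conv(cx, t, paste0("e", D - 1, ".down"), 2, stride = 2L)
  skips[[D - 1]] <- t
  t <- layer_conv(cx, t, paste0("e", D, ".down"), 2, stride = 2L)
  t <- layer_convt(cx, t, paste0("u", D - 1, ".up"))
  if (config$use_attention) {
    t <- attention_fuse_nodes(cx, skips[[D - 1]], t)
  } else {
    t <- ag_concat(cx$tape, t, skips[[D - 1]])
    t <- layer_conv(cx, t, paste0("u", D - 1, ".mix"), 3, pad = 1L)
  }
  for (i in (D - 2):1) {
    t <- layer_convt(cx, t, paste0("u", i, ".up"))
    t <- ag_concat(cx$tape, t, skips[[i]])
    t <- layer_conv(cx, t, paste0("u", i, ".mix"), 3, pad = 1L)
  }
  logits <- layer_conv(cx, t, "out", 1, bn = FALSE, act = "none")
  list(cx = cx, logits = logits)
}

#' Channel-attention fusion of two feature maps
#'
#' Per-channel weights are derived from the globally average-pooled
#' concatenation of the two maps through two 1x1 convolutions (ReLU, then
#' sigmoid), multiplied onto the low-level map, and the result is added to
#' the high-level map. The output has the shape of `high`.
#'
#' @param low,high feature maps `(H, W, C)` or `(H, W, C, N)` with equal
#'   spatial sizes and equal channel counts.
#' @param reduction channel reduction in the bottleneck of the attention MLP.
#' @param weights optional fixed per-channel weights (length C), bypassing
#'   the learned pooling path; `weights = 1` reduces the fusion to plain
#'   addition.
#' @param seed seed for the (random) attention parameters when none are
#'   learned.
#' @return fused array shaped like `high`, with the applied per-channel
#'   weights in attribute `"weights"`.
#' @export
channel_attention_fuse <- function(low, high, reduction = 4L, weights = NULL,
                                   seed = 1L) {
  was3d <- length(dim(low)) == 3L
  if (was3d) {
    dim(low) <- c(dim(low), 1L)
    dim(high) <- c(dim(high), 1L)
  }
  dl <- dim(low); dh <- dim(high)
  if (!all(dl[1:2] == dh[1:2])) stop("spatial sizes differ")
  if (dl[3] != dh[3]) stop("channel counts differ")
  if (!is.null(weights)) {
    w <- array(rep_len(weights, dh[3] * dh[4]), c(1, 1, dh[3], dh[4]))
    hw <- dh[1] * dh[2]
    out <- low * rep(as.numeric(w), each = hw) + high
    dim(out) <- dh
  } else {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
    st <- new_param_store()
    ca <- att_channels(2L * dl[3], reduction)
    reg_conv(st, "att.a", 1, 1, 2L * dl[3], ca, bn = FALSE)
    reg_conv(st, "att.b", 1, 1, ca, dl[3], bn = FALSE)
    cx <- fw_ctx(st$params, st$bn, training = FALSE)
    fused <- attention_fuse_nodes(cx, ag_leaf(cx$tape, low),
                                  ag_leaf(cx$tape, high))
    out <- fused$val
    # recompute the weights for reporting
    gcat <- ag_gap(cx$tape, ag_concat(cx$tape, ag_leaf(cx$tape, low),
                                      ag_leaf(cx$tape, high)))
    a <- layer_conv(cx, gcat, "att.a", 1, bn = FALSE, act = "relu")
    wn <- layer_conv(cx, a, "att.b", 1, bn = FALSE, act = "sigmoid")
    w <- wn$val
  }
  if (was3d) {
    dim(out) <- dh[1:3]
  }
  attr(out, "weights") <- as.numeric(w)
  out
}

#' Dice similarity coefficient
#'
#' `2|A intersect B| / (|A| + |B|)` between two binary masks; defined as 1
#' when both masks are empty.
#'
#' @param a,b binary arrays of identical shape.
#' @return a number in `[0, 1]`.
#' @export
dsc <- function(a, b) {
  if (!identical(dim(a), dim(b)) && length(a) != length(b)) {
    stop("mask shapes differ")
  }
  a <- as.numeric(a) != 0
  b <- as.numeric(b) != 0
  s <- sum(a) + sum(b)
  if (s == 0) return(1)
  2 * sum(a & b) / s
}

as_image_tensor <- function(x, channels = 1L) {
  if (is.list(x)) {
    d <- dim(x[[1]])
    if (length(d) == 2L) d <- c(d, channels)
    out <- array(0, c(d[1], d[2], d[3], length(x)))
    for (i in seq_along(x)) out[, , , i] <- x[[i]]
    return(out)
  }
  d <- dim(x)
  if (length(d) == 2L) {
    dim(x) <- c(d, 1L, 1L)
  } else if (length(d) == 3L) {
    dim(x) <- c(d[1], d[2], 1L, d[3])
  }
  x
}

seg_eval_dsc <- function(params, bn, config, images, masks, batch = 8L,
                         threshold = 0.5) {
  n <- dim(images)[4]
  out <- numeric(n)
  for (s in seq(1L, n, by = batch)) {
    ii <- s:min(s + batch - 1L, n)
    fw <- segnet_forward(params, bn, config,
                         images[, , , ii, drop = FALSE], training = FALSE)
    p <- 1 / (1 + exp(-fw$logits$val))
    for (k in seq_along(ii)) {
      out[ii[k]] <- dsc(p[, , , k] >= threshold, masks[, , , ii[k]])
    }
  }
  out
}

#' Train the segmentation model
#'
#' Seeded SGD training of the encoder-decoder on image/mask pairs, with the
#' configured augmentations applied on the fly. After every epoch the mean
#' DSC on the tuning set is recorded; the returned model carries the
#' checkpoint with the best tuning DSC (or the last epoch, per
#' `config$select`).
#'
#' @param train,tuning lists with elements `images` and `masks`: lists of
#'   matrices or `(H, W, N)` / `(H, W, 1, N)` arrays.
#' @param model a [seg_model_config()].
#' @param config a [seg_train_config()].
#' @return an `oppscreen_segnet` with `$history` (per-epoch loss and tuning
#'   DSC) and `$trained = TRUE`.
#' @export
train_segmentation <- function(train, tuning, model = seg_model_config(),
                               config = seg_train_config()) {
  stopifnot(inherits(config, "seg_train_config"))
  xtr <- as_image_tensor(train$images)
  mtr <- as_image_tensor(train$masks)
  xtu <- as_image_tensor(tuning$images)
  mtu <- as_image_tensor(tuning$masks)
  n <- dim(xtr)[4]
  if (n < 1L || dim(xtu)[4] < 1L) stop("empty training or tuning set")
  net <- build_segmentation_model(model, seed = config$seed)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(config$seed + 1L)
  opt <- new_sgd(momentum = config$momentum)
  w_dice <- if (config$loss == "bce") 0 else 1
  w_bce <- if (config$loss == "dice") 0 else 1
  params <- net$params
  hist <- data.frame(epoch = integer(), loss = numeric(), tune_dsc = numeric())
  best <- list(dsc = -Inf, params = NULL, bn = NULL)
  aug_on <- any(unlist(config$augmentation))
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    nb <- 0L
    for (s in seq(1L, n, by = config$batch_size)) {
      ii <- ord[s:min(s + config$batch_size - 1L, n)]
      xb <- xtr[, , , ii, drop = FALSE]
      mb <- mtr[, , , ii, drop = FALSE]
      if (aug_on) {
        for (k in seq_along(ii)) {
          au <- augment(xb[, , 1, k], mb[, , 1, k], config$augmentation)
          xb[, , 1, k] <- au$image
          mb[, , 1, k] <- au$mask
        }
      }
      fw <- segnet_forward(params, net$bn, net$config, xb, training = TRUE)
      loss <- ag_dice_bce(fw$cx$tape, fw$logits, mb, w_dice, w_bce)
      if (!is.finite(loss$val)) {
        stop("training diverged: non-finite loss at epoch ", ep)
      }
      ag_backward(fw$cx$tape, loss)
      params <- sgd_step(opt, params, collect_grads(fw$cx),
                         config$learning_rate)
      ep_loss <- ep_loss + loss$val
      nb <- nb + 1L
    }
    td <- mean(seg_eval_dsc(params, net$bn, net$config, xtu, mtu,
                            config$batch_size))
    hist <- rbind(hist, data.frame(epoch = ep, loss = ep_loss / nb,
                                   tune_dsc = td))
    if (td > best$dsc) {
      best <- list(dsc = td, params = params, bn = copy_bn(net$bn))
    }
  }
  if (config$select == "best") {
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

#' Predict segmentation masks
#'
#' @param object a trained `oppscreen_segnet`.
#' @param images images as accepted by [train_segmentation()].
#' @param type `"mask"` for thresholded binary masks, `"prob"` for
#'   foreground probabilities.
#' @param threshold probability threshold for `type = "mask"`.
#' @param batch_size evaluation batch size.
#' @param ... unused.
#' @return an `(H, W, N)` array.
#' @export
predict.oppscreen_segnet <- function(object, images, type = c("mask", "prob"),
                                     threshold = 0.5, batch_size = 8L, ...) {
  type <- match.arg(type)
  x <- as_image_tensor(images)
  d <- dim(x)
  out <- array(0, c(d[1], d[2], d[4]))
  for (s in seq(1L, d[4], by = batch_size)) {
    ii <- s:min(s + batch_size - 1L, d[4])
    fw <- segnet_forward(object$params, object$bn, object$config,
                         x[, , , ii, drop = FALSE], training = FALSE)
    p <- 1 / (1 + exp(-fw$logits$val))
    out[, , ii] <- p[, , 1, ]
  }
  if (type == "mask") out <- (out >= threshold) * 1
  out
}

#' @export
print.oppscreen_segnet <- function(x, ...) {
  cfg <- x$config
  cat("Encoder-decoder vertebral segmenter\n")
  cat("  depth:", cfg$depth, " channels:", paste(cfg$channels, collapse = "/"),
      "\n")
  cat("  attention skip fusion:", cfg$use_attention, "\n")
  cat("  parameters:", format(sum(vapply(x$params, length, 1L)),
                              big.mark = ","), "\n")
  if (x$trained) {
    cat("  trained:", nrow(x$history), "epochs; best tuning DSC",
        sprintf("%.4f", max(x$history$tune_dsc)), "\n")
  } else {
    cat("  untrained\n")
  }
  invisible(x)
}

#' @export
plot.oppscreen_segnet <- function(x, ...) {
  if (is.null(x$history)) stop("model has no training history")
  h <- x$history
  graphics::plot(h$epoch, h$tune_dsc, type = "b", xlab = "epoch",
                 ylab = "tuning DSC", ylim = c(0, 1), ...)
  invisible(x)
}

#' DSC-versus-training-size learning curve
#'
#' Trains the segmenter from scratch on seeded subsamples of a training
#' pool and records the mean and SD of the per-image test DSC for each
#' subsample size. The subsample seed is derived from `config$seed` and the
#' size itself, so repeated sizes give identical entries.
#'
#' @param pool,test lists with `images` and `masks`.
#' @param sizes increasing vector of training-set sizes.
#' @param model,config model and training configuration.
#' @return a data frame (class `oppscreen_learning_curve`) with columns
#'   `n_train`, `dsc_mean`, `dsc_sd`.
#' @export
learning_curve <- function(pool, test, sizes, model = seg_model_config(),
                           config = seg_train_config()) {
  xp <- as_image_tensor(pool$images)
  mp <- as_image_tensor(pool$masks)
  n <- dim(xp)[4]
  if (any(sizes > n)) stop("a requested size exceeds the pool size")
  if (any(sizes < 1)) stop("sizes must be positive")
  rows <- lapply(sizes, function(sz) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed((config$seed + 131L * sz) %% .Machine$integer.max)
    ii <- sort(sample.int(n, sz))
    # split off a small tuning subset from the subsample
    ntu <- max(1L, round(0.1 * sz))
    tune_i <- ii[seq_len(ntu)]
    train_i <- setdiff(ii, tune_i)
    if (length(train_i) == 0L) train_i <- tune_i
    fit <- train_segmentation(
      list(images = xp[, , , train_i, drop = FALSE],
           masks = mp[, , , train_i, drop = FALSE]),
      list(images = xp[, , , tune_i, drop = FALSE],
           masks = mp[, , , tune_i, drop = FALSE]),
      model, config)
    dv <- seg_eval_dsc(fit$params, fit$bn, fit$config,
                       as_image_tensor(test$images),
                       as_image_tensor(test$masks), config$batch_size)
    data.frame(n_train = sz, dsc_mean = mean(dv), dsc_sd = stats::sd(dv))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("oppscreen_learning_curve", "data.frame")
  out
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}
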