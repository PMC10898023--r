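# Paired image/mask augmentation: random flipping, left-right mirroring,
# rotation and random cropping, applied as one affine resampling so the
# image (bilinear) and mask (nearest-neighbour, stays binary) receive the
# identical spatial transform. The drawn parameters are returned so any
# transform can be replayed exactly.

apply_augment_params <- function(image, mask, params, fill = 0) {
  H <- nrow(image); W <- ncol(image)
  identityp <- !params$flip && !params$mirror && params$angle == 0 &&
    params$scale == 1 && params$dx == 0 && params$dy == 0
  if (identityp) {
    return(list(image = image, mask = mask, params = params))
  }
  if (params$angle == 0 && params$scale == 1 &&
      params$dx == 0 && params$dy == 0) {
    # pure flips: exact index reversal
    ri <- if (params$flip) rev(seq_len(H)) else seq_len(H)
    ci <- if (params$mirror) rev(seq_len(W)) else seq_len(W)
    return(list(image = image[ri, ci, drop = FALSE],
                mask = mask[ri, ci, drop = FALSE], params = params))
  }
  cr <- (H + 1) / 2; cc <- (W + 1) / 2
  u <- rep(seq_len(H) - cr, times = W)
  v <- rep(seq_len(W) - cc, each = H)
  # crop-zoom: sample a (scale*H x scale*W) window centred at (dx, dy)
  u2 <- u * params$scale + params$dx
  v2 <- v * params$scale + params$dy
  th <- params$angle * pi / 180
  u3 <- cos(th) * u2 + sin(th) * v2
  v3 <- -sin(th) * u2 + cos(th) * v2
  if (params$flip) u3 <- -u3
  if (params$mirror) v3 <- -v3
  sr <- u3 + cr; sc <- v3 + cc
  # nearest neighbour (mask)
  nr <- round(sr); nc <- round(sc)
  ok <- nr >= 1 & nr <= H & nc >= 1 & nc <= W
  mk <- numeric(H * W)
  mk[ok] <- mask[cbind(nr[ok], nc[ok])]
  dim(mk) <- c(H, W)
  # bilinear (image)
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  img <- rep(fill, H * W)
  pick <- function(r, c) {
    val <- rep(fill, length(r))
    okk <- r >= 1 & r <= H & c >= 1 & c <= W
    val[okk] <- image[cbind(r[okk], c[okk])]
    val
  }
  img <- (1 - fr) * (1 - fc) * pick(r0, c0) +
    fr * (1 - fc) * pick(r0 + 1, c0) +
    (1 - fr) * fc * pick(r0, c0 + 1) +
    fr * fc * pick(r0 + 1, c0 + 1)
  dim(img) <- c(H, W)
  list(image = img, mask = mk, params = params)
}

#' Paired augmentation of an image and its mask
#'
#' Draws one random spatial transform (vertical flip, left-right mirror,
#' rotation within +/- `rotation_range` degrees, crop of
#' `crop_range` of the field rescaled back to full size) and applies it
#' identically to image (bilinear) and mask (nearest neighbour, so the mask
#' stays binary). With all switches off the inputs are returned unchanged.
#'
#' @param image numeric matrix.
#' @param mask binary matrix of the same shape.
#' @param switches named logical list with entries `flip`, `rotation`,
#'   `mirror`, `crop`.
#' @param params optional parameter list from a previous call, replayed
#'   exactly instead of drawing new ones.
#' @param seed optional integer seed for the draw.
#' @param rotation_range,crop_range ranges for the rotation (degrees) and
#'   crop fraction draws.
#' @param fill intensity used outside the source image.
#' @return list with `image`, `mask` and the drawn `params`.
#' @export
augment <- function(image, mask,
                    switches = list(flip = TRUE, rotation = TRUE,
                                    mirror = TRUE, crop = TRUE),
                    params = NULL, seed = NULL, rotation_range = 15,
                    crop_range = c(0.9, 1), fill = 0) {
  if (!identical(dim(image), dim(mask))) stop("image and mask shapes differ")
  if (is.null(params)) {
    if (!is.null(seed)) {
      old <- get_rng_state()
      on.exit(restore_rng_state(old))
      set.seed(seed)
    }
    gs <- function(nm) isTRUE(switches[[nm]])
    params <- list(
      flip = gs("flip") && stats::runif(1) < 0.5,
      mirror = gs("mirror") && stats::runif(1) < 0.5,
      angle = if (gs("rotation")) stats::runif(1, -rotation_range,
                                               rotation_range) else 0,
      scale = if (gs("crop")) stats::runif(1, crop_range[1],
                                           crop_range[2]) else 1,
      dx = 0, dy = 0)
    if (gs("crop") && params$scale < 1) {
      lim <- (1 - params$scale) / 2
      params$dx <- stats::runif(1, -lim, lim) * nrow(image)
      params$dy <- stats::runif(1, -lim, lim) * ncol(image)
    }
  }
  apply_augment_params(image, mask, params, fill = fill)
}

#' Replay a logged augmentation transform
#'
#' @param image,mask as in [augment()].
#' @param params the `params` element returned by a previous [augment()].
#' @param fill intensity used outside the source image.
#' @return list with `image`, `mask`, `params`.
#' @export
augment_replay <- function(image, mask, params, fill = 0) {
  apply_augment_params(image, mask, params, fill = fill)
}
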