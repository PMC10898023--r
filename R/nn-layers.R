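# Layer-level helpers on top of the tape engine: parameter initialisation,
# a forward-pass context that lazily wraps parameters as tape leaves, and
# plain SGD-with-momentum updates.

init_conv_w <- function(kh, kw, cin, cout) {
  matrix(rnorm(kh * kw * cin * cout, sd = sqrt(2 / (kh * kw * cin))),
         nrow = kh * kw * cin, ncol = cout)
}

# register a conv (+ optional BN) parameter group under `name`
reg_conv <- function(st, name, kh, kw, cin, cout, bn = TRUE) {
  st$params[[paste0(name, ".W")]] <- init_conv_w(kh, kw, cin, cout)
  st$params[[paste0(name, ".b")]] <- numeric(cout)
  if (bn) {
    st$params[[paste0(name, ".g")]] <- rep(1, cout)
    st$params[[paste0(name, ".be")]] <- numeric(cout)
    rs <- new.env(parent = emptyenv())
    rs$mean <- numeric(cout)
    rs$var <- rep(1, cout)
    st$bn[[name]] <- rs
  }
  invisible(st)
}

new_param_store <- function() {
  st <- new.env(parent = emptyenv())
  st$params <- list()
  st$bn <- list()
  st
}

# forward context: one per minibatch pass
fw_ctx <- function(params, bn, training) {
  cx <- new.env(parent = emptyenv())
  cx$tape <- ag_tape()
  cx$params <- params
  cx$bn <- bn
  cx$leaves <- list()
  cx$training <- training
  cx
}

pleaf <- function(cx, name) {
  lf <- cx$leaves[[name]]
  if (is.null(lf)) {
    v <- cx$params[[name]]
    if (is.null(v)) stop("unknown parameter: ", name)
    lf <- ag_leaf(cx$tape, v)
    cx$leaves[[name]] <- lf
  }
  lf
}

layer_conv <- function(cx, x, name, kh, kw = kh, stride = 1L, pad = 0L,
                       bn = TRUE, act = c("relu", "none", "sigmoid")) {
  act <- match.arg(act)
  y <- ag_conv(cx$tape, x, pleaf(cx, paste0(name, ".W")),
               pleaf(cx, paste0(name, ".b")), kh, kw, stride, pad)
  if (bn) {
    y <- ag_bn(cx$tape, y, pleaf(cx, paste0(name, ".g")),
               pleaf(cx, paste0(name, ".be")), cx$bn[[name]], cx$training)
  }
  switch(act,
         relu = ag_relu(cx$tape, y),
         sigmoid = ag_sigmoid(cx$tape, y),
         none = y)
}

layer_convt <- function(cx, x, name, k = 2L, stride = 2L, bn = TRUE,
                        act = "relu") {
  y <- ag_convt(cx$tape, x, pleaf(cx, paste0(name, ".W")),
                pleaf(cx, paste0(name, ".b")), k, k, stride)
  if (bn) {
    y <- ag_bn(cx$tape, y, pleaf(cx, paste0(name, ".g")),
               pleaf(cx, paste0(name, ".be")), cx$bn[[name]], cx$training)
  }
  if (identical(act, "relu")) y <- ag_relu(cx$tape, y)
  y
}

# collect parameter gradients accumulated on the context's leaves
collect_grads <- function(cx) {
  out <- list()
  for (nm in names(cx$leaves)) {
    g <- cx$leaves[[nm]]$grad
    if (!is.null(g)) out[[nm]] <- g
  }
  out
}

new_sgd <- function(momentum = 0.9, weight_decay = 0) {
  o <- new.env(parent = emptyenv())
  o$v <- list()
  o$momentum <- momentum
  o$weight_decay <- weight_decay
  o
}

sgd_step <- function(opt, params, grads, lr) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    p <- params[[nm]]
    if (opt$weight_decay > 0 && grepl("\\.W$", nm)) g <- g + opt$weight_decay * p
    v <- opt$v[[nm]]
    if (is.null(v)) v <- 0
    v <- opt$momentum * v - lr * g
    opt$v[[nm]] <- v
    params[[nm]] <- p + v
  }
  params
}

# deep-copy the mutable BN state (running stats) so checkpoints are frozen
copy_bn <- function(bn) {
  lapply(bn, function(rs) {
    e <- new.env(parent = emptyenv())
    e$mean <- rs$mean
    e$var <- rs$var
    e
  })
}
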