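#' Build a U-Net segmentation model
#'
#' Constructs the network a [variant_spec()] describes: per encoder level,
#' two same-padding block convolutions (each followed by ReLU, and by batch
#' normalization when enabled) and a 2x2 max-pool; a two-convolution
#' bottleneck; per decoder level, a 2x2 stride-2 transposed convolution to
#' the mirrored channel count, channel concatenation with the matching
#' encoder skip, and two block convolutions; and a 1x1 convolution head with
#' sigmoid activation. Spatial geometry is preserved end-to-end, so inputs
#' must have height and width divisible by `2^encoder_levels`.
#'
#' Convolution weights are initialized He-uniform
#' (\eqn{U(-\sqrt{6/f}, \sqrt{6/f})} with fan-in \eqn{f = k^2 c_{in}}),
#' biases at zero; batch-norm scale/shift/statistics at 1/0/0/1.
#'
#' @param spec a [variant_spec()] or a variant name.
#' @param seed optional integer; when given, initialization is drawn under a
#'   local RNG seed (the global RNG state is untouched) and two builds with
#'   the same seed are identical.
#' @return an object of class `unet_model` with elements `spec`, `params`
#'   and `bn_epsilon`.
#' @examples
#' m <- build_unet("U-Net16", seed = 1)
#' count_parameters(m)  # 52993
#' @export
build_unet <- function(spec, seed = NULL) {
  if (is.character(spec)) spec <- resolve_variant(spec)
  stopifnot(inherits(spec, "variant_spec"))
  make <- function() .init_params(spec)
  params <- if (is.null(seed)) make() else with_local_seed(seed, make())
  structure(list(spec = spec, params = params, bn_epsilon = 1e-5),
            class = "unet_model")
}

.init_conv <- function(k, cin, cout, bn) {
  fan_in <- k * k * cin
  lim <- sqrt(6 / fan_in)
  layer <- list(w = array(runif(k * k * cin * cout, -lim, lim),
                          dim = c(k, k, cin, cout)),
                b = numeric(cout))
  if (bn) {
    layer$gamma <- rep(1, cout)
    layer$beta <- numeric(cout)
    layer$mean <- numeric(cout)
    layer$var <- rep(1, cout)
  }
  layer
}

.init_params <- function(spec) {
  k <- spec$conv_kernel
  bn <- spec$use_batchnorm
  ch <- level_channels(spec)
  L <- spec$encoder_levels
  enc <- vector("list", L)
  prev <- spec$in_channels
  for (i in seq_len(L)) {
    enc[[i]] <- list(conv1 = .init_conv(k, prev, ch$levels[i], bn),
                     conv2 = .init_conv(k, ch$levels[i], ch$levels[i], bn))
    prev <- ch$levels[i]
  }
  bott <- list(conv1 = .init_conv(k, prev, ch$bottleneck, bn),
               conv2 = .init_conv(k, ch$bottleneck, ch$bottleneck, bn))
  dec <- vector("list", L)
  up_in <- ch$bottleneck
  for (i in rev(seq_len(L))) {
    ci <- ch$levels[i]
    dec[[i]] <- list(up = .init_conv(spec$up_kernel, up_in, ci, FALSE),
                     conv1 = .init_conv(k, 2L * ci, ci, bn),
                     conv2 = .init_conv(k, ci, ci, bn))
    up_in <- ci
  }
  head <- .init_conv(1L, ch$levels[1], spec$out_channels, FALSE)
  list(encoder = enc, bottleneck = bott, decoder = dec, head = head)
}

#' Count the scalar parameters of a built model
#'
#' Total number of stored scalar values: convolution weights and biases,
#' plus batch-normalization scale, shift, mean and variance when enabled.
#' Must agree with [closed_form_param_count()] of the model's spec for every
#' valid spec.
#'
#' @param model a `unet_model`.
#' @return numeric count.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "unet_model"))
  tree_length(model$params)
}

#' @export
print.unet_model <- function(x, ...) {
  cat(sprintf("<unet_model> %s: %s parameters\n", x$spec$name,
              format(count_parameters(x), big.mark = ",")))
  print(x$spec)
  invisible(x)
}

.check_geometry <- function(spec, dims) {
  div <- 2L^spec$encoder_levels
  if (dims[1] %% div != 0L || dims[2] %% div != 0L) {
    stop(sprintf(
      "input spatial size %dx%d is not divisible by 2^%d = %d",
      dims[1], dims[2], spec$encoder_levels, div), call. = FALSE)
  }
  if (dims[3] != spec$in_channels)
    stop(sprintf("expected %d input channel(s), got %d",
                 spec$in_channels, dims[3]), call. = FALSE)
}

# conv (+ optional BN affine) + ReLU; returns activation and, if cache,
# what the backward pass needs. BN uses the folded inference form.
.block_conv_fwd <- function(layer, x, bn, epsilon, cache = FALSE) {
  z <- cpp_conv2d_fwd(x, layer$w, layer$b)
  if (bn) {
    eff <- bn_effective_affine(layer$gamma, layer$beta, layer$mean,
                               layer$var, epsilon)
    hw <- prod(dim(z)[1:2])
    z <- z * rep(eff$w_bn, each = hw) + rep(eff$b_bn, each = hw)
  }
  a <- z
  a[a < 0] <- 0
  if (cache) list(a = a, x = x, mask = z > 0) else list(a = a)
}

# Forward pass. Returns the sigmoid probability map; with cache = TRUE also
# every intermediate needed by .unet_backward().
.unet_forward <- function(model, x, cache = FALSE) {
  x <- as_feature_array(x)
  spec <- model$spec
  .check_geometry(spec, dim(x))
  bn <- spec$use_batchnorm
  eps <- model$bn_epsilon
  p <- model$params
  L <- spec$encoder_levels

  skips <- vector("list", L)
  enc_cache <- if (cache) vector("list", L)
  pool_arg <- if (cache) vector("list", L)
  h <- x
  for (i in seq_len(L)) {
    c1 <- .block_conv_fwd(p$encoder[[i]]$conv1, h, bn, eps, cache)
    c2 <- .block_conv_fwd(p$encoder[[i]]$conv2, c1$a, bn, eps, cache)
    skips[[i]] <- c2$a
    pooled <- cpp_maxpool2_fwd(c2$a)
    h <- pooled$out
    if (cache) {
      enc_cache[[i]] <- list(c1 = c1, c2 = c2)
      pool_arg[[i]] <- list(argmax = pooled$argmax, hw = dim(c2$a)[1:2])
    }
  }
  b1 <- .block_conv_fwd(p$bottleneck$conv1, h, bn, eps, cache)
  b2 <- .block_conv_fwd(p$bottleneck$conv2, b1$a, bn, eps, cache)
  h <- b2$a

  dec_cache <- if (cache) vector("list", L)
  for (i in rev(seq_len(L))) {
    lay <- p$decoder[[i]]
    u <- cpp_convt2_fwd(h, lay$up$w, lay$up$b)
    cat_in <- array(c(u, skips[[i]]),
                    dim = c(dim(u)[1:2], dim(u)[3] + dim(skips[[i]])[3]))
    d1 <- .block_conv_fwd(lay$conv1, cat_in, bn, eps, cache)
    d2 <- .block_conv_fwd(lay$conv2, d1$a, bn, eps, cache)
    if (cache) dec_cache[[i]] <- list(up_in = h, d1 = d1, d2 = d2,
                                      n_up = dim(u)[3])
    h <- d2$a
  }
  logits <- cpp_conv2d_fwd(h, p$head$w, p$head$b)
  prob <- plogis(logits)
  if (!cache) return(list(prob = prob))
  list(prob = prob, logits = logits, head_in = h,
       enc = enc_cache, pool = pool_arg, bott = list(b1 = b1, b2 = b2),
       dec = dec_cache)
}

# Backward through a cached block conv. g is the gradient wrt the block's
# ReLU output. Only the BN-free path is differentiated.
.block_conv_bwd <- function(layer, cc, g) {
  g <- g * cc$mask
  cpp_conv2d_bwd(cc$x, layer$w, g)
}

# Full backward pass from d(loss)/d(logits). Returns a gradient tree with
# the same structure as model$params. BN-free models only.
.unet_backward <- function(model, fw, g_logits) {
  p <- model$params
  L <- model$spec$encoder_levels
  grads <- list(encoder = vector("list", L),
                bottleneck = NULL,
                decoder = vector("list", L),
                head = NULL)

  hb <- cpp_conv2d_bwd(fw$head_in, p$head$w, g_logits)
  grads$head <- list(w = hb$gw, b = hb$gb)
  g <- hb$gx
  g_skip <- vector("list", L)

  for (i in seq_len(L)) {                # shallowest decoder stage first
    lay <- p$decoder[[i]]
    dc <- fw$dec[[i]]
    b2 <- .block_conv_bwd(lay$conv2, dc$d2, g)
    b1 <- .block_conv_bwd(lay$conv1, dc$d1, b2$gx)
    n_up <- dc$n_up
    g_cat <- b1$gx
    g_up <- g_cat[, , seq_len(n_up), drop = FALSE]
    g_skip[[i]] <- g_cat[, , n_up + seq_len(dim(g_cat)[3] - n_up),
                         drop = FALSE]
    ub <- cpp_convt2_bwd(dc$up_in, lay$up$w, g_up)
    grads$decoder[[i]] <- list(up = list(w = ub$gw, b = ub$gb),
                               conv1 = list(w = b1$gw, b = b1$gb),
                               conv2 = list(w = b2$gw, b = b2$gb))
    g <- ub$gx
  }

  b2 <- .block_conv_bwd(p$bottleneck$conv2, fw$bott$b2, g)
  b1 <- .block_conv_bwd(p$bottleneck$conv1, fw$bott$b1, b2$gx)
  grads$bottleneck <- list(conv1 = list(w = b1$gw, b = b1$gb),
                           conv2 = list(w = b2$gw, b = b2$gb))
  g <- b1$gx

  for (i in rev(seq_len(L))) {           # deepest encoder level first
    pl <- fw$pool[[i]]
    g_a <- cpp_maxpool2_bwd(g, pl$argmax, pl$hw[1], pl$hw[2]) + g_skip[[i]]
    e2 <- .block_conv_bwd(p$encoder[[i]]$conv2, fw$enc[[i]]$c2, g_a)
    e1 <- .block_conv_bwd(p$encoder[[i]]$conv1, fw$enc[[i]]$c1, e2$gx)
    grads$encoder[[i]] <- list(conv1 = list(w = e1$gw, b = e1$gb),
                               conv2 = list(w = e2$gw, b = e2$gb))
    g <- e1$gx
  }
  grads
}

#' Predict a segmentation from a model
#'
#' Runs the forward pass on one grayscale image.
#'
#' @param object a `unet_model`.
#' @param image 2-d matrix (or `H x W x 1` array) with spatial size
#'   divisible by `2^encoder_levels`.
#' @param type `"prob"` for the sigmoid probability map, `"mask"` for the
#'   thresholded binary mask.
#' @param threshold binarization threshold for `type = "mask"`.
#' @param ... unused.
#' @return matrix of probabilities in (0, 1) or a binary mask.
#' @export
predict.unet_model <- function(object, image, type = c("prob", "mask"),
                               threshold = 0.5, ...) {
  type <- match.arg(type)
  out <- .unet_forward(object, image)$prob
  out <- out[, , 1L]
  if (type == "mask") out <- (out > threshold) * 1
  out
}
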