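#' Training configuration
#'
#' The reference protocol used across all eight variants: 256x256 inputs,
#' 10 epochs, batch size 20, Adam at learning rate 1e-4, pixelwise binary
#' cross-entropy, and an 80/20 train/test split. Every source of randomness
#' (weight initialization, shuffling, splitting) derives from `seed`.
#'
#' The default learning rate is calibrated to that full-scale protocol
#' (thousands of optimizer steps). For desk-scale runs with only tens of
#' steps, scale it up accordingly (see the package vignette); the phantom
#' benchmark in [run_benchmark()] does this via its `config` argument.
#'
#' @param image_size `c(height, width)` inputs are resized to.
#' @param epochs number of passes over the training set.
#' @param batch_size images per Adam step.
#' @param optimizer only `"adam"` is implemented.
#' @param learning_rate Adam step size.
#' @param loss only `"bce"` (binary cross-entropy) is implemented.
#' @param split_fraction training fraction in (0, 1).
#' @param seed master integer seed.
#' @param device execution target; only `"cpu"` is available.
#' @return object of class `train_config`.
#' @export
train_config <- function(image_size = c(256L, 256L), epochs = 10L,
                         batch_size = 20L, optimizer = "adam",
                         learning_rate = 1e-4, loss = "bce",
                         split_fraction = 0.8, seed = 0L, device = "cpu") {
  image_size <- as.integer(rep(image_size, length.out = 2L))
  stopifnot(all(image_size >= 2L))
  epochs <- as.integer(epochs); batch_size <- as.integer(batch_size)
  if (epochs < 1L) stop("`epochs` must be >= 1", call. = FALSE)
  if (batch_size < 1L) stop("`batch_size` must be >= 1", call. = FALSE)
  if (learning_rate <= 0) stop("`learning_rate` must be positive", call. = FALSE)
  if (split_fraction <= 0 || split_fraction >= 1)
    stop("`split_fraction` must be in (0, 1)", call. = FALSE)
  optimizer <- match.arg(optimizer, "adam")
  loss <- match.arg(loss, "bce")
  structure(list(image_size = image_size, epochs = epochs,
                 batch_size = batch_size, optimizer = optimizer,
                 learning_rate = learning_rate, loss = loss,
                 split_fraction = split_fraction, seed = as.integer(seed),
                 device = device),
            class = "train_config")
}

# mean pixelwise binary cross-entropy and its gradient wrt the logits
.bce_loss <- function(prob, truth) {
  eps <- 1e-7
  p <- pmin(pmax(prob, eps), 1 - eps)
  -mean(truth * log(p) + (1 - truth) * log(1 - p))
}

#' Train a U-Net on segmentation pairs
#'
#' Minimizes mean pixelwise binary cross-entropy between the sigmoid output
#' and the binary mask with Adam (beta1 0.9, beta2 0.999, eps 1e-8).
#' Gradients are averaged over each mini-batch; the data order is reshuffled
#' every epoch from the config seed, so two runs with identical seeds give
#' identical loss histories and weights.
#'
#' @param model a `unet_model` built without batch normalization (the
#'   training path differentiates the plain conv-ReLU block).
#' @param pairs list of preprocessed [segmentation_pair()] objects whose
#'   geometry matches the model.
#' @param config a [train_config()].
#' @param verbose print the per-epoch mean training loss.
#' @return object of class `unet_fit`: list with the trained `model`,
#'   `loss_history` (one mean loss per epoch) and `config`.
#' @export
train_model <- function(model, pairs, config = train_config(),
                        verbose = FALSE) {
  stopifnot(inherits(model, "unet_model"), inherits(config, "train_config"))
  if (model$spec$use_batchnorm)
    stop("training is implemented for batchnorm-free models only",
         call. = FALSE)
  if (length(pairs) == 0L) stop("no training pairs", call. = FALSE)
  for (p in pairs) .check_geometry(model$spec, c(dim(p$image), 1L))

  params <- model$params
  m <- tree_map(function(x) array(0, dim = dim(x) %||% length(x)), params)
  v <- m
  b1 <- 0.9; b2 <- 0.999; aeps <- 1e-8
  lr <- config$learning_rate
  step <- 0L
  n <- length(pairs)
  loss_history <- numeric(config$epochs)

  with_local_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (start in seq(1L, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n)]
        gsum <- NULL
        bl <- 0
        for (j in idx) {
          pr <- pairs[[j]]
          model$params <- params
          fw <- .unet_forward(model, pr$image, cache = TRUE)
          truth <- array(pr$mask, dim = dim(fw$prob))
          bl <- bl + .bce_loss(fw$prob, truth)
          g_logits <- (fw$prob - truth) / length(truth)
          g <- .unet_backward(model, fw, g_logits)
          gsum <- if (is.null(gsum)) g else tree_map(`+`, gsum, g)
        }
        nb <- length(idx)
        grad <- tree_map(function(x) x / nb, gsum)
        step <- step + 1L
        m <- tree_map(function(mm, gg) b1 * mm + (1 - b1) * gg, m, grad)
        v <- tree_map(function(vv, gg) b2 * vv + (1 - b2) * gg^2, v, grad)
        corr <- lr * sqrt(1 - b2^step) / (1 - b1^step)
        params <- tree_map(function(p, mm, vv) p - corr * mm / (sqrt(vv) + aeps),
                           params, m, v)
        bl <- bl / nb
        if (!is.finite(bl))
          stop(sprintf("non-finite training loss at epoch %d", epoch),
               call. = FALSE)
        ep_loss <- ep_loss + bl * nb
      }
      loss_history[epoch] <- ep_loss / n
      if (verbose)
        message(sprintf("epoch %d/%d: loss %.5f", epoch, config$epochs,
                        loss_history[epoch]))
    }
  })
  model$params <- params
  structure(list(model = model, loss_history = loss_history, config = config),
            class = "unet_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.unet_fit <- function(x, ...) {
  cat(sprintf("<unet_fit> %s: %d epoch(s), final loss %.5f\n",
              x$model$spec$name, length(x$loss_history),
              x$loss_history[length(x$loss_history)]))
  invisible(x)
}
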