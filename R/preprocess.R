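#' Construct an image/mask segmentation pair
#'
#' Bundles one grayscale image with its binary segmentation mask and checks
#' their shared geometry. Images are stored as doubles in \[0, 1\]; masks as
#' 0/1.
#'
#' @param image 2-d numeric matrix with values in \[0, 1\].
#' @param mask 2-d binary matrix of the same size.
#' @param id identifier string.
#' @param class_label one of `"COVID"`, `"Normal"`, `"Viral Pneumonia"`,
#'   `"synthetic"`.
#' @return object of class `segmentation_pair`.
#' @export
segmentation_pair <- function(image, mask, id = "pair",
                              class_label = "synthetic") {
  image <- as.matrix(image); mask <- as.matrix(mask)
  if (length(image) == 0L) stop("empty image", call. = FALSE)
  if (!identical(dim(image), dim(mask)))
    stop("image and mask must have identical height and width", call. = FALSE)
  if (any(image < 0 | image > 1))
    stop("image intensities must lie in [0, 1]", call. = FALSE)
  if (!all(mask %in% c(0, 1)))
    stop("mask must be binary", call. = FALSE)
  structure(list(image = image, mask = mask, id = as.character(id),
                 class_label = class_label),
            class = "segmentation_pair")
}

#' @export
print.segmentation_pair <- function(x, ...) {
  cat(sprintf("<segmentation_pair> %s [%s]: %dx%d, foreground %.1f%%\n",
              x$id, x$class_label, nrow(x$image), ncol(x$image),
              100 * mean(x$mask)))
  invisible(x)
}

#' Resize an image/mask pair
#'
#' Resamples the image with bilinear interpolation and the mask with
#' nearest-neighbor (then re-binarizes), so mask values stay exactly 0/1.
#' Resampling is delegated to \pkg{EBImage}; a same-size request returns
#' the pair unchanged.
#'
#' @param pair a [segmentation_pair()].
#' @param size target `c(height, width)` (a scalar is used for both).
#' @return the resized `segmentation_pair`.
#' @export
resize_pair <- function(pair, size) {
  stopifnot(inherits(pair, "segmentation_pair"))
  size <- as.integer(rep(size, length.out = 2L))
  if (any(size < 1L)) stop("target size must be positive", call. = FALSE)
  if (identical(dim(pair$image), size)) return(pair)
  img <- EBImage::resize(pair$image, w = size[1], h = size[2],
                         filter = "bilinear")
  img <- pmin(pmax(img, 0), 1)  # bilinear stays in hull; guard fp round-off
  msk <- EBImage::resize(pair$mask, w = size[1], h = size[2],
                         filter = "none")
  segmentation_pair(img, binarize_mask(msk), pair$id, pair$class_label)
}

#' Discretized Gaussian kernel
#'
#' Evaluates \eqn{\exp(-(i^2 + j^2) / (2\sigma^2))} on an odd integer grid
#' centred at zero and normalizes to unit sum.
#'
#' @param size odd kernel side length.
#' @param sigma positive standard deviation in pixels.
#' @return `size x size` matrix with non-negative entries summing to 1.
#' @export
gaussian_kernel <- function(size = 3L, sigma = 0.5) {
  size <- as.integer(size)
  if (size < 1L || size %% 2L == 0L)
    stop("kernel size must be a positive odd integer", call. = FALSE)
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  r <- (size - 1L) / 2L
  g <- outer(-r:r, -r:r, function(i, j) exp(-(i^2 + j^2) / (2 * sigma^2)))
  g / sum(g)
}

#' Gaussian denoising of a grayscale image
#'
#' Convolves the image with the discretized, sum-normalized Gaussian kernel
#' of [gaussian_kernel()]; borders are handled by edge replication so the
#' output range never leaves the input range. The radiograph protocol uses
#' a 3x3 kernel with \eqn{\sigma = 0.5}.
#'
#' @param image 2-d numeric matrix.
#' @param kernel odd kernel size (default 3).
#' @param sigma standard deviation in pixels (default 0.5).
#' @return denoised matrix of the same size.
#' @export
gaussian_denoise <- function(image, kernel = 3L, sigma = 0.5) {
  image <- as.matrix(image)
  if (length(image) == 0L) stop("empty image", call. = FALSE)
  g <- gaussian_kernel(kernel, sigma)
  r <- (as.integer(kernel) - 1L) / 2L
  H <- nrow(image); W <- ncol(image)
  # edge-replicated pad
  ri <- pmin(pmax(seq_len(H + 2L * r) - r, 1L), H)
  ci <- pmin(pmax(seq_len(W + 2L * r) - r, 1L), W)
  xp <- image[ri, ci, drop = FALSE]
  out <- matrix(0, H, W)
  for (a in seq_len(2L * r + 1L)) {
    for (b in seq_len(2L * r + 1L)) {
      out <- out + g[a, b] * xp[(a - 1L) + seq_len(H), (b - 1L) + seq_len(W),
                                drop = FALSE]
    }
  }
  out
}

#' Histogram equalization with min-max scaling
#'
#' Maps each intensity to its normalized empirical cumulative frequency and
#' rescales so the output spans exactly \[0, 1\]:
#' \eqn{y = (F(x) - F_{min}) / (1 - F_{min})} with \eqn{F} the empirical
#' CDF of the pixel values. For 8-bit data this is 256-level histogram
#' equalization. The mapping is monotone (rank order is preserved) and
#' exactly idempotent. A constant image has no contrast to spread and is
#' returned as all zeros with a warning.
#'
#' @param image 2-d numeric matrix.
#' @return matrix with values in \[0, 1\]; min 0 and max 1 unless the input
#'   was constant.
#' @export
normalize_intensity <- function(image) {
  image <- as.matrix(image)
  if (length(image) == 0L) stop("empty image", call. = FALSE)
  vals <- sort(unique(as.vector(image)))
  if (length(vals) == 1L) {
    warning("constant image: no contrast to equalize; returning zeros",
            call. = FALSE)
    return(matrix(0, nrow(image), ncol(image)))
  }
  counts <- tabulate(match(as.vector(image), vals), nbins = length(vals))
  cdf <- cumsum(counts) / length(image)
  lut <- (cdf - cdf[1]) / (1 - cdf[1])
  matrix(lut[match(as.vector(image), vals)], nrow(image), ncol(image))
}

#' Binarize a mask array
#'
#' Thresholds at a fraction of the value range: entries above
#' `threshold * max_range` become 1, the rest 0. The range is taken as 255
#' for 8-bit-coded inputs (maximum above 1) and 1 otherwise, so both raw
#' 8-bit PNG values and already-normalized masks binarize correctly.
#'
#' @param mask 2-d numeric matrix.
#' @param threshold fraction of the value range in (0, 1); default 0.5.
#' @return binary matrix. An all-zero result triggers an empty-foreground
#'   warning.
#' @export
binarize_mask <- function(mask, threshold = 0.5) {
  mask <- as.matrix(mask)
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must be in (0, 1)", call. = FALSE)
  rng <- if (max(mask) > 1) 255 else 1
  out <- (mask > threshold * rng) * 1
  if (all(out == 0)) warning("binarized mask has empty foreground",
                             call. = FALSE)
  out
}

#' Full preprocessing chain for one pair
#'
#' Applies the radiograph conditioning protocol in order: resize (bilinear
#' image, nearest mask), Gaussian denoise, histogram equalization; the mask
#' is re-binarized after resizing.
#'
#' @param pair a [segmentation_pair()].
#' @param size target `c(height, width)`.
#' @param kernel,sigma Gaussian denoising parameters.
#' @return the preprocessed `segmentation_pair`.
#' @export
preprocess_pair <- function(pair, size = c(256L, 256L), kernel = 3L,
                            sigma = 0.5) {
  pair <- resize_pair(pair, size)
  img <- gaussian_denoise(pair$image, kernel, sigma)
  img <- normalize_intensity(img)
  segmentation_pair(img, pair$mask, pair$id, pair$class_label)
}
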