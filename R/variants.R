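#' Declare a U-Net variant configuration
#'
#' A variant spec describes one member of the U-Net family declaratively:
#' the number of contracting (encoder) stages, how channel width evolves
#' with depth, and the kernel geometry. Two width modes exist:
#' \describe{
#'   \item{`doubling`}{classic U-Net schedule: level \eqn{i} carries
#'     `initial_filters`\eqn{\cdot 2^{i-1}} channels and the bottleneck
#'     `initial_filters`\eqn{\cdot 2^{L}}.}
#'   \item{`fixed`}{every level and the bottleneck carry `fixed_filters`
#'     channels; depth stays constant while width is varied.}
#' }
#' The conventional "layer count" of a variant (the number its name carries)
#' is `2 * encoder_levels + 1`: two stage rows per resolution plus the
#' bottleneck.
#'
#' @param name identifier for reports.
#' @param encoder_levels number of contracting stages (excludes the
#'   bottleneck); at least 1.
#' @param width_mode `"doubling"` or `"fixed"`.
#' @param initial_filters channels at the shallowest level (doubling mode).
#' @param fixed_filters channels at every level (fixed mode).
#' @param in_channels,out_channels image and mask channels (both 1 for
#'   grayscale radiographs and binary lung masks).
#' @param use_batchnorm add batch-normalization parameters to every block
#'   convolution. Off in the reference configurations.
#' @param conv_kernel spatial size of the (odd, square) block convolutions.
#' @param up_kernel spatial size of the stride-2 transposed-convolution
#'   upsampler; only 2 is supported.
#' @return an object of class `variant_spec`.
#' @seealso [resolve_variant()] for the eight reference configurations,
#'   [build_unet()], [closed_form_param_count()].
#' @export
variant_spec <- function(name = "custom",
                         encoder_levels,
                         width_mode = c("doubling", "fixed"),
                         initial_filters = NULL,
                         fixed_filters = NULL,
                         in_channels = 1L,
                         out_channels = 1L,
                         use_batchnorm = FALSE,
                         conv_kernel = 3L,
                         up_kernel = 2L) {
  width_mode <- match.arg(width_mode)
  encoder_levels <- as.integer(encoder_levels)
  if (is.na(encoder_levels) || encoder_levels < 1L)
    stop("`encoder_levels` must be an integer >= 1", call. = FALSE)
  if (width_mode == "doubling") {
    if (is.null(initial_filters) || initial_filters < 1L)
      stop("doubling mode requires `initial_filters` >= 1", call. = FALSE)
    initial_filters <- as.integer(initial_filters)
  } else {
    if (is.null(fixed_filters) || fixed_filters < 1L)
      stop("fixed mode requires `fixed_filters` >= 1", call. = FALSE)
    fixed_filters <- as.integer(fixed_filters)
  }
  if (in_channels < 1L || out_channels < 1L)
    stop("channel counts must be >= 1", call. = FALSE)
  conv_kernel <- as.integer(conv_kernel)
  if (conv_kernel < 1L || conv_kernel %% 2L == 0L)
    stop("`conv_kernel` must be odd (same padding)", call. = FALSE)
  if (as.integer(up_kernel) != 2L)
    stop("only 2x2 stride-2 transposed-convolution upsampling is supported",
         call. = FALSE)
  structure(
    list(name = name,
         encoder_levels = encoder_levels,
         width_mode = width_mode,
         initial_filters = initial_filters,
         fixed_filters = fixed_filters,
         in_channels = as.integer(in_channels),
         out_channels = as.integer(out_channels),
         use_batchnorm = isTRUE(use_batchnorm),
         conv_kernel = conv_kernel,
         up_kernel = 2L),
    class = "variant_spec")
}

#' @export
print.variant_spec <- function(x, ...) {
  cat(sprintf("<variant_spec> %s: %d encoder levels (%d layers), %s width\n",
              x$name, x$encoder_levels, layer_count(x), x$width_mode))
  ch <- level_channels(x)
  cat(sprintf("  channels: %s | bottleneck %d | in %d -> out %d%s\n",
              paste(ch$levels, collapse = "-"), ch$bottleneck,
              x$in_channels, x$out_channels,
              if (x$use_batchnorm) " | batchnorm" else ""))
  invisible(x)
}

#' Conventional layer count of a variant
#'
#' `2 * encoder_levels + 1`: the count the family names refer to
#' (U-Net7 has 3 encoder levels, U-Net9 has 4, ...).
#'
#' @param spec a [variant_spec()].
#' @return integer layer count.
#' @export
layer_count <- function(spec) {
  stopifnot(inherits(spec, "variant_spec"))
  2L * spec$encoder_levels + 1L
}

# Channel schedule: encoder level channels and bottleneck channels.
level_channels <- function(spec) {
  L <- spec$encoder_levels
  if (spec$width_mode == "doubling") {
    list(levels = spec$initial_filters * 2L^(0:(L - 1L)),
         bottleneck = spec$initial_filters * 2L^L)
  } else {
    list(levels = rep(spec$fixed_filters, L),
         bottleneck = spec$fixed_filters)
  }
}

.variant_registry <- function() {
  list(
    "u-net7"   = list(encoder_levels = 3L, width_mode = "doubling", initial_filters = 64L),
    "u-net9"   = list(encoder_levels = 4L, width_mode = "doubling", initial_filters = 32L),
    "u-net11"  = list(encoder_levels = 5L, width_mode = "doubling", initial_filters = 16L),
    "u-net13"  = list(encoder_levels = 6L, width_mode = "doubling", initial_filters = 8L),
    "u-net16"  = list(encoder_levels = 4L, width_mode = "fixed", fixed_filters = 16L),
    "u-net32"  = list(encoder_levels = 4L, width_mode = "fixed", fixed_filters = 32L),
    "u-net64"  = list(encoder_levels = 4L, width_mode = "fixed", fixed_filters = 64L),
    "u-net128" = list(encoder_levels = 4L, width_mode = "fixed", fixed_filters = 128L)
  )
}

#' Names of the eight reference variants
#' @return character vector of variant names.
#' @export
variant_names <- function() {
  c("U-Net7", "U-Net9", "U-Net11", "U-Net13",
    "U-Net16", "U-Net32", "U-Net64", "U-Net128")
}

#' Look up a reference U-Net variant
#'
#' Returns the reference configuration of one of the eight family members.
#' The depth variants U-Net7/9/11/13 use 3/4/5/6 encoder levels with a
#' doubling schedule starting at 64/32/16/8 filters; the width variants
#' U-Net16/32/64/128 share the 9-layer layout (4 encoder levels) with a
#' uniform filter count of 16/32/64/128. All reference configurations use
#' 1-channel input and output, 3x3 block convolutions, 2x2 transposed-conv
#' upsampling, and no batch normalization.
#'
#' @param name variant name, case-insensitive (e.g. `"U-Net9"`, `"u-net16"`).
#' @return a [variant_spec()].
#' @examples
#' resolve_variant("U-Net16")
#' @export
resolve_variant <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  key <- tolower(trimws(name))
  reg <- .variant_registry()
  if (!key %in% names(reg)) {
    stop(sprintf("unsupported variant '%s'; valid names: %s", name,
                 paste(variant_names(), collapse = ", ")), call. = FALSE)
  }
  cfg <- reg[[key]]
  variant_spec(name = variant_names()[match(key, names(reg))],
               encoder_levels = cfg$encoder_levels,
               width_mode = cfg$width_mode,
               initial_filters = cfg$initial_filters,
               fixed_filters = cfg$fixed_filters)
}

#' Closed-form parameter count of a variant
#'
#' Pure-arithmetic audit of the total number of scalar parameters of the
#' network [build_unet()] constructs, computed without building it: each
#' convolution contributes \eqn{c_{in} c_{out} k^2 + c_{out}} (weights plus
#' bias) with \eqn{k} the block kernel, the 2x2 upsampler kernel, or 1 for
#' the output head. With batch normalization enabled each block convolution
#' additionally carries \eqn{4 c_{out}} values (scale, shift, mean,
#' variance). Serves as the independent oracle for [count_parameters()].
#'
#' @param spec a [variant_spec()] or a variant name accepted by
#'   [resolve_variant()].
#' @return integer-valued parameter count (as a double; counts exceed
#'   `.Machine$integer.max` for no reference variant, but custom specs may).
#' @examples
#' closed_form_param_count("U-Net16")  # 52993
#' @export
closed_form_param_count <- function(spec) {
  if (is.character(spec)) spec <- resolve_variant(spec)
  stopifnot(inherits(spec, "variant_spec"))
  k <- spec$conv_kernel
  bn <- spec$use_batchnorm
  conv <- function(cin, cout, ksize = k, with_bn = bn) {
    cin * cout * ksize^2 + cout + if (with_bn) 4 * cout else 0
  }
  ch <- level_channels(spec)
  L <- spec$encoder_levels
  total <- 0
  prev <- spec$in_channels
  for (i in seq_len(L)) {                 # encoder: two convs per level
    total <- total + conv(prev, ch$levels[i]) + conv(ch$levels[i], ch$levels[i])
    prev <- ch$levels[i]
  }
  total <- total + conv(prev, ch$bottleneck) + conv(ch$bottleneck, ch$bottleneck)
  up_in <- ch$bottleneck
  for (i in rev(seq_len(L))) {            # decoder: upsample, concat, two convs
    ci <- ch$levels[i]
    total <- total + conv(up_in, ci, ksize = spec$up_kernel, with_bn = FALSE)
    total <- total + conv(2 * ci, ci) + conv(ci, ci)
    up_in <- ci
  }
  total + conv(up_in, spec$out_channels, ksize = 1L, with_bn = FALSE)
}
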