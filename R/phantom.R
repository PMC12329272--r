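#' Parameters for synthetic chest-phantom generation
#'
#' Describes the geometry and photometry of a chest-radiograph-like phantom:
#' a bright thoracic background, two darker ellipse-shaped lung fields
#' (elongated vertically), sinusoidal rib-like stripes, and additive
#' Gaussian noise. The ground-truth mask is the exact union of the two lung
#' ellipses. Defaults emulate typical posteroanterior radiograph proportions
#' (lungs covering roughly 15-35% of the frame with strong lung/background
#' contrast); the `"easy"` preset removes ribs and noise for desk-scale
#' learnability runs.
#'
#' @param size image `c(height, width)` in pixels.
#' @param lung_axes_range min/max horizontal semi-axis of a lung as a
#'   fraction of image width.
#' @param lung_eccentricity vertical elongation factor (vertical semi-axis =
#'   eccentricity * horizontal).
#' @param rib_count number of rib-like stripe periods over the image height.
#' @param rib_amplitude intensity amplitude of the stripes.
#' @param noise_sigma standard deviation of additive Gaussian noise.
#' @param background_level base thoracic intensity in \[0, 1\].
#' @param lung_contrast intensity drop inside the lung fields.
#' @param seed integer seed; identical parameters and seed give identical
#'   phantoms.
#' @param preset `"default"` or `"easy"` (no ribs, no noise, contrast 0.5).
#' @return object of class `phantom_params`.
#' @export
phantom_params <- function(size = c(256L, 256L),
                           lung_axes_range = c(0.12, 0.18),
                           lung_eccentricity = 1.6,
                           rib_count = 7L,
                           rib_amplitude = 0.05,
                           noise_sigma = 0.03,
                           background_level = 0.85,
                           lung_contrast = 0.45,
                           seed = 0L,
                           preset = c("default", "easy")) {
  preset <- match.arg(preset)
  if (preset == "easy") {
    if (missing(rib_amplitude)) rib_amplitude <- 0
    if (missing(noise_sigma)) noise_sigma <- 0
    if (missing(lung_contrast)) lung_contrast <- 0.5
  }
  size <- as.integer(rep(size, length.out = 2L))
  stopifnot(all(size >= 8L), length(lung_axes_range) == 2L,
            lung_axes_range[1] > 0, diff(lung_axes_range) >= 0,
            lung_eccentricity > 0, rib_count >= 0, rib_amplitude >= 0,
            noise_sigma >= 0, background_level >= 0, background_level <= 1,
            lung_contrast > 0)
  structure(list(size = size, lung_axes_range = lung_axes_range,
                 lung_eccentricity = lung_eccentricity,
                 rib_count = as.integer(rib_count),
                 rib_amplitude = rib_amplitude, noise_sigma = noise_sigma,
                 background_level = background_level,
                 lung_contrast = lung_contrast, seed = as.integer(seed)),
            class = "phantom_params")
}

#' Generate one chest phantom with its ground-truth lung mask
#'
#' Draws lung semi-axes and small center jitters from the seeded RNG, paints
#' the two lung ellipses darker than the background, overlays sinusoidal
#' rib stripes and Gaussian noise, and clips to \[0, 1\]. The returned mask
#' is the exact lung indicator. The global RNG state is left untouched.
#'
#' @param params a [phantom_params()].
#' @return a [segmentation_pair()] with `class_label = "synthetic"`.
#' @export
generate_phantom <- function(params = phantom_params()) {
  stopifnot(inherits(params, "phantom_params"))
  with_local_seed(params$seed, .render_phantom(params))
}

.render_phantom <- function(params) {
  H <- params$size[1]; W <- params$size[2]
  ax <- runif(2L, params$lung_axes_range[1], params$lung_axes_range[2]) * W
  jx <- runif(2L, -0.015, 0.015) * W
  jy <- runif(2L, -0.02, 0.02) * H
  cx <- c(0.28, 0.72) * W + jx
  cy <- 0.52 * H + jy
  a_v <- params$lung_eccentricity * ax    # vertical semi-axes

  if ((cx[2] - ax[2]) - (cx[1] + ax[1]) < 1)
    stop("lung axes too large to place two disjoint lung fields",
         call. = FALSE)
  if (any(cx - ax < 0) || any(cx + ax > W) || any(cy - a_v < 0) ||
      any(cy + a_v > H))
    stop("lung axes too large for the image frame", call. = FALSE)

  ii <- matrix(seq_len(H), H, W)          # row = vertical coordinate
  jj <- matrix(seq_len(W), H, W, byrow = TRUE)
  mask <- matrix(0, H, W)
  for (l in 1:2) {
    inside <- ((jj - cx[l]) / ax[l])^2 + ((ii - cy[l]) / a_v[l])^2 <= 1
    mask[inside] <- 1
  }
  fg <- mean(mask)
  if (fg < 0.05 || fg > 0.6)
    stop(sprintf("foreground fraction %.3f outside [0.05, 0.6]; adjust lung axes",
                 fg), call. = FALSE)

  img <- params$background_level - params$lung_contrast * mask
  if (params$rib_amplitude > 0 && params$rib_count > 0)
    img <- img + params$rib_amplitude *
      sin(2 * pi * params$rib_count * ii / H)
  if (params$noise_sigma > 0)
    img <- img + matrix(rnorm(H * W, sd = params$noise_sigma), H, W)
  img <- pmin(pmax(img, 0), 1)
  segmentation_pair(img, mask, id = sprintf("phantom_seed%d", params$seed),
                    class_label = "synthetic")
}

#' Write a synthetic phantom dataset in the radiograph directory layout
#'
#' Generates `n` phantoms with deterministic per-item seeds derived from the
#' master seed (so item `i` is the same regardless of `n`) and writes 8-bit
#' grayscale PNGs under `<class>/images/` and `<class>/masks/` with matching
#' stems, mirroring the public chest-radiograph dataset layout. Classes are
#' assigned round-robin.
#'
#' @param n number of pairs (>= 1).
#' @param params a [phantom_params()]; its `seed` is the master seed.
#' @param out_dir output directory (created if needed). `NULL` skips
#'   writing files and returns the manifest with in-memory pairs attached.
#' @param class_labels class subdirectories to cycle through.
#' @return manifest data.frame: `id`, `class`, `image_path`, `mask_path`,
#'   `foreground_fraction`. When `out_dir` is `NULL` the pairs are attached
#'   as attribute `"pairs"`.
#' @export
generate_dataset <- function(n, params = phantom_params(), out_dir = NULL,
                             class_labels = c("COVID", "Normal",
                                              "Viral Pneumonia")) {
  stopifnot(n >= 1)
  n <- as.integer(n)
  write_files <- !is.null(out_dir)
  if (write_files) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(out_dir))
      stop(sprintf("cannot create output directory '%s'", out_dir),
           call. = FALSE)
    for (cl in class_labels) {
      dir.create(file.path(out_dir, cl, "images"), recursive = TRUE,
                 showWarnings = FALSE)
      dir.create(file.path(out_dir, cl, "masks"), recursive = TRUE,
                 showWarnings = FALSE)
    }
  }
  ids <- sprintf("phantom_%04d", seq_len(n))
  classes <- rep_len(class_labels, n)
  fg <- numeric(n)
  img_paths <- character(n); msk_paths <- character(n)
  pairs <- if (!write_files) vector("list", n)
  for (i in seq_len(n)) {
    pi <- params
    pi$seed <- derive_seed(params$seed, i)
    pair <- generate_phantom(pi)
    pair$id <- ids[i]; pair$class_label <- classes[i]
    fg[i] <- mean(pair$mask)
    if (write_files) {
      img_paths[i] <- file.path(out_dir, classes[i], "images",
                                paste0(ids[i], ".png"))
      msk_paths[i] <- file.path(out_dir, classes[i], "masks",
                                paste0(ids[i], ".png"))
      png::writePNG(pair$image, img_paths[i])
      png::writePNG(pair$mask, msk_paths[i])
    } else {
      pairs[[i]] <- pair
    }
  }
  manifest <- data.frame(id = ids, class = classes,
                         image_path = img_paths, mask_path = msk_paths,
                         foreground_fraction = fg,
                         stringsAsFactors = FALSE)
  if (write_files) {
    write.csv(manifest, file.path(out_dir, "manifest.csv"),
              row.names = FALSE)
  } else {
    attr(manifest, "pairs") <- pairs
  }
  manifest
}
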