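#' Read one image/mask PNG pair
#'
#' Reads grayscale PNGs (color images are collapsed by channel mean), and
#' binarizes the mask at half range so anti-aliased 8-bit masks come out
#' exactly 0/1.
#'
#' @param image_path,mask_path PNG file paths.
#' @param id identifier; defaults to the image file stem.
#' @param class_label class of the pair.
#' @return a [segmentation_pair()].
#' @export
read_pair <- function(image_path, mask_path, id = NULL,
                      class_label = "synthetic") {
  img <- .read_gray_png(image_path)
  msk <- binarize_mask(.read_gray_png(mask_path))
  if (is.null(id)) id <- sub("\\.png$", "", basename(image_path))
  segmentation_pair(img, msk, id, class_label)
}

.read_gray_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- apply(x[, , seq_len(min(3L, dim(x)[3])),
                                        drop = FALSE], c(1, 2), mean)
  x
}

#' Load a dataset directory into a manifest
#'
#' Scans the `<class>/images/*.png` + `<class>/masks/*.png` layout (every
#' image must have a same-named mask). If a `manifest.csv` written by
#' [generate_dataset()] is present it is used directly.
#'
#' @param dir dataset root directory.
#' @return manifest data.frame with `id`, `class`, `image_path`,
#'   `mask_path`.
#' @export
load_manifest <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  if (file.exists(mf)) {
    m <- read.csv(mf, stringsAsFactors = FALSE)
    m$image_path <- ifelse(file.exists(m$image_path), m$image_path,
                           file.path(dir, m$class, "images",
                                     paste0(m$id, ".png")))
    m$mask_path <- ifelse(file.exists(m$mask_path), m$mask_path,
                          file.path(dir, m$class, "masks",
                                    paste0(m$id, ".png")))
    return(m)
  }
  classes <- list.dirs(dir, recursive = FALSE, full.names = FALSE)
  rows <- list()
  for (cl in classes) {
    imgs <- sort(list.files(file.path(dir, cl, "images"), "\\.png$",
                            full.names = TRUE))
    if (length(imgs) == 0L) next
    ids <- sub("\\.png$", "", basename(imgs))
    msks <- file.path(dir, cl, "masks", paste0(ids, ".png"))
    missing <- !file.exists(msks)
    if (any(missing))
      stop(sprintf("missing mask(s) for: %s",
                   paste(ids[missing], collapse = ", ")), call. = FALSE)
    rows[[cl]] <- data.frame(id = ids, class = cl, image_path = imgs,
                             mask_path = msks, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    stop(sprintf("no <class>/images/*.png found under '%s'", dir),
         call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a side-by-side actual/predicted mask panel
#'
#' Composes `[image | truth | prediction]` horizontally with thin white
#' separators and writes an 8-bit grayscale PNG, for visual comparison of
#' segmentations.
#'
#' @param pair a [segmentation_pair()] (ground truth).
#' @param pred predicted binary mask of the same size.
#' @param path output PNG path.
#' @return the path, invisibly.
#' @export
write_panel <- function(pair, pred, path) {
  stopifnot(inherits(pair, "segmentation_pair"))
  sep <- matrix(1, nrow(pair$image), 2L)
  panel <- cbind(pair$image, sep, pair$mask, sep, as.matrix(pred))
  png::writePNG(pmin(pmax(panel, 0), 1), path)
  invisible(path)
}
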