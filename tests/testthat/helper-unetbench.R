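# shared fixtures and independent oracles, built in code at test time

# smallest non-trivial doubling spec; hand-auditable
toy_spec <- function(levels = 1L, filters = 2L, bn = FALSE) {
  variant_spec("toy", encoder_levels = levels, width_mode = "doubling",
               initial_filters = filters, use_batchnorm = bn)
}

# in-memory easy phantom pairs at a given size, already preprocessed
make_easy_pairs <- function(n, size = 64L, seed = 0L) {
  man <- generate_dataset(n, phantom_params(size = size, preset = "easy",
                                            seed = seed))
  pairs <- lapply(attr(man, "pairs"), preprocess_pair, size = size)
  names(pairs) <- man$id
  list(manifest = man, pairs = pairs)
}

# brute-force IoU/Dice from raw set definitions (independent of the
# count-based implementation)
oracle_overlap <- function(pred, truth) {
  p <- which(pred == 1); t <- which(truth == 1)
  inter <- length(intersect(p, t)); union <- length(union(p, t))
  list(iou = if (union == 0) 1 else inter / union,
       dice = if (length(p) + length(t) == 0) 1
              else 2 * inter / (length(p) + length(t)))
}

# naive O(H W k^2 C) same-padding convolution, independent of the GEMM path
naive_conv2d <- function(x, w, b) {
  k <- dim(w)[1]; cin <- dim(w)[3]; cout <- dim(w)[4]
  H <- dim(x)[1]; W <- dim(x)[2]; p <- (k - 1) / 2
  out <- array(0, dim = c(H, W, cout))
  for (co in seq_len(cout)) {
    acc <- matrix(b[co], H, W)
    for (ci in seq_len(cin)) for (a in 1:k) for (bb in 1:k) {
      for (i in 1:H) for (j in 1:W) {
        si <- i + a - 1 - p; sj <- j + bb - 1 - p
        if (si >= 1 && si <= H && sj >= 1 && sj <= W)
          acc[i, j] <- acc[i, j] + w[a, bb, ci, co] * x[si, sj, ci]
      }
    }
    out[, , co] <- acc
  }
  out
}

random_small_spec <- function() {
  mode <- sample(c("doubling", "fixed"), 1)
  variant_spec("rand",
               encoder_levels = sample(1:4, 1),
               width_mode = mode,
               initial_filters = if (mode == "doubling") sample(1:16, 1),
               fixed_filters = if (mode == "fixed") sample(1:16, 1),
               in_channels = sample(1:3, 1),
               out_channels = sample(1:2, 1),
               use_batchnorm = FALSE)
}
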