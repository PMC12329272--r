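# internal helpers

# Run `expr` under a temporary RNG seed, restoring (or removing) the global
# .Random.seed afterwards so generators stay pure.
with_local_seed <- function(seed, expr) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Deterministic per-item seed derived from a master seed; keeps values in
# [0, 2^31) so they are valid R integer seeds.
derive_seed <- function(master_seed, index) {
  as.integer((as.numeric(master_seed) * 7919 + as.numeric(index) * 104729) %%
               2147483629)
}

# Map f over parallel lists with identical nesting (parameters, gradients,
# optimiser state). Leaves are numeric arrays.
tree_map <- function(f, ...) {
  trees <- list(...)
  t1 <- trees[[1L]]
  if (is.list(t1)) {
    out <- vector("list", length(t1))
    names(out) <- names(t1)
    for (i in seq_along(t1)) {
      out[[i]] <- do.call(tree_map, c(list(f), lapply(trees, `[[`, i)))
    }
    out
  } else {
    do.call(f, trees)
  }
}

# Sum of leaf lengths of a parameter tree.
tree_length <- function(tree) {
  if (is.list(tree)) sum(vapply(tree, tree_length, numeric(1))) else length(tree)
}

as_feature_array <- function(x) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  stopifnot(is.array(x), length(dim(x)) == 3L)
  storage.mode(x) <- "double"
  x
}
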