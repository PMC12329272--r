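#' Seeded train/test split of a dataset manifest
#'
#' Partitions the manifest into disjoint, exhaustive train and test id sets
#' with a reproducible seeded shuffle. Unstratified, the train set holds
#' `floor(fraction * n)` items. Stratified (the default when a `class`
#' column is present), the split is applied within each class and a
#' fractional remainder stays in the training set.
#'
#' @param manifest data.frame with an `id` column (and `class` when
#'   stratifying).
#' @param fraction training fraction in (0, 1); 0.8 in the reference
#'   protocol.
#' @param seed integer seed for the shuffle.
#' @param stratify split within each class.
#' @return list with character vectors `train` and `test`.
#' @examples
#' m <- data.frame(id = as.character(1:100))
#' s <- split_dataset(m, 0.8, seed = 1, stratify = FALSE)
#' lengths(s)  # 80 / 20
#' @export
split_dataset <- function(manifest, fraction = 0.8, seed = 0L,
                          stratify = TRUE) {
  stopifnot(is.data.frame(manifest), "id" %in% names(manifest))
  if (nrow(manifest) == 0L) stop("empty manifest", call. = FALSE)
  if (fraction <= 0 || fraction >= 1)
    stop("`fraction` must be in (0, 1)", call. = FALSE)
  if (stratify && !"class" %in% names(manifest))
    stop("stratified split needs a `class` column", call. = FALSE)
  ids <- as.character(manifest$id)
  with_local_seed(seed, {
    # tiny epsilon guards floor() against binary round-off (0.2 * 30 -> 5.999...)
    if (!stratify) {
      ord <- sample(ids)
      n_train <- floor(fraction * length(ids) + 1e-9)
      train <- ord[seq_len(n_train)]
    } else {
      strata <- split(ids, manifest$class)
      sizes <- lengths(strata)
      if (any(sizes < 2L))
        stop(sprintf("stratum with fewer than 2 items: %s",
                     paste(names(strata)[sizes < 2L], collapse = ", ")),
             call. = FALSE)
      train <- unlist(lapply(strata, function(s) {
        ord <- sample(s)
        n_test <- floor((1 - fraction) * length(s) + 1e-9)
        ord[seq_len(length(s) - n_test)]
      }), use.names = FALSE)
    }
    list(train = train, test = setdiff(ids, train))
  })
}

.metric_rows <- function(variant, process, report) {
  data.frame(model = variant, process = process,
             dice_micro = report$micro_dice, iou_micro = report$micro_iou,
             dice_macro = report$macro_dice, iou_macro = report$macro_iou,
             stringsAsFactors = FALSE)
}

.evaluate_split <- function(model, pairs, threshold = 0.5) {
  evaluate_dataset(lapply(pairs, function(p) {
    list(pred = predict(model, p$image, type = "mask", threshold = threshold),
         truth = p$mask, id = p$id)
  }))
}

#' Run the variant benchmark end to end
#'
#' For each requested variant: resolve the reference spec, audit its
#' parameter count against the closed-form oracle, train on the training
#' split, evaluate Dice and IoU (micro and macro) on both splits, and write
#' comparison reports. The dataset is read from the `<class>/images|masks`
#' directory layout, preprocessed (resize, Gaussian denoise, histogram
#' equalization), and split stratified by class. Everything derives from
#' `config$seed`, so two runs with the same inputs are identical.
#'
#' @param variants character vector of variant names (see
#'   [variant_names()]).
#' @param data_dir dataset directory ([generate_dataset()] layout).
#' @param config a [train_config()].
#' @param out_dir where reports are written: `params.csv` (parameter audit
#'   with informational wall time), `metrics.csv` (per-variant Dice/IoU by
#'   split), and `panels/` with `[image | actual | predicted]` PNGs for
#'   sample test images. `NULL` skips writing.
#' @param n_panels number of sample test panels per variant.
#' @param threshold mask binarization threshold for evaluation.
#' @param verbose print progress.
#' @return list of run records (one per successful variant): `variant`,
#'   `parameter_count`, `train_metrics`, `test_metrics`, `loss_history`,
#'   `wall_time`. Failed variants are dropped with a warning and listed in
#'   attribute `"failures"`.
#' @export
run_benchmark <- function(variants, data_dir, config = train_config(),
                          out_dir = NULL, n_panels = 4L, threshold = 0.5,
                          verbose = FALSE) {
  if (length(variants) == 0L) stop("empty variant list", call. = FALSE)
  stopifnot(inherits(config, "train_config"))
  manifest <- load_manifest(data_dir)
  pairs <- lapply(seq_len(nrow(manifest)), function(i) {
    preprocess_pair(read_pair(manifest$image_path[i], manifest$mask_path[i],
                              manifest$id[i], manifest$class[i]),
                    size = config$image_size)
  })
  names(pairs) <- manifest$id
  sp <- split_dataset(manifest, config$split_fraction, config$seed,
                      stratify = TRUE)
  stopifnot(length(intersect(sp$train, sp$test)) == 0L)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(out_dir, "panels"), showWarnings = FALSE)
  }

  records <- list()
  failures <- character(0)
  for (vn in variants) {
    rec <- tryCatch({
      if (verbose) message("== ", vn)
      spec <- resolve_variant(vn)
      audit <- closed_form_param_count(spec)
      t0 <- proc.time()[["elapsed"]]
      model <- build_unet(spec, seed = derive_seed(config$seed, match(vn, variants)))
      stopifnot(count_parameters(model) == audit)
      fit <- train_model(model, pairs[sp$train], config, verbose = verbose)
      wall <- proc.time()[["elapsed"]] - t0
      train_rep <- .evaluate_split(fit$model, pairs[sp$train], threshold)
      test_rep <- .evaluate_split(fit$model, pairs[sp$test], threshold)
      if (!is.null(out_dir)) {
        for (id in utils::head(sp$test, n_panels)) {
          p <- pairs[[id]]
          write_panel(p, predict(fit$model, p$image, type = "mask",
                                 threshold = threshold),
                      file.path(out_dir, "panels",
                                sprintf("%s_%s.png", spec$name, id)))
        }
      }
      list(variant = spec$name, parameter_count = audit,
           train_metrics = train_rep, test_metrics = test_rep,
           loss_history = fit$loss_history, wall_time = wall,
           model = fit$model)
    }, error = function(e) {
      warning(sprintf("variant %s failed: %s", vn, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
    if (is.null(rec)) failures <- c(failures, vn) else records[[vn]] <- rec
  }

  if (!is.null(out_dir) && length(records) > 0L) {
    params_tab <- do.call(rbind, lapply(records, function(r)
      data.frame(model = r$variant,
                 image_size = paste(config$image_size, collapse = "x"),
                 total_params = r$parameter_count,
                 wall_time_sec_informational = round(r$wall_time, 2),
                 stringsAsFactors = FALSE)))
    write.csv(params_tab, file.path(out_dir, "params.csv"),
              row.names = FALSE)
    metrics_tab <- do.call(rbind, lapply(records, function(r)
      rbind(.metric_rows(r$variant, "Train", r$train_metrics),
            .metric_rows(r$variant, "Test", r$test_metrics))))
    write.csv(metrics_tab, file.path(out_dir, "metrics.csv"),
              row.names = FALSE)
  }
  attr(records, "failures") <- failures
  attr(records, "split") <- sp
  records
}
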