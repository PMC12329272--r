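test_that("split arithmetic matches the 80/20 protocol", {
  m100 <- data.frame(id = as.character(1:100))
  s <- split_dataset(m100, 0.8, seed = 1, stratify = FALSE)
  expect_length(s$train, 80)
  expect_length(s$test, 20)

  big <- data.frame(id = as.character(1:3886))
  sb <- split_dataset(big, 0.8, seed = 1, stratify = FALSE)
  expect_length(sb$train, 3108)   # floor(0.8 * 3886)
  expect_length(sb$test, 778)

  expect_length(intersect(sb$train, sb$test), 0)
  expect_setequal(c(sb$train, sb$test), big$id)
})

test_that("splits are seeded, reproducible, and stratified by class", {
  m <- data.frame(id = as.character(1:90),
                  class = rep(c("COVID", "Normal", "Viral Pneumonia"), 30))
  s1 <- split_dataset(m, 0.8, seed = 4)
  s2 <- split_dataset(m, 0.8, seed = 4)
  expect_identical(s1, s2)
  s3 <- split_dataset(m, 0.8, seed = 5)
  expect_false(identical(s1$train, s3$train))
  # per-class balance: 30 per class -> 24/6
  cls <- m$class[match(s1$train, m$id)]
  expect_equal(unname(table(cls)["COVID"]), 24, ignore_attr = TRUE)

  tiny <- data.frame(id = c("a", "b", "c"), class = c("x", "x", "y"))
  expect_error(split_dataset(tiny, 0.8, seed = 1), "fewer than 2")
  expect_error(split_dataset(m, 1.2, seed = 1), "0, 1")
  expect_error(split_dataset(m[0, , drop = FALSE], 0.8), "empty")
})

test_that("training config validates the protocol invariants", {
  cfg <- train_config()
  expect_equal(cfg$image_size, c(256L, 256L))
  expect_equal(cfg$epochs, 10L)
  expect_equal(cfg$batch_size, 20L)
  expect_equal(cfg$learning_rate, 1e-4)
  expect_equal(cfg$split_fraction, 0.8)
  expect_error(train_config(epochs = 0), "epochs")
  expect_error(train_config(batch_size = 0), "batch_size")
  expect_error(train_config(learning_rate = 0), "learning_rate")
  expect_error(train_config(split_fraction = 1), "split_fraction")
})

test_that("training reduces the loss on easy phantoms and is deterministic", {
  dat <- make_easy_pairs(50, size = 64, seed = 0)
  cfg <- train_config(image_size = 64, epochs = 3, batch_size = 20,
                      learning_rate = 3e-3, seed = 0)
  fit1 <- train_model(build_unet("U-Net16", seed = 0), dat$pairs, cfg)
  expect_length(fit1$loss_history, 3)
  expect_lt(fit1$loss_history[3], fit1$loss_history[1])
  fit2 <- train_model(build_unet("U-Net16", seed = 0), dat$pairs, cfg)
  expect_identical(fit1$loss_history, fit2$loss_history)
  expect_identical(fit1$model$params, fit2$model$params)
})

test_that("training refuses batch-norm models and bad geometry", {
  dat <- make_easy_pairs(2, size = 32, seed = 1)
  mbn <- build_unet(toy_spec(levels = 1, bn = TRUE), seed = 1)
  expect_error(train_model(mbn, dat$pairs, train_config(image_size = 32)),
               "batchnorm")
  m <- build_unet("U-Net16", seed = 1)
  bad <- lapply(dat$pairs, function(p) {
    p$image <- p$image[1:30, 1:30]; p$mask <- p$mask[1:30, 1:30]; p
  })
  expect_error(train_model(m, bad, train_config(image_size = 30)),
               "not divisible")
})

test_that("the benchmark harness audits, trains, reports, and stays leak-free", {
  d <- withr::local_tempdir()
  out <- file.path(d, "results")
  generate_dataset(24, phantom_params(size = 32, preset = "easy", seed = 2),
                   file.path(d, "data"))
  cfg <- train_config(image_size = 32, epochs = 1, batch_size = 8,
                      learning_rate = 3e-3, seed = 2)
  rec <- run_benchmark("U-Net16", file.path(d, "data"), cfg,
                       out_dir = out, n_panels = 2)
  expect_length(rec, 1)
  r <- rec[["U-Net16"]]
  expect_equal(r$parameter_count, closed_form_param_count("U-Net16"))
  expect_length(r$loss_history, 1)
  expect_s3_class(r$test_metrics, "metric_report")

  sp <- attr(rec, "split")
  expect_length(intersect(sp$train, sp$test), 0)
  expect_equal(length(sp$train) + length(sp$test), 24)

  expect_true(file.exists(file.path(out, "params.csv")))
  mt <- read.csv(file.path(out, "metrics.csv"))
  expect_equal(nrow(mt), 2)                  # Train + Test rows
  expect_true(all(mt$dice_micro >= mt$iou_micro))
  expect_true(all(mt$dice_macro >= mt$iou_macro))
  pt <- read.csv(file.path(out, "params.csv"))
  expect_equal(pt$total_params, 52993)
  panels <- list.files(file.path(out, "panels"))
  expect_length(panels, 2)

  expect_error(run_benchmark(character(0), file.path(d, "data"), cfg),
               "empty")
  # unknown variants are skipped with a warning, not fatal
  expect_warning(
    rec2 <- run_benchmark(c("U-Net5"), file.path(d, "data"), cfg),
    "failed")
  expect_equal(attr(rec2, "failures"), "U-Net5")
})

test_that("two benchmark runs with the same seed emit identical tables", {
  d <- withr::local_tempdir()
  generate_dataset(16, phantom_params(size = 32, preset = "easy", seed = 3),
                   file.path(d, "data"))
  cfg <- train_config(image_size = 32, epochs = 1, batch_size = 8,
                      learning_rate = 3e-3, seed = 3)
  o1 <- file.path(d, "r1"); o2 <- file.path(d, "r2")
  run_benchmark("U-Net16", file.path(d, "data"), cfg, out_dir = o1)
  run_benchmark("U-Net16", file.path(d, "data"), cfg, out_dir = o2)
  expect_identical(readLines(file.path(o1, "metrics.csv")),
                   readLines(file.path(o2, "metrics.csv")))
})
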