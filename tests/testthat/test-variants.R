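test_that("the registry returns the reference family configurations", {
  depth <- list("U-Net7" = c(3, 64), "U-Net9" = c(4, 32),
                "U-Net11" = c(5, 16), "U-Net13" = c(6, 8))
  for (nm in names(depth)) {
    sp <- resolve_variant(nm)
    expect_equal(sp$encoder_levels, depth[[nm]][1])
    expect_equal(sp$width_mode, "doubling")
    expect_equal(sp$initial_filters, depth[[nm]][2])
    expect_equal(layer_count(sp), as.integer(sub("U-Net", "", nm)))
  }
  for (f in c(16, 32, 64, 128)) {
    sp <- resolve_variant(paste0("U-Net", f))
    expect_equal(sp$encoder_levels, 4L)
    expect_equal(sp$width_mode, "fixed")
    expect_equal(sp$fixed_filters, f)
    expect_equal(layer_count(sp), 9L)   # same depth as U-Net9
  }
  sp <- resolve_variant("u-NET16")      # case-insensitive
  expect_equal(sp$name, "U-Net16")
  expect_true(all(vapply(variant_names(), function(v) {
    s <- resolve_variant(v)
    s$in_channels == 1 && s$out_channels == 1 && !s$use_batchnorm &&
      s$conv_kernel == 3 && s$up_kernel == 2
  }, logical(1))))
})

test_that("unknown variants give an error listing the valid names", {
  expect_error(resolve_variant("U-Net5"), "unsupported")
  expect_error(resolve_variant("U-Net5"), "U-Net128")
})

test_that("spec validation rejects degenerate configurations", {
  expect_error(variant_spec(encoder_levels = 0, width_mode = "doubling",
                            initial_filters = 4), "encoder_levels")
  expect_error(variant_spec(encoder_levels = 2, width_mode = "doubling",
                            initial_filters = 0), "initial_filters")
  expect_error(variant_spec(encoder_levels = 2, width_mode = "fixed"),
               "fixed_filters")
  expect_error(variant_spec(encoder_levels = 2, width_mode = "doubling",
                            initial_filters = 4, conv_kernel = 4), "odd")
})

test_that("doubling and fixed channel schedules follow their definitions", {
  sp <- variant_spec("d", 3, "doubling", initial_filters = 8)
  ch <- unetbench:::level_channels(sp)
  expect_equal(ch$levels, c(8, 16, 32))
  expect_equal(ch$bottleneck, 64)
  sp <- variant_spec("f", 3, "fixed", fixed_filters = 24)
  ch <- unetbench:::level_channels(sp)
  expect_equal(ch$levels, rep(24, 3))
  expect_equal(ch$bottleneck, 24)
})

test_that("closed-form count reproduces the hand-computed toy audit", {
  # levels 1, doubling from 2, in 1, out 1, no BN:
  # enc (20 + 38) + bottleneck (76 + 148) + up 34 + convs (74 + 38) + head 3
  expect_equal(closed_form_param_count(toy_spec()), 431)
  m <- build_unet(toy_spec(), seed = 1)
  expect_equal(count_parameters(m), 431)
})

test_that("closed-form count equals the built-model count on random specs", {
  set.seed(101)
  for (i in 1:25) {
    sp <- random_small_spec()
    expect_equal(count_parameters(build_unet(sp, seed = i)),
                 closed_form_param_count(sp), info = paste("spec", i))
  }
})

test_that("parameter counts grow as expected with width", {
  fixed_counts <- vapply(c(8, 16, 24, 32, 48), function(f)
    closed_form_param_count(variant_spec("f", 4, "fixed", fixed_filters = f)),
    numeric(1))
  expect_true(all(diff(fixed_counts) > 0))
  r <- closed_form_param_count(variant_spec("d", 3, "doubling",
                                            initial_filters = 16)) /
    closed_form_param_count(variant_spec("d", 3, "doubling",
                                         initial_filters = 8))
  expect_gt(r, 3.8)
  expect_lt(r, 4.2)
})

test_that("building with a fixed seed is deterministic and pure", {
  set.seed(999)
  before <- .Random.seed
  m1 <- build_unet("U-Net16", seed = 7)
  m2 <- build_unet("U-Net16", seed = 7)
  expect_identical(m1$params, m2$params)
  expect_identical(before, .Random.seed)  # global RNG untouched
  m3 <- build_unet("U-Net16", seed = 8)
  expect_false(identical(m1$params, m3$params))
})

test_that("batch-norm accounting adds four values per block-conv channel", {
  sp_off <- toy_spec(levels = 2, filters = 3)
  sp_on <- toy_spec(levels = 2, filters = 3, bn = TRUE)
  ch <- unetbench:::level_channels(sp_on)
  # two block convs per encoder level, bottleneck and decoder level;
  # upsamplers and head carry no BN
  bn_channels <- 2 * sum(ch$levels) + 2 * ch$bottleneck + 2 * sum(ch$levels)
  expect_equal(closed_form_param_count(sp_on),
               closed_form_param_count(sp_off) + 4 * bn_channels)
  expect_equal(count_parameters(build_unet(sp_on, seed = 1)),
               closed_form_param_count(sp_on))
})

test_that("batch-norm folds into the effective affine form", {
  gamma <- c(1.5, 0.5); beta <- c(0.2, -0.1)
  mu <- c(0.3, -0.4); va <- c(2, 0.25); eps <- 1e-5
  eff <- bn_effective_affine(gamma, beta, mu, va, eps)
  x <- c(0.7, 1.3)
  # folded affine must equal normalize-then-scale-shift
  expect_equal(eff$w_bn * x + eff$b_bn,
               gamma * (x - mu) / sqrt(va + eps) + beta, tolerance = 1e-12)
  expect_error(bn_effective_affine(1, 0, 0, -1), "non-negative")
  expect_error(bn_effective_affine(1, 0, 0, 1, epsilon = 0), "positive")
})
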