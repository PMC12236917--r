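test_that("noiseless five-pool spectra are recovered exactly", {
  ax <- build_offset_axis()
  tp <- five_pool_truth(c(0.8, 0.08, 0.04, 0.05, 0.06))
  tp$amplitude <- c(0.85, 0.08, 0.04, 0.05, 0.06)
  z <- model_zspectrum(tp, ax)
  f <- fit_zspectrum(z, ax)
  expect_true(f$ok)
  expect_true(f$converged)
  expect_lt(f$rss, 1e-10)
  expect_lt(max(abs(f$pools$amplitude - tp$amplitude)), 1e-4)
  expect_lt(max(abs(f$pools$fwhm - tp$fwhm)), 1e-3)
})

test_that("truth-valued initialization closes the forward/inverse loop", {
  ax <- build_offset_axis()
  tp <- five_pool_truth()
  z <- simulate_zspectrum(tp, ax)
  f <- fit_zspectrum(z, ax, init = tp)
  expect_lt(max(abs(f$pools$amplitude - tp$amplitude)), 1e-6)
})

test_that("a flat spectrum drives solute amplitudes to the lower bound", {
  ax <- build_offset_axis()
  f <- fit_zspectrum(rep(1, 91), ax)
  solutes <- f$pools$name != "water"
  expect_lt(max(f$pools$amplitude[solutes]), 1e-6)
})

test_that("masked points never influence the fit", {
  ax <- build_offset_axis()
  z <- model_zspectrum(five_pool_truth(), ax)
  w <- rep(1, 91)
  zb <- z; zb[40] <- 10; wb <- w; wb[40] <- 0
  f_clean <- fit_zspectrum(z, ax, weights = wb)
  f_outlier <- fit_zspectrum(zb, ax, weights = wb)
  expect_identical(f_clean$pools, f_outlier$pools)
  expect_identical(f_clean$rss, f_outlier$rss)
})

test_that("insufficient or implausible data is skipped with a reason", {
  ax <- build_offset_axis()
  z <- model_zspectrum(five_pool_truth(), ax)
  few <- fit_zspectrum(c(z[1:10], rep(NA, 81)), ax)
  expect_false(few$ok)
  expect_match(few$reason, "unmasked points")
  wild <- z; wild[10] <- 7
  bad <- fit_zspectrum(wild, ax)
  expect_false(bad$ok)
  expect_match(bad$reason, "plausible range")
})

test_that("fitted amplitude is monotone in the true amplitude", {
  ax <- build_offset_axis()
  fitted <- sapply(c(0.03, 0.05, 0.08), function(a) {
    tp <- five_pool_truth(c(0.75, 0.06, 0.04, a, 0.06))
    f <- fit_zspectrum(simulate_zspectrum(tp, ax), ax)
    f$pools$amplitude[f$pools$name == "glutamate"]
  })
  expect_true(all(diff(fitted) > 0))
})

test_that("default configuration is identifiable on the default axis", {
  expect_true(check_identifiability())
  expect_invisible(check_identifiability(fit_config(), build_offset_axis()))
})

test_that("fit_stack fits uniform phantoms uniformly and honors the mask", {
  cfg <- tiny_phantom_config(n = 1L, noise_sigma = 0, wassr_noise_sigma = 0,
                             b0_coef = rep(0, 6), subject_cv = 0)
  ph <- simulate_phantom(cfg)
  mask <- ph$labels == 1L  # cortex only
  fits <- fit_stack(ph$subjects[[1]]$z, ph$axis, mask = mask)
  expect_identical(unname(fits$counts["fitted"]), sum(mask))
  expect_true(all(is.na(fits$amplitude[!mask])))  # background absent
  glu <- fits$amplitude[, , match("glutamate", fits$names)]
  expect_lt(diff(range(glu[mask])), 1e-6)
})

test_that("fitted amplitudes cluster by region according to ground truth", {
  lay <- default_region_layout(c(12L, 12L), size = 2L)[c("cortex",
                                                         "thalamus")]
  tr <- default_pool_truth(arms = "baseline", regions = names(lay))
  tr$amplitude[tr$region == "cortex" & tr$pool == "glutamate"] <- 0.08
  cfg <- phantom_config(grid_shape = c(12L, 12L), region_layout = lay,
                        arms = "baseline",
                        n_subjects_per_arm = c(baseline = 1L),
                        pool_truth = tr, noise_sigma = 0,
                        wassr_noise_sigma = 0, b0_coef = rep(0, 6),
                        subject_cv = 0, seed = 2L)
  ph <- simulate_phantom(cfg)
  fits <- fit_stack(ph$subjects[[1]]$z, ph$axis, mask = ph$labels > 0L)
  glu <- fits$amplitude[, , match("glutamate", fits$names)]
  expect_equal(unname(mean(glu[ph$labels == 1L])), 0.08, tolerance = 1e-4)
  expect_equal(unname(mean(glu[ph$labels == 2L])), 0.05, tolerance = 1e-4)
})

test_that("fit_stack with no usable voxels errors out", {
  cfg <- tiny_phantom_config(n = 1L)
  ph <- simulate_phantom(cfg)
  expect_error(fit_stack(ph$subjects[[1]]$z, ph$axis,
                         mask = matrix(FALSE, 12, 12)),
               "no valid voxels")
})
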