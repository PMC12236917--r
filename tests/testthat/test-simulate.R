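test_that("single-pool spectrum equals amplitude drop at the center", {
  ax <- build_offset_axis()
  z <- simulate_zspectrum(pool_params("glutamate", 0.2, 3, 1), ax)
  expect_equal(z[ax == 3], 0.8)
  empty <- pool_params(character(0), numeric(0), numeric(0), numeric(0))
  expect_equal(simulate_zspectrum(empty, ax), rep(1, 91))
})

test_that("five-pool noiseless minimum sits at the water center", {
  dense <- seq(-5, 5, by = 0.01)
  z <- simulate_zspectrum(five_pool_truth(), dense)
  # MT (-1 ppm) and NOE (-3.5 ppm) skew the minimum slightly upfield
  expect_lt(abs(dense[which.min(z)]), 0.02)
})

test_that("pool systems with amplitude sum >= 1 are rejected", {
  ax <- build_offset_axis()
  bad <- five_pool_truth(c(0.85, 0.08, 0.04, 0.05, 0.06) * 0.9)
  bad$amplitude <- c(0.85, 0.08, 0.04, 0.05, 0.06)  # sums to 1.08
  expect_error(simulate_zspectrum(bad, ax), "invalid pool system")
})

test_that("seeded simulation is reproducible and leaves the RNG alone", {
  ax <- build_offset_axis()
  tp <- five_pool_truth()
  set.seed(99); before <- .Random.seed
  z1 <- simulate_zspectrum(tp, ax, noise_sigma = 0.01, seed = 5)
  expect_identical(.Random.seed, before)
  z2 <- simulate_zspectrum(tp, ax, noise_sigma = 0.01, seed = 5)
  expect_identical(z1, z2)
})

test_that("wassr spectrum minimum tracks the B0 offset", {
  dense <- seq(-1, 1, by = 0.001)
  w <- simulate_wassr(0.3, axis = dense)
  expect_equal(dense[which.min(w)], 0.3)
  w0 <- simulate_wassr(0, axis = default_wassr_axis())
  expect_equal(w0, rev(w0))  # symmetric about 0
  est <- estimate_b0(simulate_wassr(-0.4, noise_sigma = 0.01, seed = 3),
                     default_wassr_axis())
  expect_true(est$valid)
  expect_lt(abs(est$offset - (-0.4)), 0.02)
})

test_that("phantom configuration validates its invariants", {
  expect_error(
    tiny_phantom_config(region_layout = list(cortex = rect_region(1:20, 1:2))),
    "exceeds the grid")
  lay <- default_region_layout(c(12L, 12L), size = 2L)
  lay$hippocampus <- lay$cortex
  expect_error(tiny_phantom_config(region_layout = lay), "overlaps")
  tr <- default_pool_truth()
  tr$amplitude[tr$pool == "water"] <- 0.97
  expect_error(tiny_phantom_config(pool_truth = tr), "sum to < 1")
  expect_error(tiny_phantom_config(b0_coef = c(0.6, 0, 0, 0, 0, 0)),
               "exceeds its bound")
})

test_that("zero-noise flat-field phantom gives identical spectra per region", {
  cfg <- tiny_phantom_config(noise_sigma = 0, wassr_noise_sigma = 0,
                             b0_coef = rep(0, 6), n = 1L, subject_cv = 0)
  ph <- simulate_phantom(cfg)
  s <- ph$subjects[[1]]
  for (id in seq_along(cfg$region_layout)) {
    vox <- which(ph$labels == id, arr.ind = TRUE)
    specs <- apply(vox, 1, function(ij) s$z[ij[1], ij[2], ])
    expect_lt(max(abs(specs - specs[, 1])), 1e-12)
  }
})

test_that("arm effects are encoded exactly in the ground truth", {
  tr <- default_pool_truth()
  base <- function(region, pool)
    tr$amplitude[tr$arm == "baseline" & tr$region == region & tr$pool == pool]
  veh <- function(region, pool)
    tr$amplitude[tr$arm == "wk12_vehicle" & tr$region == region &
                   tr$pool == pool]
  expect_equal(veh("cortex", "glutamate") / base("cortex", "glutamate"), 0.8)
  expect_equal(veh("thalamus", "glutamate") / base("thalamus", "glutamate"), 1)
  art <- function(region, pool)
    tr$amplitude[tr$arm == "wk12_art" & tr$region == region & tr$pool == pool]
  expect_equal(art("cortex", "glutamate"), base("cortex", "glutamate"))
})

test_that("identical config and seed give bit-identical phantoms", {
  cfg <- tiny_phantom_config(n = 2L)
  ph1 <- simulate_phantom(cfg)
  ph2 <- simulate_phantom(cfg)
  expect_identical(ph1$subjects, ph2$subjects)
  expect_identical(ph1$truth, ph2$truth)
})

test_that("phantom truth jitter matches the configured CV", {
  cfg <- tiny_phantom_config(n = 40L, seed = 21L)
  ph <- simulate_phantom(cfg)
  glu <- ph$truth[ph$truth$region == "cortex" & ph$truth$pool == "glutamate" &
                    ph$truth$arm == "baseline", "amplitude"]
  expect_equal(mean(glu), 0.05, tolerance = 0.05)
  expect_equal(stats::sd(glu) / mean(glu), 0.05, tolerance = 0.5)
})
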