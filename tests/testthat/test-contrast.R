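test_that("analytic AUC matches the closed form and is linear in A", {
  expect_equal(lorentzian_auc_analytic(1, 2), pi)
  expect_equal(lorentzian_auc_analytic(0.04, 1), 0.02 * pi)
  A <- c(0.1, 0.37, 0.9); G <- 1.7
  expect_equal(lorentzian_auc_analytic(A, G),
               A * lorentzian_auc_analytic(1, G))
})

test_that("numeric AUC converges to the windowed closed form", {
  # quadrature: trapezoid vs exact integral over the same window
  num <- lorentzian_auc_numeric(1, 0, 2, range = c(-100, 100), n = 40001L)
  expect_equal(num, lorentzian_auc_window(1, 0, 2, -100, 100),
               tolerance = 1e-6)
  # widening the window converges monotonically to the full-line value
  wins <- c(5, 50, 500, 5000)
  vals <- sapply(wins, function(w)
    lorentzian_auc_window(1, 0, 2, -w, w))
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals < pi))
  expect_lt(abs(vals[4] - pi) / pi, 1e-3)
})

test_that("in-window fraction equals the arctan closed form per pool", {
  ax_win <- c(-5, 5)
  for (i in seq_len(nrow(five_pool_truth()))) {
    p <- five_pool_truth()[i, ]
    num <- lorentzian_auc_numeric(p$amplitude, p$center, p$fwhm,
                                  range = ax_win, n = 20001L)
    ana <- lorentzian_auc_analytic(p$amplitude, p$fwhm)
    frac <- (atan(2 * (5 - p$center) / p$fwhm) +
               atan(2 * (5 + p$center) / p$fwhm)) / pi
    expect_lt(num, ana)
    expect_equal(num / ana, frac, tolerance = 1e-6)
  }
})

test_that("pool_auc reads fits and rejects unknown pools", {
  ax <- build_offset_axis()
  f <- fit_zspectrum(model_zspectrum(five_pool_truth(), ax), ax)
  expect_equal(pool_auc(f, "glutamate"),
               with(f$pools[f$pools$name == "glutamate", ],
                    amplitude * pi * fwhm / 2))
  expect_error(pool_auc(f, "lactate"), "unknown pool")
})

test_that("contrast maps are constant on uniform phantoms and masked off it", {
  cfg <- tiny_phantom_config(n = 1L, noise_sigma = 0, wassr_noise_sigma = 0,
                             b0_coef = rep(0, 6), subject_cv = 0)
  ph <- simulate_phantom(cfg)
  mask <- ph$labels > 0L
  fits <- fit_stack(ph$subjects[[1]]$z, ph$axis, mask = mask)
  cm <- contrast_map(fits, "creatine")
  expect_true(all(is.na(cm[!mask])))
  for (id in seq_along(cfg$region_layout))
    expect_lt(diff(range(cm[ph$labels == id])), 1e-6)
})

test_that("a 15% regional amplitude drop shows as a 0.85 AUC ratio", {
  lay <- default_region_layout(c(12L, 12L), size = 2L)[c("cortex",
                                                         "thalamus")]
  tr <- default_pool_truth(arms = "baseline", regions = names(lay))
  tr$amplitude[tr$region == "cortex" & tr$pool == "glutamate"] <-
    0.85 * tr$amplitude[tr$region == "thalamus" & tr$pool == "glutamate"]
  cfg <- phantom_config(grid_shape = c(12L, 12L), region_layout = lay,
                        arms = "baseline",
                        n_subjects_per_arm = c(baseline = 1L),
                        pool_truth = tr, noise_sigma = 0,
                        wassr_noise_sigma = 0, b0_coef = rep(0, 6),
                        subject_cv = 0, seed = 2L)
  ph <- simulate_phantom(cfg)
  fits <- fit_stack(ph$subjects[[1]]$z, ph$axis, mask = ph$labels > 0L)
  cm <- contrast_map(fits, "glutamate")
  ratio <- mean(cm[ph$labels == 1L]) / mean(cm[ph$labels == 2L])
  expect_equal(ratio, 0.85, tolerance = 1e-3)
})

test_that("heatmap rendering is deterministic and windows comparably", {
  m <- structure(matrix(c(1, 2, 3, 4, NA, 6), 2, 3),
                 class = c("contrast_map", "matrix"), pool = "glutamate",
                 mode = "analytic")
  f1 <- tempfile(fileext = ".png"); f2 <- tempfile(fileext = ".png")
  render_heatmap(m, f1, window = c(0, 6))
  render_heatmap(m, f2, window = c(0, 6))
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  meta <- jsonlite::read_json(paste0(f1, ".json"))
  expect_equal(unlist(meta$window), c(0, 6))

  # constant map renders a uniform color field
  cmap <- matrix(2, 4, 4)
  fc <- tempfile(fileext = ".png")
  render_heatmap(cmap, fc, window = c(0, 4), scale = 1L)
  px <- png::readPNG(fc)[, 1:4, ]
  expect_equal(length(unique(as.vector(round(px, 6)))), 3L)  # one RGB triple

  # shared window: the arm with lower values renders darker on average
  lo <- matrix(1, 4, 4); hi <- matrix(3, 4, 4)
  flo <- tempfile(fileext = ".png"); fhi <- tempfile(fileext = ".png")
  render_heatmap(lo, flo, window = c(0, 4), scale = 1L)
  render_heatmap(hi, fhi, window = c(0, 4), scale = 1L)
  expect_lt(mean(png::readPNG(flo)[, 1:4, ]), mean(png::readPNG(fhi)[, 1:4, ]))

  expect_error(render_heatmap(cmap, tempfile(), window = c(2, 2)),
               "increasing")
})

test_that("all-masked fit stacks cannot produce a map", {
  cfg <- tiny_phantom_config(n = 1L, noise_sigma = 0, wassr_noise_sigma = 0)
  ph <- simulate_phantom(cfg)
  fits <- fit_stack(ph$subjects[[1]]$z, ph$axis, mask = ph$labels > 0L)
  fits$converged[] <- FALSE
  expect_error(contrast_map(fits, "glutamate"), "no converged voxels")
})
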