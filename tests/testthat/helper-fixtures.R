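# Shared fixtures: small, fast phantom configurations and truth tables.

five_pool_truth <- function(amplitudes = c(0.75, 0.06, 0.04, 0.05, 0.06)) {
  pool_params(c("water", "mt", "creatine", "glutamate", "noe"),
              amplitudes, c(0, -1, 2, 3, -3.5), c(1.4, 3.0, 1.0, 1.2, 2.5))
}

# naive reference evaluation of the sum-of-Lorentzians model, coded
# independently of model_zspectrum()
naive_model <- function(pools, axis) {
  sapply(axis, function(x) {
    1 - sum(pools$amplitude * (pools$fwhm / 2)^2 /
              ((pools$fwhm / 2)^2 + (x - pools$center)^2))
  })
}

tiny_phantom_config <- function(grid = c(12L, 12L), n = 3L,
                                noise_sigma = 0.005,
                                wassr_noise_sigma = 0.005,
                                seed = 11L, region_layout = NULL, ...) {
  if (is.null(region_layout))
    region_layout <- default_region_layout(grid, size = 2L)
  phantom_config(
    grid_shape = grid, region_layout = region_layout,
    n_subjects_per_arm = n, noise_sigma = noise_sigma,
    wassr_noise_sigma = wassr_noise_sigma, seed = seed, ...)
}

# brute-force one-way ANOVA from explicit sums of squares
bruteforce_anova_F <- function(values, groups) {
  groups <- as.character(groups)
  gm <- mean(values)
  k <- length(unique(groups))
  ssb <- sum(tapply(values, groups,
                    function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  dfb <- k - 1; dfw <- length(values) - k
  list(F = (ssb / dfb) / (ssw / dfw), df1 = dfb, df2 = dfw,
       p = stats::pf((ssb / dfb) / (ssw / dfw), dfb, dfw,
                     lower.tail = FALSE))
}

# brute-force pooled two-sample t from the closed-form pooled variance
bruteforce_pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
    (na + nb - 2)
  tt <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = tt, df = na + nb - 2,
       p = 2 * stats::pt(-abs(tt), na + nb - 2))
}

# closed-form Welch-Satterthwaite df
bruteforce_welch_df <- function(a, b) {
  va <- stats::var(a) / length(a); vb <- stats::var(b) / length(b)
  (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
}
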