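test_that("region aggregation takes means of unmasked voxels", {
  lab <- matrix(0L, 4, 4)
  lab[1:2, 1:2] <- 1L
  lab[3:4, 3:4] <- 2L
  attr(lab, "regions") <- c("cortex", "thalamus")
  m <- matrix(5, 4, 4)
  rows <- aggregate_regions(m, lab, subject = "s1", arm = "baseline",
                            pool = "glutamate")
  expect_equal(rows$contrast, c(5, 5))
  m2 <- matrix(NA_real_, 4, 4)
  m2[1:2, 1:2] <- c(1, 2, 3, 4)
  expect_warning(
    rows2 <- aggregate_regions(m2, lab, "s1", "baseline", pool = "glu"),
    "no unmasked voxels")
  expect_equal(nrow(rows2), 1L)
  expect_equal(rows2$contrast, 2.5)
  lab_bad <- lab; lab_bad[1, 4] <- 9L
  expect_error(aggregate_regions(m, lab_bad, "s1", "baseline", pool = "g"),
               "region registry")
})

test_that("significance tiers bin exactly", {
  expect_identical(tier(c(0.04, 0.0006, 0.5)), c("*", "***", "ns"))
  expect_identical(tier(c(0, 9.9e-5, 1e-4, 9.9e-4, 1e-3, 9.9e-3, 0.01,
                          0.049, 0.05, 0.099, 0.1, 1)),
                   c("****", "****", "***", "***", "**", "**", "*", "*",
                     "#", "#", "ns", "ns"))
  expect_error(tier(1.2), "\\[0, 1\\]")
  expect_error(tier(-0.1), "\\[0, 1\\]")
})

test_that("one-way ANOVA matches hand-computed sums of squares", {
  r <- omnibus_anova(c(0, 1, 2, 10, 11, 12, 20, 21, 22),
                     rep(c("a", "b", "c"), each = 3))
  expect_equal(r$statistic, 300)       # between-SS 600 on 2 df, within 6 on 6
  expect_equal(r$df, 2); expect_equal(r$df2, 6)
  expect_lt(r$p, 1e-4)
  r0 <- omnibus_anova(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 1)
  rd <- omnibus_anova(rep(5, 6), rep(c("a", "b"), each = 3))
  expect_true(rd$degenerate)
  expect_warning(omnibus_anova(c(1, 2, 3, 4, 9), c("a", "a", "b", "b", "c")),
                 "excluded")
  expect_error(suppressWarnings(omnibus_anova(c(1, 2, 9), c("a", "a", "c"))),
               ">= 2 arms")
})

test_that("t-tests match closed-form pooled and Welch computations", {
  same <- pairwise_ttest(c(1, 2, 3), c(1, 2, 3), "pooled")
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  r <- pairwise_ttest(c(1, 2, 3), c(4, 5, 6), "pooled")
  expect_equal(r$statistic, -3.674235, tolerance = 1e-6)
  expect_equal(r$df, 4)
  w <- pairwise_ttest(c(1, 2, 3, 4, 5), c(10, 20), "welch")
  expect_lt(w$df, 5 + 2 - 2)
  expect_equal(w$df, bruteforce_welch_df(c(1, 2, 3, 4, 5), c(10, 20)))
  dg <- pairwise_ttest(c(2, 2), c(2, 2), "pooled")
  expect_true(dg$degenerate)
  expect_error(pairwise_ttest(1, c(1, 2), "pooled"), "n >= 2")
})

test_that("statistics agree with brute-force oracles on random tables", {
  set.seed(31)
  for (rep in 1:20) {
    ns <- sample(3:8, 3, replace = TRUE)
    g <- rep(c("a", "b", "c"), ns)
    v <- stats::rnorm(sum(ns), mean = rep(stats::runif(3, 0, 2), ns))
    bf <- bruteforce_anova_F(v, g)
    r <- omnibus_anova(v, g)
    expect_equal(r$statistic, bf$F, tolerance = 1e-10)
    expect_equal(r$p, bf$p, tolerance = 1e-10)
    a <- v[g == "a"]; b <- v[g == "b"]
    bt <- bruteforce_pooled_t(a, b)
    rt <- pairwise_ttest(a, b, "pooled")
    expect_equal(rt$statistic, bt$t, tolerance = 1e-10)
    expect_equal(rt$p, bt$p, tolerance = 1e-10)
    expect_equal(pairwise_ttest(a, b, "welch")$df,
                 bruteforce_welch_df(a, b), tolerance = 1e-10)
  }
})

test_that("SEM is sd over sqrt(n)", {
  expect_equal(sem(c(2, 4, 6)), 2 / sqrt(3))
})

test_that("the comparison suite runs the full scheme per region and pool", {
  tab <- simulate_group_table(tiny_phantom_config(), seed = 4L)
  out <- comparison_suite(tab)
  per <- table(out$tests$region, out$tests$pool)
  expect_true(all(per == 4L))  # 1 ANOVA + 3 pairwise per (region, pool)
  expect_setequal(unique(out$tests$variant[out$tests$comparison ==
                                             "baseline vs wk12_vehicle"]),
                  "welch")
  expect_setequal(unique(out$tests$variant[out$tests$comparison ==
                                             "baseline vs wk6"]), "pooled")
  expect_true(all(out$tests$p >= 0 & out$tests$p <= 1, na.rm = TRUE))
  expect_true(all(out$tests$tier == tier(out$tests$p), na.rm = TRUE))
  # summary carries mean and SEM per arm
  s <- out$summary[out$summary$region == "cortex" &
                     out$summary$pool == "glutamate", ]
  expect_setequal(s$arm, c("baseline", "wk6", "wk12_vehicle", "wk12_art"))
  one <- tab[tab$region == "cortex" & tab$pool == "glutamate" &
               tab$arm == "baseline", "contrast"]
  expect_equal(s$mean[s$arm == "baseline"], mean(one))
  expect_equal(s$sem[s$arm == "baseline"], sem(one))
})

test_that("missing arms skip their comparisons with a warning", {
  tab <- simulate_group_table(tiny_phantom_config(), seed = 4L)
  tab <- tab[tab$arm != "wk12_art", ]
  tab <- tab[tab$region == "cortex" & tab$pool == "glutamate", ]
  expect_warning(out <- comparison_suite(tab), "missing arm")
  expect_false("wk12_art vs wk12_vehicle" %in% out$tests$comparison)
  expect_true("baseline vs wk12_vehicle" %in% out$tests$comparison)
})

test_that("paired mode pairs equal-size arms and falls back otherwise", {
  cfg <- tiny_phantom_config(n = 4L)
  tab <- simulate_group_table(cfg, seed = 9L)
  tab <- tab[tab$region == "cortex" & tab$pool == "creatine", ]
  out <- suppressWarnings(comparison_suite(tab, paired = TRUE))
  expect_equal(out$tests$variant[out$tests$comparison == "baseline vs wk6"],
               "paired")
  a <- tab$contrast[tab$arm == "baseline"]
  b <- tab$contrast[tab$arm == "wk6"]
  ref <- stats::t.test(a, b, paired = TRUE)
  expect_equal(out$tests$p[out$tests$comparison == "baseline vs wk6"],
               ref$p.value)
})

test_that("holm adjustment only ever increases p-values", {
  tab <- simulate_group_table(tiny_phantom_config(), seed = 12L)
  raw <- comparison_suite(tab)
  adj <- comparison_suite(tab, adjust = "holm")
  expect_true(all(adj$tests$p >= raw$tests$p - 1e-12, na.rm = TRUE))
})
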