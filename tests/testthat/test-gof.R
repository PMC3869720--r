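test_that("the deviation statistic matches hand computation and its symmetries", {
  # three curves on r = {0, 1}, dr = 1: the first deviates by 2 at r = 1
  u <- u_statistic(rbind(c(0, 2), c(0, 0), c(0, 0)), dr = 1)
  expect_equal(u, c(4, 1, 1))
  # a curve equal to the mean of the others has u = 0
  curves <- rbind(c(1, 2, 3), c(0, 0, 0), c(2, 4, 6))
  expect_equal(u_statistic(curves, dr = 0.5)[1], 0)
  # homogeneity: scaling all curves by c scales u by c^2
  set.seed(3)
  m <- matrix(rnorm(15), 5, 3)
  expect_equal(u_statistic(3 * m, dr = 0.25), 9 * u_statistic(m, dr = 0.25))
  # invariance to adding a constant to all curves
  expect_equal(u_statistic(m + 7, dr = 0.25), u_statistic(m, dr = 0.25))
  expect_error(u_statistic(m[1:2, ], dr = 1), "nrow")
})

test_that("gof p-values are rank-based with the documented floor and are reproducible", {
  w <- plot_window(100, 100)
  pp <- simulate_csr(40, w, 17)
  g1 <- gof_test(pp, "univariate", "csr", n_sim = 99, r_max = 9, seed = 23)
  g2 <- gof_test(pp, "univariate", "csr", n_sim = 99, r_max = 9, seed = 23)
  expect_identical(g1$p_value, g2$p_value)
  expect_gte(g1$p_value, 1 / 100)
  expect_equal(g1$p_value,
               (1 + sum(g1$u_simulated >= g1$u_observed)) / 100)
  # a strongly clustered pattern hits the floor at n_sim = 99
  clus <- simulate_matern_fixed_n(80, w, 3, kappa = 8e-4, mu = 10, seed = 5)
  expect_equal(gof_test(clus, "univariate", "csr", n_sim = 99, seed = 2)$p_value,
               0.01)
})

test_that("p-values under a true null are discrete-uniform", {
  w <- plot_window(100, 100)
  seeds <- substream_seeds(101, 600)
  p <- vapply(1:300, function(k) {
    pp <- simulate_csr(25, w, seeds[2 * k - 1])
    gof_test(pp, "univariate", "csr", n_sim = 99, r_max = 9,
             seed = seeds[2 * k])$p_value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_equal(mean(p <= 0.05), 0.05, tolerance = 0.05)
})

test_that("Bonferroni thresholds and battery decisions follow alpha / m", {
  expect_equal(bonferroni_threshold(0.05, 12), 0.05 / 12)
  expect_equal(round(bonferroni_threshold(0.05, 12), 3), 0.004)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.10, 4), 0.025)
  expect_error(bonferroni_threshold(1.2, 3))
  w <- plot_window(100, 100)
  res <- list(a = gof_test(simulate_csr(30, w, 1), n_sim = 19, seed = 2),
              b = gof_test(simulate_csr(30, w, 3), n_sim = 19, seed = 4))
  bat <- test_battery(res, alpha = 0.05)
  expect_equal(bat$threshold, rep(0.025, 2))
  expect_equal(bat$reject, bat$p_value <= 0.025)
})

test_that("power against a hard-core alternative behaves like a size/power curve", {
  w <- plot_window(800, 320)
  # radius 0: the null is true, rejection rate ~ alpha
  p0 <- power_vs_hardcore(93, w, 0, n_experiments = 20, n_sim = 49, seed = 41)
  expect_lte(p0$power, 0.25)
  # at the reference intensity (93 large hemlocks in 25.6 ha) a hard core
  # at the observed inhibition scale (~6 m) is indistinguishable from CSR
  p6 <- power_vs_hardcore(93, w, 6, n_experiments = 20, n_sim = 49,
                          seed = 43)
  expect_lt(p6$power, 0.5)
  # a blatant hard core at high intensity is detected more often than size
  p_strong <- power_vs_hardcore(300, w, 15, n_experiments = 10, n_sim = 49,
                                seed = 47)
  expect_gte(p_strong$power, p0$power)
})

test_that("gof results export to JSON losslessly", {
  w <- plot_window(100, 100)
  g <- gof_test(simulate_csr(30, w, 1), n_sim = 19, seed = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_gof_result(g, path)
  back <- jsonlite::fromJSON(path)
  expect_equal(back$u_observed, g$u_observed)
  expect_equal(back$p_value, g$p_value)
})
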