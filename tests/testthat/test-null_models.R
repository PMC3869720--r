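test_that("CSR simulation is uniform, at the requested count, and reproducible", {
  w <- plot_window(800, 320)
  expect_equal(npoints(simulate_csr(0, w, 1)), 0L)
  p <- simulate_csr(10000, w, 2)
  expect_lt(abs(mean(p$x) - 400), 3 * (800 / sqrt(12)) / 100)
  expect_lt(abs(mean(p$y) - 160), 3 * (320 / sqrt(12)) / 100)
  # quadrant counts ~ multinomial(n, 1/4 each)
  quad <- table(p$x > 400, p$y > 160)
  expect_gt(chisq.test(as.vector(quad))$p.value, 0.01)
  expect_identical(simulate_csr(50, w, 7)$x, simulate_csr(50, w, 7)$x)
})

test_that("toroidal shifts wrap, preserve intratype structure, and compose", {
  w <- plot_window(800, 320)
  p1 <- point_pattern(600, 100, w)
  expect_equal(toroidal_shift(p1, 400, 0)$x, 200)
  p <- simulate_csr(20, w, 3)
  p$marks <- rep(c("large", "small"), 10)
  expect_equal(toroidal_shift(p, 0, 0, "large"), p)
  sh <- toroidal_shift(p, 123.4, 56.7, "large")
  ia <- p$marks == "large"
  expect_equal(sort(toroidal_dist(sh$x[ia], sh$y[ia], 800, 320)),
               sort(toroidal_dist(p$x[ia], p$y[ia], 800, 320)))
  expect_identical(sh$x[!ia], p$x[!ia])
  # composition = shift of the summed vector (mod window)
  two <- toroidal_shift(toroidal_shift(p, 500, 200, "large"), 700, 300, "large")
  one <- toroidal_shift(p, (500 + 700) %% 800, (200 + 300) %% 320, "large")
  expect_equal(two$x, one$x)
  expect_equal(two$y, one$y)
  expect_error(toroidal_shift(p, 800, 0, "large"), "dx")
})

test_that("envelopes are reproducible and bracket their generating null", {
  w <- plot_window(100, 100)
  pp <- simulate_csr(40, w, 11)
  g <- r_grid(9, 30)
  e1 <- make_envelope(pp, "univariate", "csr", n_sim = 39, grid = g, seed = 5)
  e2 <- make_envelope(pp, "univariate", "csr", n_sim = 39, grid = g, seed = 5)
  expect_identical(e1$sims, e2$sims)
  # a CSR pattern lies inside the pointwise band nearly everywhere
  inside <- mean(e1$empirical >= e1$lo & e1$empirical <= e1$hi)
  expect_gt(inside, 0.8)
  expect_error(make_envelope(pp, "univariate", "independence", grid = g),
               "CSR null")
  expect_error(make_envelope(pp, "bivariate", "csr", grid = g),
               "independence")
})

test_that("a regular grid falls below the CSR band at small distances", {
  w <- plot_window(100, 100)
  gx <- seq(5, 95, by = 10)
  grid_pp <- point_pattern(rep(gx, 10), rep(gx, each = 10), w)
  g <- r_grid(9, 30)
  env <- make_envelope(grid_pp, "univariate", "csr", n_sim = 99, grid = g,
                       seed = 8)
  at8 <- findInterval(8, g$r)
  expect_lt(env$empirical[at8], env$lo[at8])
})

test_that("under independence the empirical curve rarely leaves the band", {
  w <- plot_window(200, 200)
  set.seed(42)
  pp <- point_pattern(runif(120, 0, 200), runif(120, 0, 200), w,
                      marks = rep(c("large", "small"), 60))
  g <- r_grid(9, 30)
  env <- make_envelope(pp, "bivariate", "independence", n_sim = 99, grid = g,
                       seed = 13)
  outside <- mean(env$empirical < env$lo | env$empirical > env$hi)
  expect_lt(outside, 0.15)
})

test_that("full envelope exports reconstruct the identical test", {
  w <- plot_window(100, 100)
  pp <- simulate_csr(30, w, 21)
  g <- r_grid(9, 30)
  env <- make_envelope(pp, "univariate", "csr", n_sim = 49, grid = g,
                       seed = 31)
  path <- withr::local_tempfile(fileext = ".csv")
  write_envelope(env, path, full = TRUE)
  back <- read_envelope(path)
  expect_equal(gof_from_envelope(back)$p_value,
               gof_from_envelope(env)$p_value)
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_envelope(env, path2)
  expect_error(read_envelope(path2), "full")
})
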