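test_that("pairwise distances match the closed form and flag duplicates", {
  w <- plot_window(100, 100)
  pp <- point_pattern(c(0, 3), c(0, 4), w)
  expect_equal(pairwise_distances(pp)[1, 2], 5)
  dup <- point_pattern(c(1, 1), c(2, 2), w)
  expect_warning(d <- pairwise_distances(dup), "duplicated")
  expect_equal(d[1, 2], 0)
  expect_error(pairwise_distances(point_pattern(1, 1, w)), "two points")
  set.seed(31)
  pp2 <- point_pattern(runif(60, 0, 100), runif(60, 0, 100), w)
  D <- pairwise_distances(pp2)
  i <- sample(60, 20, replace = TRUE); j <- sample(60, 20, replace = TRUE)
  expect_equal(D[cbind(i, j)],
               sqrt((pp2$x[i] - pp2$x[j])^2 + (pp2$y[i] - pp2$y[j])^2))
})

test_that("isotropic edge weights hit the interior/edge/corner closed forms", {
  w <- plot_window(100, 100)
  expect_equal(isotropic_edge_weight(50, 50, 10, w), 1)
  expect_equal(isotropic_edge_weight(0, 50, 10, w), 2)
  expect_equal(isotropic_edge_weight(0, 0, 10, w), 4)
  expect_equal(isotropic_edge_weight(50, 0, 10, w), 2)
  expect_equal(isotropic_edge_weight(100, 100, 10, w), 4)
  expect_error(isotropic_edge_weight(50, 50, 0, w), "positive")
})

test_that("the analytic arc fraction agrees with numeric integration everywhere", {
  set.seed(7)
  W <- 800; H <- 320
  x <- runif(60, 0, W); y <- runif(60, 0, H); d <- runif(60, 0.5, H)
  fa <- stemspat:::arc_fraction_analytic(x, y, d, W, H)
  fo <- vapply(seq_along(x), function(i)
    arc_fraction_oracle(x[i], y[i], d[i], W, H), numeric(1))
  expect_equal(fa, fo, tolerance = 1e-3)
  # including points on edges and corners at a range of radii
  for (d0 in c(1, 50, 150, 319)) {
    expect_equal(stemspat:::arc_fraction_analytic(0, 160, d0, W, H),
                 arc_fraction_oracle(0, 160, d0, W, H), tolerance = 1e-3)
    expect_equal(stemspat:::arc_fraction_analytic(5, 5, d0, W, H),
                 arc_fraction_oracle(5, 5, d0, W, H), tolerance = 1e-3)
  }
})

test_that("ripley_K matches closed forms and the brute-force oracle", {
  w <- plot_window(100, 100)
  # two interior points 5 m apart: K jumps from 0 to |A|
  pp <- point_pattern(c(40, 45), c(50, 50), w)
  K <- ripley_K(pp, r_grid(20, 80))
  expect_equal(K$values[K$grid$r < 5], rep(0, sum(K$grid$r < 5)))
  expect_equal(K$values[K$grid$r >= 5], rep(1e4, sum(K$grid$r >= 5)))
  expect_true(all(diff(K$values) >= 0))
  # brute-force equivalence on a random pattern, including edge-affected pairs
  set.seed(12)
  pp2 <- point_pattern(runif(35, 0, 100), runif(35, 0, 100), w)
  g <- r_grid(25, 10)
  expect_equal(ripley_K(pp2, g)$values, brute_force_K(pp2, g$r),
               tolerance = 1e-4)
  expect_error(ripley_K(pp2, r_grid(60, 10)), "half the shorter")
  expect_error(ripley_K(point_pattern(1, 1, w)), "two points")
})

test_that("L transform linearizes K with the CSR zero", {
  w <- plot_window(100, 100)
  g <- r_grid(10, 10)
  csr_K <- summary_curve(g, pi * g$r^2, scale = "K")
  expect_equal(L_transform(csr_K)$values, rep(0, length(g$r)))
  flat <- summary_curve(g, rep(0, length(g$r)), scale = "K")
  expect_equal(L_transform(flat)$values[g$r == 5], -5)
  big <- summary_curve(g, rep(100 * pi, length(g$r)), scale = "K")
  expect_equal(L_transform(big)$values[g$r == 5], 5)
})

test_that("bivariate K12 obeys its closed forms and the random-labeling identity", {
  w <- plot_window(100, 100)
  g <- r_grid(20, 40)
  pp <- point_pattern(c(40, 45), c(50, 50), w, marks = c("large", "small"))
  K12 <- ripley_K12(pp, g)
  expect_equal(K12$values, ifelse(g$r >= 5, 1e4, 0))
  expect_error(ripley_K12(point_pattern(1, 1, w, marks = "large"), g),
               "at least one point")
  # coincident type sets: strong attraction at small r
  xy <- simulate_csr(30, w, 5)
  both <- point_pattern(c(xy$x, xy$x), c(xy$y, xy$y), w,
                        marks = rep(c("large", "small"), each = 30))
  L12 <- L_transform(ripley_K12(both, g))
  expect_gt(L12$values[findInterval(2, g$r)], 5)
  # randomly labeled CSR: E[K12] equals E[K] of the pooled pattern
  set.seed(77)
  diffs <- replicate(40, {
    p <- simulate_csr(60, w)
    m <- sample(rep(c("large", "small"), 30))
    lab <- point_pattern(p$x, p$y, w, marks = m)
    k12 <- ripley_K12(lab, g)$values
    k <- ripley_K(p, g)$values
    mean(k12 - k)
  })
  expect_lt(abs(mean(diffs)), 40)  # K scale, m^2; CSR K(20) ~ 1250
})

test_that("summary curves survive CSV export with metadata", {
  w <- plot_window(100, 100)
  pp <- simulate_csr(25, w, 3)
  cv <- L_transform(ripley_K(pp, r_grid(20, 40)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_summary_curve(cv, path)
  meta <- jsonlite::fromJSON(sub("^# ", "", readLines(path, n = 1)))
  expect_equal(meta$scale, "L")
  back <- utils::read.csv(path, skip = 1)
  expect_equal(back$value, cv$values, tolerance = 1e-9)
})
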