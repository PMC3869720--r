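test_that("sequential inhibition respects the minimum distance and exact count", {
  w <- plot_window(100, 100)
  p <- simulate_ssi(2, w, 20, seed = 1)
  expect_gte(min(dist(cbind(p$x, p$y))), 20)
  p2 <- simulate_ssi(60, w, 8, seed = 2)
  expect_equal(npoints(p2), 60L)
  expect_gte(min(dist(cbind(p2$x, p2$y))), 8)
  expect_identical(simulate_ssi(30, w, 5, seed = 9)$x,
                   simulate_ssi(30, w, 5, seed = 9)$x)
  # infeasible packing aborts with a packing error naming the shortfall
  expect_error(simulate_ssi(10, plot_window(10, 10), 20, seed = 1,
                            max_attempts = 200),
               "packing failed")
  # radius 0 is distributionally CSR
  p0 <- simulate_ssi(2000, w, 0, seed = 3)
  quad <- table(p0$x > 50, p0$y > 50)
  expect_gt(chisq.test(as.vector(quad))$p.value, 0.01)
})

test_that("the Matern simulator returns exactly n clustered in-window points", {
  w <- plot_window(800, 320)
  for (R in c(10, 20)) {
    p <- simulate_matern_fixed_n(451, w, R, seed = R)
    expect_equal(npoints(p), 451L)
    expect_true(all(p$x >= 0 & p$x <= 800 & p$y >= 0 & p$y <= 320))
  }
  expect_identical(simulate_matern_fixed_n(50, w, 15, seed = 4)$x,
                   simulate_matern_fixed_n(50, w, 15, seed = 4)$x)
  # clustering signature: mean centered L positive below the cluster radius
  g <- r_grid(15, 30)
  lbar <- rowMeans(vapply(1:10, function(k) {
    p <- simulate_matern_fixed_n(300, w, 10, seed = 100 + k)
    L_transform(ripley_K(p, g))$values
  }, numeric(length(g$r))))
  expect_gt(lbar[findInterval(8, g$r)], 0)
})

test_that("jitter randomization reflects at boundaries and conserves counts", {
  w <- plot_window(100, 50)
  ref <- simulate_csr(40, w, 6)
  expect_equal(simulate_randomized(ref, "jitter", jitter_radius = 0, seed = 1),
               ref)
  j <- simulate_randomized(ref, "jitter", jitter_radius = 10, seed = 2)
  expect_equal(npoints(j), 40L)
  expect_true(all(j$x >= 0 & j$x <= 100 & j$y >= 0 & j$y <= 50))
  expect_true(all(sqrt((j$x - ref$x)^2 + (j$y - ref$y)^2) <= 20 + 1e-9))
  expect_error(simulate_randomized(ref, "jitter"), "jitter_radius")
  r <- simulate_randomized(ref, "resample_csr", seed = 3)
  expect_equal(npoints(r), 40L)
  # jitter with a radius beyond the diagonal scrambles to uniformity
  big <- simulate_randomized(ref, "jitter", jitter_radius = 500, seed = 4)
  expect_equal(npoints(big), 40L)
})

test_that("the seven levels order by mean nearest-neighbor distance", {
  w <- plot_window(800, 320)
  res <- sapply(pattern_levels(), function(l) {
    mean(vapply(1:8, function(k)
      mean_nn(simulate_pattern_level(l, 451, w, seed = 600 + k)), numeric(1)))
  })
  expect_true(all(diff(res) < 0))
  expect_error(simulate_pattern_level("thomas-5", 10, w))
})

test_that("coupled level simulation reproduces each family's marginal behavior", {
  w <- plot_window(800, 320)
  pats <- simulate_coupled_levels(pattern_levels(), 100, w, seed = 55)
  expect_named(pats, pattern_levels())
  for (lv in pattern_levels()) expect_equal(npoints(pats[[lv]]), 100L)
  expect_gte(min(dist(cbind(pats[["ssi-20"]]$x, pats[["ssi-20"]]$y))), 20)
  expect_gte(min(dist(cbind(pats[["ssi-10"]]$x, pats[["ssi-10"]]$y))), 10)
  # the coupled CSR level is exactly uniform (it accepts every proposal)
  big <- simulate_coupled_levels("random", 2000, w, seed = 66)$random
  quad <- table(big$x > 400, big$y > 160)
  expect_gt(chisq.test(as.vector(quad))$p.value, 0.01)
  # coupling: the random level shares most points with weakly inhibited ssi
  pats2 <- simulate_coupled_levels(c("ssi-10", "random"), 100, w, seed = 77)
  shared <- length(intersect(round(pats2[["ssi-10"]]$x, 9),
                             round(pats2$random$x, 9)))
  expect_gt(shared, 50)
  # determinism
  again <- simulate_coupled_levels(pattern_levels(), 100, w, seed = 55)
  expect_equal(pats, again)
})
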