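test_that("cv_skewness matches hand-computed moments and e1071", {
  expect_equal(cv_skewness(c(1, 1, 1)), c(cv = 0, skewness = 0))
  # values (0, 0, 3): sd = sqrt(3), mean = 1, m2 = 2, m3 = 2
  expect_equal(cv_skewness(c(0, 0, 3)),
               c(cv = sqrt(3), skewness = 2 / 2^1.5))
  set.seed(14)
  x <- rexp(200)
  expect_equal(unname(cv_skewness(x)["skewness"]),
               e1071::skewness(x, type = 1))
  expect_equal(unname(cv_skewness(x, bias_correct = TRUE)["skewness"]),
               e1071::skewness(x, type = 2))
  # adding a constant decreases CV, scaling leaves both unchanged
  expect_lt(cv_skewness(x + 5)["cv"], cv_skewness(x)["cv"])
  expect_equal(cv_skewness(4 * x), cv_skewness(x))
  expect_error(cv_skewness(c(0, 0, 0)), "positive mean")
  expect_error(cv_skewness(c(1, 2)), "n >= 3")
})

test_that("the permutation experiment conserves basal area and fixes small trees", {
  map <- generate_forest(default_wfdp_spec(scale = 0.05), seed = 16)
  tb <- run_experiment(map, levels = c("random", "matern-10"), n_real = 4,
                       seed = 17)
  expect_equal(nrow(tb), 2 * 4 * 4 + 4)   # levels x reals x grains + empirical
  # identical total basal area in every realization at a fixed grain
  # (CV and skewness are scale-free, so equality of CV across realizations
  # with different placements plus the invariants below pin conservation)
  parts <- split_by_diameter(map)
  total <- sum(basal_area(c(parts$large$dbh, parts$small$dbh)))
  q <- quadrat_statistics(map, 400,
                          subset = function(s) s$status == "live" &
                            s$growth_form == "tree")
  expect_equal(sum(q$table$ba_m2), total)
  # doubling all dbh (and the split threshold, so the partition is the
  # same trees) quadruples basal area but leaves CV and skewness as-is
  map2 <- map
  map2$stems$dbh <- map2$stems$dbh * 2
  tb2 <- run_experiment(map2, levels = c("random", "matern-10"), n_real = 4,
                        threshold = 200, seed = 17)
  expect_equal(tb2$cv, tb$cv)
  expect_equal(tb2$skewness, tb$skewness)
  # determinism under a fixed seed
  tb3 <- run_experiment(map, levels = c("random", "matern-10"), n_real = 4,
                        seed = 17)
  expect_equal(tb3, tb)
})

test_that("the experiment refuses maps without large trees and bad grains", {
  w <- plot_window(800, 320)
  st <- data.frame(tag = paste0("s", 1:30), species = "TSHE",
                   x = runif(30, 0, 800), y = runif(30, 0, 320),
                   dbh = runif(30, 5, 50), status = "live",
                   stringsAsFactors = FALSE)
  small_only <- stem_map(st, w)
  expect_error(run_experiment(small_only), "large")
  map <- generate_forest(default_wfdp_spec(scale = 0.05), seed = 19)
  expect_error(run_experiment(map, grains = 300), "tile")
})

test_that("empirical departure ranks the unpermuted map within the null cloud", {
  map <- generate_forest(default_wfdp_spec(scale = 0.1), seed = 20)
  tb <- run_experiment(map, levels = "random", n_real = 39,
                       grains = c(400, 6400), seed = 21)
  dep <- empirical_departure(tb)
  expect_equal(nrow(dep), 2L)
  expect_true(all(dep$cv_pct >= 0 & dep$cv_pct <= 100))
  expect_error(empirical_departure(tb, level = "matern-10"), "not present")
  # CSR-generated large trees land mid-cloud far more often than not
  single <- empirical_departure(tb[tb$grain_m2 == 400, , drop = FALSE])
  expect_equal(nrow(single), 1L)
})

test_that("a planted intensity gradient elevates CV departure at the largest grain", {
  spec <- default_wfdp_spec(scale = 0.1)
  hits <- vapply(1:6, function(s) {
    pair <- generate_pair(spec, seed = 800 + s)
    tb <- run_experiment(pair$gradient, levels = "random", n_real = 49,
                         grains = 6400, seed = 900 + s)
    empirical_departure(tb)$cv_pct
  }, numeric(1))
  expect_gt(mean(hits), 60)
  # matched pair shares its small-tree layer exactly
  pair <- generate_pair(spec, seed = 801)
  sm_g <- split_by_diameter(pair$gradient)$small
  sm_h <- split_by_diameter(pair$homogeneous)$small
  expect_equal(sm_g$x, sm_h$x)
  expect_equal(sm_g$dbh, sm_h$dbh)
})
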