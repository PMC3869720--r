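test_that("stem-map files round-trip and invalid rows are rejected with diagnostics", {
  w <- plot_window(100, 50)
  map <- stem_map(tiny_stems(), w)
  path <- withr::local_tempfile(fileext = ".csv")
  write_stem_map(map, path)
  back <- read_stem_map(path, w)
  expect_equal(back$stems, map$stems)

  bad_dbh <- tiny_stems(); bad_dbh$dbh[1] <- 0.5
  expect_error(stem_map(bad_dbh, w), "tagging threshold")
  out_of_window <- tiny_stems(); out_of_window$x[2] <- 105
  expect_error(stem_map(out_of_window, w), "t2")
  dup <- rbind(tiny_stems(), tiny_stems()[1, ])
  expect_error(stem_map(dup, w), "duplicate tag")
  expect_error(
    read_stem_map(withr::local_tempfile(lines = "tag,species,x", fileext = ".csv"), w),
    "required column")
  snag <- tiny_stems(); snag$status[3] <- "snag"; snag$dbh[3] <- 9
  expect_error(stem_map(snag, w), "snag below")
})

test_that("basal area follows the closed form and rejects non-positive dbh", {
  expect_equal(basal_area(100), pi * 0.25)
  expect_equal(basal_area(200 / sqrt(pi)), 1)
  expect_equal(basal_area(c(10, 20)), pi * c(0.05, 0.1)^2)
  expect_error(basal_area(0), "positive")
  expect_error(basal_area(-3), "positive")
})

test_that("diameter histograms use a [1,5) first bin and half-open classes", {
  w <- plot_window(100, 50)
  st <- tiny_stems()[rep(1, 3), ]
  st$tag <- paste0("t", 1:3)
  st$dbh <- c(1, 4.9, 5.0)
  h <- diameter_distribution(stem_map(st, w), "TSHE", bin_width = 5)
  expect_equal(h$count[1:2], c(2, 1))
  expect_equal(sum(h$count), 3)
  expect_equal(sum(h$basal_area), sum(basal_area(st$dbh)))
  expect_error(diameter_distribution(stem_map(st, w), "XXXX"), "not present")
})

test_that("quadrat statistics conserve totals, use the corner convention, and nest across grains", {
  map <- generate_forest(default_wfdp_spec(scale = 0.02), seed = 4)
  total_ba <- sum(basal_area(map$stems$dbh[map$stems$status == "live"]))
  for (grain in c(100, 400, 1600, 6400)) {
    q <- quadrat_statistics(map, grain)
    expect_equal(sum(q$table$ba_m2), total_ba)
    expect_equal(sum(q$table$count),
                 sum(map$stems$status == "live"))
  }
  # 2x2 blocks of the 400 m2 grid aggregate to the 1600 m2 grid
  q400 <- quadrat_statistics(map, 400)$table
  q1600 <- quadrat_statistics(map, 1600)$table
  agg <- aggregate(ba_m2 ~ bx + by,
                   transform(q400, bx = qx %/% 2, by = qy %/% 2), sum)
  agg <- agg[order(agg$by, agg$bx), ]
  expect_equal(agg$ba_m2, q1600$ba_m2)

  # stem on the southwest corner belongs to quadrat (0, 0)
  w <- plot_window(800, 320)
  st <- data.frame(tag = "c", species = "TSHE", x = 0, y = 0, dbh = 10,
                   status = "live", stringsAsFactors = FALSE)
  q <- quadrat_statistics(stem_map(st, w), 400)
  expect_equal(q$table$count[q$table$qx == 0 & q$table$qy == 0], 1L)
  # far-edge stem is clamped into the last quadrat, not dropped
  st$x <- 800; st$y <- 320
  q <- quadrat_statistics(stem_map(st, w), 400)
  expect_equal(sum(q$table$count), 1L)
  expect_error(quadrat_statistics(stem_map(st, w), 300), "tile")
})

test_that("split_by_diameter partitions live trees with an inclusive threshold", {
  map <- generate_forest(default_wfdp_spec(scale = 0.02), seed = 5)
  parts <- split_by_diameter(map)
  live_trees <- map$stems[map$stems$status == "live" &
                            map$stems$growth_form == "tree", ]
  expect_equal(nrow(parts$large) + nrow(parts$small), nrow(live_trees))
  expect_true(all(parts$large$dbh >= 100))
  expect_true(all(parts$small$dbh < 100))
  w <- plot_window(100, 50)
  st <- tiny_stems(); st$dbh[3] <- 100    # exactly at the threshold
  expect_equal(nrow(split_by_diameter(stem_map(st, w))$large), 1L)
})
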