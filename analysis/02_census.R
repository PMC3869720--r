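#!/usr/bin/env Rscript
# Census summarization: the published-table arithmetic on the reference
# fixture, plus the census of the synthetic map from 01_generate_forest.R
# (species x diameter-threshold counts, basal areas, large-diameter
# proportions), diameter histograms for the three principal conifers, and
# 20 m quadrat summaries. Tables land under results/census/.

library(stemspat)

out_dir <- "results/census"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

# 1. Reference-table arithmetic (the validation surface for summarize_census)
fx <- reference_census_fixture()
cs_ref <- summarize_census(fx)
utils::write.csv(format_census(cs_ref),
                 file.path(out_dir, "census_reference.csv"),
                 row.names = FALSE)
grand <- cs_ref[cs_ref$population == "live woody total", ]
cat(sprintf("reference census: %d live stems, %.2f m2/ha; large-diameter %.1f%% of stems, %.1f%% of basal area\n",
            grand$n_ge1, grand$ba_ge1, grand$large_stem_prop,
            grand$large_ba_prop))

# 2. Synthetic-map census
map_path <- "results/maps/wfdp_synthetic_10pct.csv"
if (!file.exists(map_path)) stop("run analysis/01_generate_forest.R first")
map <- read_stem_map(map_path, plot_window(800, 320))
cs <- summarize_census(map)
utils::write.csv(format_census(cs),
                 file.path(out_dir, "census_synthetic.csv"),
                 row.names = FALSE)

# 3. Diameter distributions of the three principal species
for (sp in c("PSME", "TSHE", "THPL")) {
  h <- diameter_distribution(map, sp, bin_width = 5)
  utils::write.csv(h, file.path(out_dir, sprintf("dbh_hist_%s.csv", sp)),
                   row.names = FALSE)
}

# 4. Quadrat summaries at the four grains
for (grain in c(100, 400, 1600, 6400)) {
  q <- quadrat_statistics(map, grain)
  utils::write.csv(q$table,
                   file.path(out_dir, sprintf("quadrats_%dm2.csv", grain)),
                   row.names = FALSE)
}
q400 <- quadrat_statistics(map, 400)
cv <- stats::sd(q400$table$ba_m2) / mean(q400$table$ba_m2)
cat(sprintf("synthetic map: %d quadrats at 400 m2, basal-area CV %.2f\n",
            nrow(q400$table), cv))
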