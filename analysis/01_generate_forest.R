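#!/usr/bin/env Rscript
# Generate the synthetic stem maps used by the downstream analyses: a
# desk-scale (10%) map of the old-growth Pseudotsuga/Tsuga reference stand,
# and a matched pair differing only in the first-order intensity of the
# large-diameter trees (log-linear west-east gradient vs homogeneous).
# Writes stem-map CSVs plus provenance sidecars under results/maps/.

library(stemspat)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 20120801L
out_dir <- "results/maps"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

spec <- default_wfdp_spec(scale = 0.1)
map <- generate_forest(spec, seed = seed)
write_stem_map(map, file.path(out_dir, "wfdp_synthetic_10pct.csv"))

pair <- generate_pair(spec, seed = seed)
write_stem_map(pair$gradient, file.path(out_dir, "pair_gradient.csv"))
write_stem_map(pair$homogeneous, file.path(out_dir, "pair_homogeneous.csv"))

for (nm in c("wfdp_synthetic_10pct", "pair_gradient", "pair_homogeneous")) {
  m <- switch(nm, wfdp_synthetic_10pct = map,
              pair_gradient = pair$gradient, pair_homogeneous = pair$homogeneous)
  jsonlite::write_json(
    list(seed = seed, spec_digest = attr(m, "spec_digest"),
         n_stems = nrow(m$stems),
         n_large = nrow(split_by_diameter(m)$large)),
    file.path(out_dir, paste0(nm, ".json")), auto_unbox = TRUE)
}

parts <- split_by_diameter(map)
cat(sprintf("generated %d stems (%d live) with %d large-diameter trees; seed %d\n",
            nrow(map$stems), sum(map$stems$status == "live"),
            nrow(parts$large), seed))
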