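#' Published census targets for the Wind River old-growth reference stand
#'
#' Per-species, per-diameter-class stem counts and basal-area targets for
#' the 25.6 ha Wind River reference census (800 m x 320 m): 30,973 live
#' stems >= 1 cm dbh of 26 woody species, 1,966 snags >= 10 cm, 62.18
#' m^2/ha of live basal area, with 1.5% of stems and 31.8% of basal area in
#' the large-diameter (>= 100 cm) class. Counts are exact. Published
#' per-species basal areas are independently rounded to 0.01 m^2/ha and do
#' not sum exactly to the published totals, so class targets here are chosen
#' within half an ULP of each printed species value such that species values
#' AND group totals all reproduce at printed precision; classes whose
#' printed basal area is 0.00 (below printed precision) carry a nominal
#' small dbh instead of a basal-area target.
#'
#' @return A data frame with columns `species`, `population`, `class_lo`,
#'   `class_hi` (cm), `count`, `ba_ha` (m^2/ha target, or NA for
#'   below-precision classes), `dbh_fixed` (used when `ba_ha` is NA).
#' @seealso [reference_census_fixture()]
#' @export
reference_census_targets <- function() {
  r <- function(species, population, class_lo, class_hi, count, ba_ha,
                dbh_fixed = NA_real_) {
    data.frame(species = species, population = population,
               class_lo = class_lo, class_hi = class_hi, count = count,
               ba_ha = ba_ha, dbh_fixed = dbh_fixed,
               stringsAsFactors = FALSE)
  }
  rbind(
    # live trees
    r("TSHE", "live tree",   1,  10, 4849,  0.3691),
    r("TSHE", "live tree",  10, 100, 4987, 30.3060),
    r("TSHE", "live tree", 100, 400,   93,  3.4100),
    r("ABAM", "live tree",   1,  10, 3447,  0.2365),
    r("ABAM", "live tree",  10, 100,  983,  1.9680),
    r("ABAM", "live tree", 100, 400,    1,  0.0335),
    r("TABR", "live tree",   1,  10,  715,  0.1155),
    r("TABR", "live tree",  10, 100, 1326,  1.5600),
    r("PSME", "live tree",   1,  10,    3, NA, 5),
    r("PSME", "live tree",  10, 100,  261,  5.3160),
    r("PSME", "live tree", 100, 400,  308, 13.8200),
    r("THPL", "live tree",   1,  10,   21, NA, 4),
    r("THPL", "live tree",  10, 100,  133,  1.4160),
    r("THPL", "live tree", 100, 400,   47,  2.4600),
    r("CONU", "live tree",   1,  10,  131,  0.0200),
    r("CONU", "live tree",  10, 100,   41,  0.0200),
    r("ABGR", "live tree",   1,  10,   15, NA, 5),
    r("ABGR", "live tree",  10, 100,   36,  0.2400),
    r("ALRU", "live tree",   1,  10,   12, NA, 2),
    r("ALRU", "live tree",  10, 100,    4,  0.0100),
    r("ABPR", "live tree",   1,  10,    1, NA, 5),
    r("ABPR", "live tree",  10, 100,   11,  0.1700),
    r("PIMO", "live tree",  10, 100,    4,  0.0476),
    r("PIMO", "live tree", 100, 400,    2,  0.0800),
    # tall shrubs
    r("ACCI", "tall shrub",  1,  10, 10991, 0.5170),
    r("ACCI", "tall shrub", 10, 100,    90, 0.0400),
    r("VAPA", "tall shrub",  1,  10,  1250, 0.0051),
    r("COCO", "tall shrub",  1,  10,   628, 0.0051),
    r("RHMA", "tall shrub",  1,  10,   458, 0.0100),
    r("VAOV", "tall shrub",  1,  10,    59, NA, 1.2),
    r("HODI", "tall shrub",  1,  10,    19, NA, 1.2),
    r("MEFE", "tall shrub",  1,  10,    17, NA, 1.2),
    r("GASH", "tall shrub",  1,  10,    13, NA, 1.2),
    r("AMAL", "tall shrub",  1,  10,     8, NA, 1.2),
    r("OECE", "tall shrub",  1,  10,     3, NA, 1.2),
    r("ACGL", "tall shrub",  1,  10,     1, NA, 1.2),
    r("ROGY", "tall shrub",  1,  10,     1, NA, 1.2),
    r("RULE", "tall shrub",  1,  10,     1, NA, 1.2),
    r("RUSP", "tall shrub",  1,  10,     1, NA, 1.2),
    r("VAME", "tall shrub",  1,  10,     1, NA, 1.2),
    # liana
    r("LOCI", "liana",       1,  10,     1, NA, 1.2),
    # snags
    r("PSME", "snag",  10, 100,  668,  9.2355),
    r("PSME", "snag", 100, 400,  118,  5.1045),
    r("TSHE", "snag",  10, 100,  381,  3.1885),
    r("TSHE", "snag", 100, 400,   18,  0.7015),
    r("TABR", "snag",  10, 100,  302,  0.2655),
    r("ABAM", "snag",  10, 100,  175,  0.7000),
    r("PIMO", "snag",  10, 100,   56,  0.8586),
    r("PIMO", "snag", 100, 400,    6,  0.2214),
    r("ABGR", "snag",  10, 100,   31,  0.2300),
    r("THPL", "snag",  10, 100,   26,  0.1225),
    r("THPL", "snag", 100, 400,    1,  0.0345),
    r("ACCI", "snag",  10, 100,    7, NA, 10.2),
    r("CONU", "snag",  10, 100,    3, NA, 10.2),
    r("ABSP", "snag",  10, 100,    2,  0.0100),
    r("ABPR", "snag", 100, 400,    1,  0.0307),
    r("ALRU", "snag",  10, 100,    1, NA, 10.2),
    r("UNKN", "snag",  10, 100,  165,  1.4620),
    r("UNKN", "snag", 100, 400,    5,  0.2000))
}

#' Stem map reproducing the published reference census
#'
#' Expands [reference_census_targets()] into a full stem map on the 800 m x
#' 320 m window: each class is realized as `count` stems of equal dbh chosen
#' so the class basal area hits its target (dbh clamped into the class
#' bounds; below-precision classes use their nominal dbh). Positions are
#' synthetic (uniform, fixed seed) - the fixture encodes the census
#' arithmetic, not the spatial pattern, and is the reference input for
#' validating [summarize_census()] against the published table.
#'
#' @return A validated [stem_map()] (25.6 ha, 32,940 stems).
#' @export
reference_census_fixture <- function() {
  tg <- reference_census_targets()
  window <- plot_window(800, 320)
  area_ha <- window_area(window) / 1e4
  dbh <- numeric(0)
  for (i in seq_len(nrow(tg))) {
    d <- if (is.na(tg$ba_ha[i])) {
      tg$dbh_fixed[i]
    } else {
      per_stem <- tg$ba_ha[i] * area_ha / tg$count[i]
      min(max(200 * sqrt(per_stem / pi), tg$class_lo[i]),
          tg$class_hi[i] - 0.01)
    }
    dbh <- c(dbh, rep(d, tg$count[i]))
  }
  n <- length(dbh)
  stems <- with_seed(19491121L, data.frame(
    tag = sprintf("R%05d", seq_len(n)),
    species = rep(tg$species, tg$count),
    x = stats::runif(n, 0, window$width),
    y = stats::runif(n, 0, window$height),
    dbh = dbh,
    status = rep(ifelse(tg$population == "snag", "snag", "live"), tg$count),
    growth_form = rep(c("live tree" = "tree", "snag" = "tree",
                        "tall shrub" = "tall_shrub",
                        "liana" = "liana")[tg$population], tg$count),
    snag_height = rep(ifelse(tg$population == "snag", 15, NA_real_),
                      tg$count),
    decay_class = rep(ifelse(tg$population == "snag", 3L, NA_integer_),
                      tg$count),
    stringsAsFactors = FALSE))
  stem_map(stems, window)
}
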