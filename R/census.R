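#' Census summary of a stem map
#'
#' Per-species and per-population summary of a mapped census: stem density,
#' counts above the 1 / 10 / 100 cm dbh thresholds, basal area above the same
#' thresholds (m^2/ha), and the large-diameter proportions (stems >= 100 cm as
#' a share of stems >= 1 cm, and basal area >= 100 cm as a share of basal
#' area >= 1 cm). Populations are live trees, tall shrubs, lianas, and snags;
#' snags are summarized over the >= 10 cm and >= 100 cm thresholds only and
#' their large-diameter proportions use the >= 10 cm classes as denominator.
#' Thresholds are inclusive throughout.
#'
#' @param map A [stem_map()].
#' @param plot_area_ha Plot area in hectares; defaults to the window area.
#' @return A data frame of class `census_summary` with one row per species
#'   per population plus total rows (`population` of the form `"<pop> total"`
#'   and the grand `"live woody total"`). Columns: `species`, `population`,
#'   `density` (stems/ha), `n_ge1`, `n_ge10`, `n_ge100`, `large_stem_prop`
#'   (percent), `ba_ge1`, `ba_ge10`, `ba_ge100` (m^2/ha), `large_ba_prop`
#'   (percent). An empty map yields rows of zeros, not an error.
#' @export
summarize_census <- function(map, plot_area_ha = window_area(map$window) / 1e4) {
  stopifnot(inherits(map, "stem_map"), plot_area_ha > 0)
  st <- map$stems
  st$ba <- if (nrow(st)) basal_area(st$dbh) else numeric()

  pop_of <- function(s) {
    ifelse(s$status == "snag", "snag",
           c(tree = "live tree", tall_shrub = "tall shrub",
             liana = "liana")[s$growth_form])
  }
  st$population <- if (nrow(st)) pop_of(st) else character()

  species_rows <- function(sub, population) {
    snag <- population == "snag"
    base_thr <- if (snag) 10 else 1
    split_sp <- split(sub, sub$species)
    rows <- lapply(names(split_sp), function(sp) {
      s <- split_sp[[sp]]
      n1 <- sum(s$dbh >= 1); n10 <- sum(s$dbh >= 10); n100 <- sum(s$dbh >= 100)
      b1 <- sum(s$ba[s$dbh >= 1]); b10 <- sum(s$ba[s$dbh >= 10])
      b100 <- sum(s$ba[s$dbh >= 100])
      n_base <- if (snag) n10 else n1
      b_base <- if (snag) b10 else b1
      data.frame(
        species = sp, population = population,
        density = n_base / plot_area_ha,
        n_ge1 = if (snag) NA_integer_ else n1,
        n_ge10 = n10, n_ge100 = n100,
        large_stem_prop = if (n_base > 0) 100 * n100 / n_base else NA_real_,
        ba_ge1 = if (snag) NA_real_ else b1 / plot_area_ha,
        ba_ge10 = b10 / plot_area_ha, ba_ge100 = b100 / plot_area_ha,
        large_ba_prop = if (b_base > 0) 100 * b100 / b_base else NA_real_,
        stringsAsFactors = FALSE)
    })
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  }

  total_row <- function(rows, label, snag = FALSE) {
    if (is.null(rows) || !nrow(rows)) {
      rows <- data.frame(species = character(), n_ge1 = integer(),
                         n_ge10 = integer(), n_ge100 = integer(),
                         ba_ge1 = numeric(), ba_ge10 = numeric(),
                         ba_ge100 = numeric())
    }
    n1 <- sum(rows$n_ge1); n10 <- sum(rows$n_ge10); n100 <- sum(rows$n_ge100)
    b1 <- sum(rows$ba_ge1); b10 <- sum(rows$ba_ge10); b100 <- sum(rows$ba_ge100)
    n_base <- if (snag) n10 else n1
    b_base <- if (snag) b10 else b1
    data.frame(
      species = "(all)", population = label,
      density = if (snag) n10 / plot_area_ha else n1 / plot_area_ha,
      n_ge1 = if (snag) NA_integer_ else n1,
      n_ge10 = n10, n_ge100 = n100,
      large_stem_prop = if (isTRUE(n_base > 0)) 100 * n100 / n_base else NA_real_,
      ba_ge1 = if (snag) NA_real_ else b1,
      ba_ge10 = b10, ba_ge100 = b100,
      large_ba_prop = if (isTRUE(b_base > 0)) 100 * b100 / b_base else NA_real_,
      stringsAsFactors = FALSE)
  }

  pieces <- list()
  for (population in c("live tree", "tall shrub", "liana")) {
    sub <- st[st$population == population, , drop = FALSE]
    if (nrow(sub)) {
      rows <- species_rows(sub, population)
      pieces[[population]] <- rows
      pieces[[paste(population, "total")]] <-
        total_row(rows, paste(population, "total"))
    }
  }
  live_rows <- do.call(rbind, pieces[c("live tree", "tall shrub", "liana")])
  pieces[["live woody total"]] <- total_row(live_rows, "live woody total")
  sub <- st[st$population == "snag", , drop = FALSE]
  if (nrow(sub)) {
    rows <- species_rows(sub, "snag")
    pieces[["snag"]] <- rows
    pieces[["snag total"]] <- total_row(rows, "snag total", snag = TRUE)
  }
  out <- do.call(rbind, c(pieces, list(make.row.names = FALSE)))
  if (is.null(out) || !nrow(out)) {
    out <- total_row(NULL, "live woody total")
    out[is.na(out)] <- 0
  }
  class(out) <- c("census_summary", "data.frame")
  out
}

#' Format a census summary for reporting
#'
#' Rounds densities to 0.1 stems/ha and basal areas to 0.01 m^2/ha, rendering
#' values below half those precisions as the trace mark `"t"` (the printed-table
#' convention for densities under one stem per 10 ha).
#'
#' @param cs A `census_summary`.
#' @return A character data frame suitable for CSV export.
#' @export
format_census <- function(cs) {
  stopifnot(inherits(cs, "census_summary"))
  trace <- function(v, digits, cut) {
    ifelse(is.na(v), "-",
           ifelse(v > 0 & v < cut, "t", formatC(round(v, digits),
                                                format = "f", digits = digits)))
  }
  data.frame(
    species = cs$species, population = cs$population,
    density = trace(cs$density, 1, 0.05),
    n_ge1 = ifelse(is.na(cs$n_ge1), "-", cs$n_ge1),
    n_ge10 = cs$n_ge10, n_ge100 = cs$n_ge100,
    large_stem_prop = trace(cs$large_stem_prop, 1, 0),
    ba_ge1 = trace(cs$ba_ge1, 2, 0.005),
    ba_ge10 = trace(cs$ba_ge10, 2, 0.005),
    ba_ge100 = trace(cs$ba_ge100, 2, 0.005),
    large_ba_prop = trace(cs$large_ba_prop, 1, 0),
    stringsAsFactors = FALSE)
}

#' Diameter distribution of one species
#'
#' Histogram of stem counts and basal area by dbh class. The first bin is
#' `[1, 5)` cm; subsequent bins are half-open `[a, a + bin_width)`.
#'
#' @param map A [stem_map()].
#' @param species Species code present in the map.
#' @param bin_width Width of bins after the first, in cm.
#' @return A data frame of class `diameter_histogram` with columns `lower`,
#'   `upper`, `count`, `basal_area` (m^2). Counts sum to the number of live
#'   stems of the species; basal areas to their total.
#' @export
diameter_distribution <- function(map, species, bin_width = 5) {
  stopifnot(inherits(map, "stem_map"), bin_width > 0)
  if (!species %in% map$stems$species) {
    stop("species not present in stem map: ", species, call. = FALSE)
  }
  st <- map$stems[map$stems$species == species & map$stems$status == "live", ,
                  drop = FALSE]
  top <- if (nrow(st)) max(st$dbh) else 1
  edges <- c(1, seq(5, by = bin_width,
                    length.out = max(1, ceiling((top - 5) / bin_width) + 1L)))
  edges <- c(edges, edges[length(edges)] + bin_width)
  idx <- findInterval(st$dbh, edges, rightmost.closed = FALSE)
  nb <- length(edges) - 1L
  count <- tabulate(idx, nbins = nb)
  ba <- numeric(nb)
  if (nrow(st)) {
    agg <- rowsum(basal_area(st$dbh), idx)
    ba[as.integer(rownames(agg))] <- agg[, 1]
  }
  out <- data.frame(lower = edges[-length(edges)], upper = edges[-1],
                    count = count, basal_area = ba)
  class(out) <- c("diameter_histogram", "data.frame")
  attr(out, "species") <- species
  out
}

#' Quadrat statistics of a stem map
#'
#' Partitions the window into square quadrats of the given grain and sums stem
#' counts and basal area per quadrat. Stems on an interior quadrat boundary
#' belong to the quadrat to the north/east (half-open intervals); stems on the
#' window's far edge are clamped into the last quadrat, so every stem is
#' counted exactly once and totals are conserved at every grain.
#'
#' @param map A [stem_map()].
#' @param grain Quadrat area in m^2; its square root must divide both window
#'   dimensions exactly.
#' @param subset Optional predicate `function(stems) -> logical` selecting the
#'   stems to tally; default: all live stems.
#' @return A list of class `quadrat_grid`: `grain`, `side`, `nx`, `ny`,
#'   `table` (row-major from the southwest: `qx`, `qy`, `count`, `ba_m2`,
#'   `ba_per_ha`), and `summary` (5/25/50/75/95 percentiles of per-quadrat
#'   count and basal area).
#' @export
quadrat_statistics <- function(map, grain, subset = NULL) {
  stopifnot(inherits(map, "stem_map"), grain > 0)
  side <- sqrt(grain)
  W <- map$window$width; H <- map$window$height
  nx <- W / side; ny <- H / side
  if (abs(nx - round(nx)) > 1e-9 || abs(ny - round(ny)) > 1e-9) {
    stop(sprintf("quadrat side %.6g m does not tile the %g x %g window",
                 side, W, H), call. = FALSE)
  }
  nx <- as.integer(round(nx)); ny <- as.integer(round(ny))
  st <- map$stems
  keep <- if (is.null(subset)) st$status == "live" else subset(st)
  st <- st[keep & !is.na(keep), , drop = FALSE]
  v <- quadrat_sums(st$x, st$y, basal_area_safe(st$dbh), W, H, side)
  cnt <- quadrat_sums(st$x, st$y, rep(1, nrow(st)), W, H, side)
  qx <- rep(seq_len(nx) - 1L, times = ny)
  qy <- rep(seq_len(ny) - 1L, each = nx)
  tab <- data.frame(qx = qx, qy = qy, count = as.integer(cnt), ba_m2 = v,
                    ba_per_ha = v / (grain / 1e4))
  pct <- c(0.05, 0.25, 0.5, 0.75, 0.95)
  structure(list(grain = grain, side = side, nx = nx, ny = ny, table = tab,
                 summary = data.frame(
                   percentile = 100 * pct,
                   count = stats::quantile(tab$count, pct, names = FALSE),
                   ba_m2 = stats::quantile(tab$ba_m2, pct, names = FALSE))),
            class = "quadrat_grid")
}

basal_area_safe <- function(dbh) if (length(dbh)) basal_area(dbh) else numeric()

# Sum `values` over a side x side quadrat grid; row-major from the southwest.
# Far-edge coordinates are clamped into the last quadrat.
quadrat_sums <- function(x, y, values, W, H, side) {
  nx <- as.integer(round(W / side)); ny <- as.integer(round(H / side))
  out <- numeric(nx * ny)
  if (!length(x)) return(out)
  ix <- pmin(floor(x / side), nx - 1L)
  iy <- pmin(floor(y / side), ny - 1L)
  q <- as.integer(ix + nx * iy + 1L)
  agg <- rowsum(values, q)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Split live trees by the large-diameter threshold
#'
#' Partitions the live trees of a map into the large-diameter (dbh >=
#' `threshold`) and small-diameter (dbh < `threshold`) subpopulations.
#' Snags, tall shrubs, and lianas are excluded. The partition is exhaustive
#' and disjoint on live trees; the threshold is inclusive.
#'
#' @param map A [stem_map()].
#' @param threshold dbh threshold in cm (default 100, the operational
#'   definition of a large-diameter tree).
#' @return A list with elements `large` and `small`, each a data frame of
#'   stem records, plus the shared `window`.
#' @export
split_by_diameter <- function(map, threshold = 100) {
  stopifnot(inherits(map, "stem_map"))
  live <- map$stems[map$stems$status == "live" &
                      map$stems$growth_form == "tree", , drop = FALSE]
  list(large = live[live$dbh >= threshold, , drop = FALSE],
       small = live[live$dbh < threshold, , drop = FALSE],
       window = map$window)
}
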