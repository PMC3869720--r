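#' Rectangular plot window
#'
#' A survey plot is a rectangle with its origin at the southwest corner,
#' x increasing east and y increasing north. All coordinates in the package
#' are in meters relative to this origin.
#'
#' @param width East-west extent in meters (> 0).
#' @param height North-south extent in meters (> 0).
#' @return An object of class `plot_window` with fields `width` and `height`.
#' @examples
#' w <- plot_window(800, 320)   # a 25.6 ha plot
#' window_area(w) / 1e4         # area in hectares
#' @export
plot_window <- function(width, height) {
  stopifnot(is.numeric(width), length(width) == 1L, is.finite(width), width > 0,
            is.numeric(height), length(height) == 1L, is.finite(height), height > 0)
  structure(list(width = as.numeric(width), height = as.numeric(height)),
            class = "plot_window")
}

#' @rdname plot_window
#' @param window A `plot_window`.
#' @return `window_area()`: the area in square meters.
#' @export
window_area <- function(window) {
  stopifnot(inherits(window, "plot_window"))
  window$width * window$height
}

#' @export
print.plot_window <- function(x, ...) {
  cat(sprintf("plot window %g m x %g m (%.4g ha)\n",
              x$width, x$height, window_area(x) / 1e4))
  invisible(x)
}

STEM_COLUMNS <- c("tag", "species", "x", "y", "dbh", "status",
                  "growth_form", "snag_height", "decay_class")

#' Assemble a validated stem map
#'
#' A stem map is the universal input of the package: one record per tagged,
#' mapped woody stem inside a rectangular window. Records are validated
#' against the tagging protocol: live stems have dbh >= 1 cm, snags have
#' dbh >= 10 cm and (where measured) height >= 1.8 m, all coordinates lie
#' inside the window, and tags are unique.
#'
#' @param stems A data frame with columns `tag`, `species`, `x`, `y`, `dbh`
#'   (cm at 1.37 m), `status` (`"live"` or `"snag"`), and optionally
#'   `growth_form` (`"tree"`, `"tall_shrub"`, `"liana"`; default `"tree"`),
#'   `snag_height` (m, snags only), `decay_class` (integer 1-5, snags only).
#' @param window A [plot_window()].
#' @param shrub_patches Optional data frame with columns `species` and
#'   `area` (m^2): shrub-patch cover reduced to per-species areas.
#' @return An object of class `stem_map`.
#' @export
stem_map <- function(stems, window, shrub_patches = NULL) {
  stopifnot(inherits(window, "plot_window"), is.data.frame(stems))
  required <- c("tag", "species", "x", "y", "dbh", "status")
  missing_cols <- setdiff(required, names(stems))
  if (length(missing_cols)) {
    stop("stem table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  stems <- as.data.frame(stems, stringsAsFactors = FALSE)
  if (!"growth_form" %in% names(stems)) {
    stems$growth_form <- rep("tree", nrow(stems))
  }
  stems$growth_form[is.na(stems$growth_form)] <- "tree"
  if (!"snag_height" %in% names(stems)) {
    stems$snag_height <- rep(NA_real_, nrow(stems))
  }
  if (!"decay_class" %in% names(stems)) {
    stems$decay_class <- rep(NA_integer_, nrow(stems))
  }
  stems <- stems[STEM_COLUMNS]
  stems$tag <- as.character(stems$tag)
  stems$species <- as.character(stems$species)
  for (col in c("x", "y", "dbh", "snag_height")) stems[[col]] <- as.numeric(stems[[col]])
  stems$decay_class <- as.integer(stems$decay_class)

  problems <- validate_stems(stems, window)
  if (nrow(problems)) {
    show <- utils::head(problems, 10L)
    stop(sprintf("%d stem record(s) violate the tagging protocol:\n%s",
                 nrow(problems),
                 paste(sprintf("  tag %s: %s", show$tag, show$problem),
                       collapse = "\n")),
         call. = FALSE)
  }
  if (!is.null(shrub_patches)) {
    stopifnot(is.data.frame(shrub_patches),
              all(c("species", "area") %in% names(shrub_patches)),
              all(shrub_patches$area >= 0))
  }
  structure(list(window = window, stems = stems, shrub_patches = shrub_patches),
            class = "stem_map")
}

# Row-level diagnostics; returns a data frame (tag, problem), empty when valid.
validate_stems <- function(stems, window) {
  probs <- list()
  flag <- function(idx, msg) {
    if (any(idx, na.rm = TRUE)) {
      probs[[length(probs) + 1L]] <<-
        data.frame(tag = stems$tag[which(idx)], problem = msg,
                   stringsAsFactors = FALSE)
    }
  }
  dup <- duplicated(stems$tag)
  flag(dup, "duplicate tag")
  flag(is.na(stems$x) | is.na(stems$y), "missing coordinate")
  flag(stems$x < 0 | stems$x > window$width |
         stems$y < 0 | stems$y > window$height, "coordinate outside window")
  flag(!stems$status %in% c("live", "snag"), "status must be 'live' or 'snag'")
  flag(!stems$growth_form %in% c("tree", "tall_shrub", "liana"),
       "unknown growth form")
  flag(is.na(stems$dbh) | stems$dbh <= 0, "missing or non-positive dbh")
  live <- stems$status == "live"
  flag(live & stems$dbh < 1, "live stem below the 1 cm tagging threshold")
  snag <- stems$status == "snag"
  flag(snag & stems$dbh < 10, "snag below the 10 cm threshold")
  flag(snag & !is.na(stems$snag_height) & stems$snag_height < 1.8,
       "snag shorter than 1.8 m")
  flag(!is.na(stems$decay_class) & !(stems$decay_class %in% 1:5),
       "decay class outside 1-5")
  if (length(probs)) do.call(rbind, probs) else
    data.frame(tag = character(), problem = character(), stringsAsFactors = FALSE)
}

#' @export
print.stem_map <- function(x, ...) {
  live <- sum(x$stems$status == "live")
  cat(sprintf("stem map: %d stems (%d live, %d snags) in %g m x %g m\n",
              nrow(x$stems), live, nrow(x$stems) - live,
              x$window$width, x$window$height))
  invisible(x)
}

#' Read and write stem-map files
#'
#' The on-disk dialect is a UTF-8 CSV with header
#' `tag,species,x,y,dbh,status[,growth_form,snag_height,decay_class]`;
#' coordinates in meters, dbh in cm. `write_stem_map()` and
#' `read_stem_map()` round-trip exactly on valid maps.
#'
#' @param path File path.
#' @param window The [plot_window()] the coordinates refer to.
#' @return `read_stem_map()`: a validated [stem_map()].
#' @export
read_stem_map <- function(path, window) {
  if (!file.exists(path)) stop("stem-map file not found: ", path, call. = FALSE)
  stems <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("tag", "species", "x", "y", "dbh", "status")
  missing_cols <- setdiff(required, names(stems))
  if (length(missing_cols)) {
    stop("stem-map file lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  stem_map(stems, window)
}

#' @rdname read_stem_map
#' @param map A [stem_map()].
#' @export
write_stem_map <- function(map, path) {
  stopifnot(inherits(map, "stem_map"))
  utils::write.csv(map$stems, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Basal area of a stem
#'
#' Cross-sectional area at breast height: `pi * (dbh / 200)^2` square meters
#' for dbh in centimeters (the standard forestry definition).
#'
#' @param dbh Diameter at breast height in cm (> 0); vectorized.
#' @return Basal area in m^2.
#' @examples
#' basal_area(100)           # 0.7853982
#' basal_area(200 / sqrt(pi)) # exactly 1 m^2
#' @export
basal_area <- function(dbh) {
  if (any(!is.finite(dbh)) || any(dbh <= 0)) {
    stop("dbh must be positive and finite", call. = FALSE)
  }
  pi * (dbh / 200)^2
}
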