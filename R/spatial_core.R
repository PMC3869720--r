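#' Planar point pattern in a rectangular window
#'
#' Bare locations of a (sub)population of stems; the substrate of all
#' second-order statistics in the package. Points may carry a label (mark),
#' used by the bivariate statistics to distinguish e.g. large-diameter
#' (type 1) from small-diameter (type 2) trees.
#'
#' @param x,y Numeric coordinate vectors (meters).
#' @param window A [plot_window()] containing all points.
#' @param marks Optional per-point labels (character or factor).
#' @return An object of class `point_pattern`.
#' @export
point_pattern <- function(x, y, window, marks = NULL) {
  stopifnot(inherits(window, "plot_window"), length(x) == length(y))
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) && (any(!is.finite(x)) || any(!is.finite(y)) ||
                    any(x < 0) || any(x > window$width) ||
                    any(y < 0) || any(y > window$height))) {
    stop("all points must lie inside the window", call. = FALSE)
  }
  if (!is.null(marks)) {
    stopifnot(length(marks) == length(x))
    marks <- as.character(marks)
  }
  structure(list(x = x, y = y, window = window, marks = marks),
            class = "point_pattern")
}

#' @rdname point_pattern
#' @param pattern A `point_pattern`.
#' @export
npoints <- function(pattern) length(pattern$x)

#' @export
print.point_pattern <- function(x, ...) {
  cat(sprintf("point pattern: %d points in %g m x %g m%s\n",
              npoints(x), x$window$width, x$window$height,
              if (is.null(x$marks)) "" else
                sprintf(" (%d types)", length(unique(x$marks)))))
  invisible(x)
}

#' Point pattern from a stem map
#'
#' @param map A [stem_map()] or a stem data frame plus `window`.
#' @param window Window (required when `map` is a data frame).
#' @param marks Optional per-point labels.
#' @return A [point_pattern()].
#' @export
as_point_pattern <- function(map, window = NULL, marks = NULL) {
  if (inherits(map, "stem_map")) {
    point_pattern(map$stems$x, map$stems$y, map$window, marks)
  } else {
    point_pattern(map$x, map$y, window, marks)
  }
}

#' Pairwise Euclidean distances
#'
#' @param pattern A [point_pattern()] with at least two points.
#' @return A symmetric distance matrix in meters. Duplicate points (zero
#'   distance) are permitted but raise a warning.
#' @export
pairwise_distances <- function(pattern) {
  n <- npoints(pattern)
  if (n < 2) stop("at least two points are required", call. = FALSE)
  d <- stats::dist(cbind(pattern$x, pattern$y))
  if (any(d < 1e-12)) {
    warning("pattern contains duplicated points (zero pairwise distance)",
            call. = FALSE)
  }
  as.matrix(d)
}

#' Uniform evaluation grid for summary functions
#'
#' Distances `r_k = k * r_max / n_steps` for `k = 0, ..., n_steps`. The
#' default resolution (512 steps) gives smooth curves at negligible cost.
#'
#' @param r_max Largest evaluation distance in meters (> 0).
#' @param n_steps Number of steps (>= 1).
#' @return An object of class `r_grid` with fields `r`, `r_max`, `n_steps`,
#'   `dr`.
#' @export
r_grid <- function(r_max, n_steps = 512L) {
  stopifnot(r_max > 0, n_steps >= 1)
  dr <- r_max / n_steps
  structure(list(r = seq(0, r_max, by = dr), r_max = r_max,
                 n_steps = as.integer(n_steps), dr = dr), class = "r_grid")
}

#' @rdname r_grid
#' @param window A [plot_window()]; the default analysis grid runs to one
#'   quarter of the shorter window side.
#' @export
default_grid <- function(window, n_steps = 512L) {
  r_grid(min(window$width, window$height) / 4, n_steps)
}

#' @rdname r_grid
#' @param grid An `r_grid`.
#' @param r_max_new New upper limit; the prefix of `grid` up to `r_max_new`
#'   is returned (same step size).
#' @export
restrict_grid <- function(grid, r_max_new) {
  stopifnot(inherits(grid, "r_grid"), r_max_new > 0)
  keep <- grid$r <= r_max_new + 1e-12
  structure(list(r = grid$r[keep], r_max = max(grid$r[keep]),
                 n_steps = sum(keep) - 1L, dr = grid$dr), class = "r_grid")
}

#' Isotropic edge-correction weight
#'
#' Ripley's isotropic correction for a rectangular window: the weight of a
#' pair at distance `d` is the reciprocal of the fraction of the circumference
#' of the circle of radius `d`, centered on the focal point, that lies inside
#' the rectangle. The fraction is computed from the exact arc geometry: each
#' side closer than `d` removes an arc of half-angle `acos(d_side/d)`, and
#' each corner whose both adjacent sides are crossed (corner inside the
#' circle) returns the doubly removed overlap. For distances beyond the
#' shorter window side the fraction is computed by numeric arc integration
#' instead, and weights are capped at 4 with a warning (a quarter circle, the
#' corner case) - far outside the validity range `r <= min(side)/2` of the
#' estimator itself.
#'
#' @param x,y Coordinates of the circle centers (inside the window);
#'   vectorized.
#' @param d Circle radii in meters (> 0); recycled against `x`.
#' @param window A [plot_window()].
#' @return Weights `>= 1`; exactly 1 when the circle is fully interior,
#'   2 for a center on an edge with the circle crossing only that edge,
#'   4 for a center on a corner.
#' @export
isotropic_edge_weight <- function(x, y, d, window) {
  stopifnot(inherits(window, "plot_window"))
  n <- max(length(x), length(d))
  x <- rep_len(as.numeric(x), n); y <- rep_len(as.numeric(y), n)
  d <- rep_len(as.numeric(d), n)
  if (any(d <= 0)) stop("d must be positive", call. = FALSE)
  W <- window$width; H <- window$height
  frac <- numeric(n)
  analytic <- d <= min(W, H)
  if (any(analytic)) {
    frac[analytic] <- arc_fraction_analytic(x[analytic], y[analytic],
                                            d[analytic], W, H)
  }
  if (any(!analytic)) {
    frac[!analytic] <- arc_fraction_numeric(x[!analytic], y[!analytic],
                                            d[!analytic], W, H)
  }
  w <- 1 / frac
  if (any(w > 4 + 1e-9)) {
    warning("edge-correction weight capped at 4 (circle radius comparable ",
            "to the window size)", call. = FALSE)
    w <- pmin(w, 4)
  }
  w
}

# Exact in-window circumference fraction for a rectangle (vectorized).
arc_fraction_analytic <- function(x, y, d, W, H) {
  half <- function(a) ifelse(a < d, acos(pmin(1, pmax(-1, a / d))), 0)
  aL <- half(x); aR <- half(W - x); aB <- half(y); aT <- half(H - y)
  exterior <- 2 * (aL + aR + aB + aT)
  corner <- function(aa, bb, da, db) {
    inside <- da^2 + db^2 < d^2
    ifelse(inside, aa + bb - pi / 2, 0)
  }
  exterior <- exterior -
    corner(aL, aB, x, y) - corner(aL, aT, x, H - y) -
    corner(aR, aB, W - x, y) - corner(aR, aT, W - x, H - y)
  pmax(1 - exterior / (2 * pi), 0)
}

# Fallback: sample the circle at n_arc points and count those in the window.
arc_fraction_numeric <- function(x, y, d, W, H, n_arc = 1024L) {
  theta <- (seq_len(n_arc) - 0.5) * 2 * pi / n_arc
  ct <- cos(theta); st <- sin(theta)
  vapply(seq_along(x), function(i) {
    px <- x[i] + d[i] * ct; py <- y[i] + d[i] * st
    mean(px >= 0 & px <= W & py >= 0 & py <= H)
  }, numeric(1))
}

# Ordered close pairs of a pattern: distances d <= r_max with the
# edge-correction weight of the pair's *center* point. Both orders (i,j) and
# (j,i) are returned, as the estimator sums over ordered pairs.
close_pairs <- function(pattern, r_max) {
  n <- npoints(pattern)
  dv <- stats::dist(cbind(pattern$x, pattern$y))
  keep <- which(dv <= r_max)
  if (!length(keep)) return(list(d = numeric(), w = numeric()))
  ij <- pair_index(keep, n)
  d <- dv[keep]
  w_i <- isotropic_edge_weight(pattern$x[ij$i], pattern$y[ij$i],
                               pmax(d, 1e-12), pattern$window)
  w_j <- isotropic_edge_weight(pattern$x[ij$j], pattern$y[ij$j],
                               pmax(d, 1e-12), pattern$window)
  list(d = c(d, d), w = c(w_i, w_j))
}

# Map linear indices of a 'dist' object to (i, j) with i < j.
pair_index <- function(k, n) {
  # For column j (1-based, j = 1..n-1): entries ((j-1)*(2n-j)/2 + 1) ... cover i = j+1..n
  k <- as.numeric(k)
  j <- ceiling((2 * n - 1 - sqrt((2 * n - 1)^2 - 8 * k)) / 2)
  base <- (j - 1) * (2 * n - j) / 2
  i <- k - base + j
  list(i = as.integer(i), j = as.integer(j))  # i is the larger row index
}

#' Ripley's K function (univariate)
#'
#' `K_hat(r) = |A| / (n (n - 1)) * sum_{i != j} w_ij 1(d_ij <= r)`, where
#' `w_ij` is the isotropic edge-correction weight of the circle of radius
#' `d_ij` centered on point i. Under complete spatial randomness
#' `E[K(r)] = pi r^2`.
#'
#' @param pattern A [point_pattern()] with `n >= 2`.
#' @param grid An [r_grid()]; `r_max` must not exceed half the shorter
#'   window side (validity of the analytic isotropic correction).
#' @return A `summary_curve` on the K scale (`values` in m^2), monotone
#'   non-decreasing in r.
#' @export
ripley_K <- function(pattern, grid = default_grid(pattern$window)) {
  n <- npoints(pattern)
  if (n < 2) stop("at least two points are required", call. = FALSE)
  short <- min(pattern$window$width, pattern$window$height)
  if (grid$r_max > short / 2 + 1e-9) {
    stop("r_max exceeds half the shorter window side", call. = FALSE)
  }
  cp <- close_pairs(pattern, grid$r_max)
  if (any(cp$d < 1e-12)) {
    warning("pattern contains duplicated points; zero-distance pairs ",
            "contribute at every r", call. = FALSE)
  }
  A <- window_area(pattern$window)
  K <- step_cumsum(cp$d, cp$w, grid$r) * A / (n * (n - 1))
  summary_curve(grid, K, scale = "K", estimator = "isotropic", n = n)
}

# values(r_k) = sum of w over pairs with d <= r_k
step_cumsum <- function(d, w, r) {
  if (!length(d)) return(numeric(length(r)))
  o <- order(d)
  cw <- cumsum(w[o])
  idx <- findInterval(r, d[o])
  ifelse(idx == 0, 0, cw[pmax(idx, 1L)])
}

#' Bivariate Ripley's K function
#'
#' `K12_hat(r) = |A| / (n1 n2) * sum_{i in type1} sum_{j in type2}
#' w_ij 1(d_ij <= r)` with the edge weight of the circle centered on the
#' type-1 point. Under independence of the two populations
#' `E[K12(r)] = pi r^2`.
#'
#' @param pattern A labeled [point_pattern()].
#' @param grid An [r_grid()].
#' @param type1,type2 Mark values of the focal (type 1) and neighbor
#'   (type 2) populations.
#' @return A `summary_curve` on the K scale with attributes `n1`, `n2`.
#' @export
ripley_K12 <- function(pattern, grid = default_grid(pattern$window),
                       type1 = "large", type2 = "small") {
  if (is.null(pattern$marks)) stop("pattern has no marks", call. = FALSE)
  i1 <- which(pattern$marks == type1); i2 <- which(pattern$marks == type2)
  n1 <- length(i1); n2 <- length(i2)
  if (n1 < 1 || n2 < 1) {
    stop("both types must contain at least one point", call. = FALSE)
  }
  short <- min(pattern$window$width, pattern$window$height)
  if (grid$r_max > short / 2 + 1e-9) {
    stop("r_max exceeds half the shorter window side", call. = FALSE)
  }
  dx <- outer(pattern$x[i1], pattern$x[i2], "-")
  dy <- outer(pattern$y[i1], pattern$y[i2], "-")
  d <- sqrt(dx^2 + dy^2)
  keep <- which(d <= grid$r_max)
  A <- window_area(pattern$window)
  if (length(keep)) {
    ridx <- ((keep - 1L) %% n1) + 1L
    w <- isotropic_edge_weight(pattern$x[i1][ridx], pattern$y[i1][ridx],
                               pmax(d[keep], 1e-12), pattern$window)
    K <- step_cumsum(d[keep], w, grid$r) * A / (n1 * n2)
  } else {
    K <- numeric(length(grid$r))
  }
  out <- summary_curve(grid, K, scale = "K", estimator = "isotropic",
                       n = n1 + n2)
  attr(out, "n1") <- n1; attr(out, "n2") <- n2
  out
}

#' Summary curve container
#'
#' A discretized second-order summary: values on the K scale (m^2) or the
#' CSR-centered L scale `L_hat(r) - r` (meters), one per grid distance.
#'
#' @param grid An [r_grid()].
#' @param values Numeric vector, one value per `grid$r`.
#' @param scale `"K"` or `"L"`.
#' @param estimator Estimator name (metadata).
#' @param n Number of points behind the estimate.
#' @return An object of class `summary_curve`.
#' @export
summary_curve <- function(grid, values, scale = c("K", "L"),
                          estimator = "isotropic", n = NA_integer_) {
  scale <- match.arg(scale)
  stopifnot(inherits(grid, "r_grid"), length(values) == length(grid$r),
            all(is.finite(values)))
  structure(list(grid = grid, values = values, scale = scale,
                 estimator = estimator, n = n), class = "summary_curve")
}

#' L transformation of a K curve
#'
#' `L_hat(r) - r` with `L_hat(r) = sqrt(K_hat(r) / pi)`: zero wherever
#' `K_hat(r) = pi r^2`, positive under clumping, negative under regularity.
#'
#' @param curve A `summary_curve` on the K scale (values >= 0).
#' @return A `summary_curve` on the centered L scale (meters).
#' @export
L_transform <- function(curve) {
  stopifnot(inherits(curve, "summary_curve"))
  if (curve$scale == "L") return(curve)
  if (any(curve$values < 0)) stop("K values must be non-negative", call. = FALSE)
  out <- curve
  out$values <- sqrt(curve$values / pi) - curve$grid$r
  out$scale <- "L"
  out
}

#' @export
print.summary_curve <- function(x, ...) {
  cat(sprintf("summary curve (%s scale, %s estimator, n = %s) on [0, %g] m (%d steps)\n",
              x$scale, x$estimator, x$n, x$grid$r_max, x$grid$n_steps))
  invisible(x)
}

#' Export a summary curve as CSV with a JSON metadata header
#'
#' @param curve A `summary_curve`.
#' @param path Output path; the first line is a `#`-prefixed JSON object
#'   (estimator, scale, n), followed by a `r,value` CSV body.
#' @export
write_summary_curve <- function(curve, path) {
  meta <- jsonlite::toJSON(list(estimator = curve$estimator,
                                scale = curve$scale, n = curve$n),
                           auto_unbox = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", meta), con)
  utils::write.csv(data.frame(r = curve$grid$r, value = curve$values),
                   con, row.names = FALSE)
  invisible(path)
}
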