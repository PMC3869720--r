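# RNG helpers: a single top-level seed is fanned out into named substream
# seeds so replicate k is reproducible independently of evaluation order.

#' Derive reproducible substream seeds
#'
#' @param seed Integer master seed (or NULL for the current RNG state).
#' @param n Number of substream seeds to draw.
#' @return Integer vector of `n` seeds in `[1, 2^31 - 1]`.
#' @export
substream_seeds <- function(seed, n) {
  with_seed(seed, sample.int(2147483646L, n, replace = FALSE))
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Simulate complete spatial randomness
#'
#' `n` points i.i.d. uniform on the window (a binomial process - the CSR
#' null at fixed observed count).
#'
#' @param n Number of points (>= 0).
#' @param window A [plot_window()].
#' @param seed Optional integer seed; a fixed seed reproduces the pattern.
#' @return A [point_pattern()].
#' @export
simulate_csr <- function(n, window, seed = NULL) {
  stopifnot(n >= 0)
  with_seed(seed, point_pattern(stats::runif(n, 0, window$width),
                                stats::runif(n, 0, window$height), window))
}

#' Toroidal shift of one subpopulation
#'
#' Translates every point of the moved type by `(dx, dy)` modulo the window
#' dimensions (wrapping), leaving the other type unchanged. Intratype
#' toroidal pairwise distances are preserved exactly, which is what makes
#' the shift a null model for independence of two populations: the internal
#' configuration of each type is held fixed while their relative displacement
#' is randomized.
#'
#' @param pattern A labeled [point_pattern()].
#' @param dx,dy Shift vector, in `[0, width) x [0, height)`.
#' @param type Mark value of the subpopulation to move; `NULL` moves all
#'   points.
#' @return The shifted [point_pattern()].
#' @export
toroidal_shift <- function(pattern, dx, dy, type = NULL) {
  W <- pattern$window$width; H <- pattern$window$height
  stopifnot(dx >= 0, dx < W, dy >= 0, dy < H)
  move <- if (is.null(type)) rep(TRUE, npoints(pattern)) else
    pattern$marks == type
  x <- pattern$x; y <- pattern$y
  x[move] <- (x[move] + dx) %% W
  y[move] <- (y[move] + dy) %% H
  point_pattern(x, y, pattern$window, pattern$marks)
}

#' Monte Carlo simulation envelope for a summary statistic
#'
#' Computes the empirical centered-L curve of a pattern together with
#' `n_sim` curves simulated under a null model:
#' \describe{
#'   \item{`"csr"` (univariate)}{each replicate resimulates the analyzed
#'     population at its observed count, uniform on the window.}
#'   \item{`"independence"` (bivariate)}{each replicate draws one uniform
#'     random shift vector and toroidally shifts the type-1 (large-diameter)
#'     subpopulation, holding both intratype configurations fixed. A single
#'     relative shift is equivalent to shifting both types, since only the
#'     relative displacement enters the cross statistic.}
#' }
#'
#' @param pattern A [point_pattern()] (labeled, for the bivariate statistic).
#' @param statistic `"univariate"` (centered L) or `"bivariate"`
#'   (centered L12).
#' @param null `"csr"` or `"independence"`; only univariate/CSR and
#'   bivariate/independence are meaningful combinations.
#' @param n_sim Number of simulated patterns (the convention in this
#'   literature is 999).
#' @param grid An [r_grid()].
#' @param seed Optional master seed; replicate k uses substream k.
#' @param type1,type2 Mark values for the bivariate statistic.
#' @return An object of class `envelope_set`: `grid`, `empirical` (vector),
#'   `sims` (n_sim x length(r) matrix), pointwise `lo`/`hi`/`mean`, `null`,
#'   `n_sim`, `seed`.
#' @export
make_envelope <- function(pattern, statistic = c("univariate", "bivariate"),
                          null = c("csr", "independence"), n_sim = 999,
                          grid = default_grid(pattern$window), seed = NULL,
                          type1 = "large", type2 = "small") {
  statistic <- match.arg(statistic)
  null <- match.arg(null)
  if (statistic == "univariate" && null != "csr") {
    stop("the univariate statistic is tested against the CSR null",
         call. = FALSE)
  }
  if (statistic == "bivariate" && null != "independence") {
    stop("the bivariate statistic is tested against the independence ",
         "(toroidal-shift) null", call. = FALSE)
  }
  seeds <- substream_seeds(seed, n_sim)
  if (statistic == "univariate") {
    emp <- L_transform(ripley_K(pattern, grid))$values
    n <- npoints(pattern)
    sims <- vapply(seq_len(n_sim), function(k) {
      p <- simulate_csr(n, pattern$window, seeds[k])
      L_transform(ripley_K(p, grid))$values
    }, numeric(length(grid$r)))
  } else {
    emp <- L_transform(ripley_K12(pattern, grid, type1, type2))$values
    W <- pattern$window$width; H <- pattern$window$height
    sims <- vapply(seq_len(n_sim), function(k) {
      shifted <- with_seed(seeds[k], {
        toroidal_shift(pattern, stats::runif(1, 0, W), stats::runif(1, 0, H),
                       type = type1)
      })
      L_transform(ripley_K12(shifted, grid, type1, type2))$values
    }, numeric(length(grid$r)))
  }
  sims <- t(sims)
  structure(list(grid = grid, empirical = emp, sims = sims,
                 lo = apply(sims, 2, min), hi = apply(sims, 2, max),
                 mean = colMeans(sims), statistic = statistic, null = null,
                 n_sim = n_sim, seed = seed),
            class = "envelope_set")
}

#' @export
print.envelope_set <- function(x, ...) {
  cat(sprintf("envelope: %s statistic vs %s null, %d simulations on [0, %g] m\n",
              x$statistic, x$null, x$n_sim, x$grid$r_max))
  invisible(x)
}

#' Restrict an envelope to a shorter distance interval
#'
#' Keeps the `[0, r_max_new]` prefix of every curve, so one wide envelope
#' (say to 80 m, for exploratory plots) can also feed the goodness-of-fit
#' test on its inferential interval (say 9 m).
#'
#' @param env An `envelope_set`.
#' @param r_max_new New upper limit in meters.
#' @return An `envelope_set` on the restricted grid.
#' @export
restrict_envelope <- function(env, r_max_new) {
  stopifnot(inherits(env, "envelope_set"))
  keep <- env$grid$r <= r_max_new + 1e-12
  env$grid <- restrict_grid(env$grid, r_max_new)
  env$empirical <- env$empirical[keep]
  env$sims <- env$sims[, keep, drop = FALSE]
  env$lo <- env$lo[keep]; env$hi <- env$hi[keep]; env$mean <- env$mean[keep]
  env
}

#' Export an envelope as CSV with a JSON metadata header
#'
#' Columns `r, empirical, sim_min, sim_mean, sim_max` (plus one `sim_k`
#' column per simulated curve when `full = TRUE`, which makes the export
#' sufficient to recompute the goodness-of-fit test); the first line is a
#' `#`-prefixed JSON object recording the null, simulation count, and seed.
#'
#' @param env An `envelope_set`.
#' @param path Output path.
#' @param full Also write every simulated curve.
#' @export
write_envelope <- function(env, path, full = FALSE) {
  meta <- jsonlite::toJSON(list(statistic = env$statistic, null = env$null,
                                n_sim = env$n_sim, seed = env$seed,
                                dr = env$grid$dr, full = full),
                           auto_unbox = TRUE)
  df <- data.frame(r = env$grid$r, empirical = env$empirical,
                   sim_min = env$lo, sim_mean = env$mean, sim_max = env$hi)
  if (full) {
    sims <- as.data.frame(t(env$sims))
    names(sims) <- sprintf("sim_%d", seq_len(env$n_sim))
    df <- cbind(df, sims)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", meta), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_envelope
#' @return `read_envelope()`: an `envelope_set` reconstructed from a file
#'   written with `full = TRUE`.
#' @export
read_envelope <- function(path) {
  header <- readLines(path, n = 1L)
  meta <- jsonlite::fromJSON(sub("^# ", "", header))
  if (!isTRUE(meta$full)) {
    stop("envelope file lacks the simulated curves (written with full = ",
         "FALSE); the test cannot be recomputed from it", call. = FALSE)
  }
  df <- utils::read.csv(path, skip = 1L)
  r <- df$r
  grid <- structure(list(r = r, r_max = max(r), n_steps = length(r) - 1L,
                         dr = meta$dr), class = "r_grid")
  sims <- t(as.matrix(df[sprintf("sim_%d", seq_len(meta$n_sim))]))
  dimnames(sims) <- NULL
  structure(list(grid = grid, empirical = df$empirical, sims = sims,
                 lo = df$sim_min, hi = df$sim_max, mean = df$sim_mean,
                 statistic = meta$statistic, null = meta$null,
                 n_sim = meta$n_sim, seed = meta$seed),
            class = "envelope_set")
}
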