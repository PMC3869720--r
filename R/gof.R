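#' Loosmore-Ford deviation statistic
#'
#' Integrated squared deviation of each curve from the leave-one-out mean of
#' the joint set (empirical plus simulations):
#' `u_i = sum_k (H_i(r_k) - Hbar_{-i}(r_k))^2 * dr`, where `Hbar_{-i}` is
#' the pointwise mean of all curves except curve i. Because every curve -
#' empirical and simulated alike - is compared to the mean of the others,
#' the resulting rank-based p-value is exact under the null.
#'
#' @param curves Numeric matrix, one row per curve, columns sharing one
#'   evaluation grid (at least 3 rows).
#' @param dr Grid spacing in meters (the integration weight).
#' @return Numeric vector of `u` values (m^2 * m on the L scale), one per
#'   row of `curves`.
#' @export
u_statistic <- function(curves, dr) {
  stopifnot(is.matrix(curves), nrow(curves) >= 3, dr > 0,
            all(is.finite(curves)))
  m <- nrow(curves)
  S <- colSums(curves)
  loo_mean <- (matrix(S, m, ncol(curves), byrow = TRUE) - curves) / (m - 1)
  rowSums((curves - loo_mean)^2) * dr
}

#' Monte Carlo goodness-of-fit test
#'
#' The rank-based test of a point pattern against a Monte Carlo null model:
#' the deviation `u` (see [u_statistic()]) of the empirical summary curve is
#' ranked among the deviations of the simulated curves, giving
#' `p = (1 + #\{u_sim >= u_obs\}) / (n_sim + 1)`. Ties count toward
#' rejection (the conservative convention); the smallest attainable p is
#' `1 / (n_sim + 1)`.
#'
#' @param pattern A [point_pattern()].
#' @param statistic,null Passed to [make_envelope()].
#' @param n_sim Number of simulations (default 999).
#' @param r_max Upper end of the tested distance interval in meters
#'   (default 9); the test integrates over the `[0, r_max]` prefix of `grid`.
#' @param grid Evaluation grid; default: the standard analysis grid of the
#'   window, restricted to `[0, r_max]`.
#' @param seed Optional master seed.
#' @param type1,type2 Mark values for the bivariate statistic.
#' @return An object of class `gof_result`: `u_observed`, `u_simulated`,
#'   `p_value`, `r_max`, `n_sim`, `null`, `statistic`, `seed`, and the
#'   underlying `envelope`.
#' @export
gof_test <- function(pattern, statistic = c("univariate", "bivariate"),
                     null = c("csr", "independence"), n_sim = 999, r_max = 9,
                     grid = NULL, seed = NULL,
                     type1 = "large", type2 = "small") {
  statistic <- match.arg(statistic)
  null <- match.arg(null)
  if (is.null(grid)) grid <- restrict_grid(default_grid(pattern$window), r_max)
  env <- make_envelope(pattern, statistic, null, n_sim = n_sim, grid = grid,
                       seed = seed, type1 = type1, type2 = type2)
  gof_from_envelope(env)
}

#' @rdname gof_test
#' @param env An `envelope_set` (e.g. reloaded from export); the test is
#'   recomputed from its curves.
#' @export
gof_from_envelope <- function(env) {
  stopifnot(inherits(env, "envelope_set"))
  curves <- rbind(env$empirical, env$sims)
  u <- u_statistic(curves, env$grid$dr)
  u_obs <- u[1]; u_sim <- u[-1]
  p <- (1 + sum(u_sim >= u_obs)) / (env$n_sim + 1)
  structure(list(u_observed = u_obs, u_simulated = u_sim, p_value = p,
                 r_max = env$grid$r_max, n_sim = env$n_sim, null = env$null,
                 statistic = env$statistic, seed = env$seed, envelope = env),
            class = "gof_result")
}

#' @export
print.gof_result <- function(x, ...) {
  cat(sprintf("goodness-of-fit: %s statistic vs %s null over [0, %g] m\n",
              x$statistic, x$null, x$r_max))
  cat(sprintf("  u = %.6g, P = %.4g (%d simulations)\n",
              x$u_observed, x$p_value, x$n_sim))
  invisible(x)
}

#' Bonferroni-corrected per-test threshold
#'
#' @param alpha Family-wise error level in (0, 1).
#' @param m Number of tests (>= 1).
#' @return `alpha / m`. With `alpha = 0.05` and a battery of 12 tests the
#'   per-test threshold is 0.00417, i.e. 0.004 at three decimals.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  stopifnot(alpha > 0, alpha < 1, m >= 1)
  alpha / m
}

#' Assemble a battery of tests under family-wise control
#'
#' @param results Named list of `gof_result` objects.
#' @param alpha Family-wise error level.
#' @return Data frame of class `test_battery` with one row per test:
#'   `test`, `statistic`, `null`, `u_observed`, `p_value`, `n_sim`,
#'   `threshold`, `reject`.
#' @export
test_battery <- function(results, alpha = 0.05) {
  stopifnot(length(results) >= 1, !is.null(names(results)))
  thr <- bonferroni_threshold(alpha, length(results))
  out <- do.call(rbind, lapply(names(results), function(nm) {
    g <- results[[nm]]
    data.frame(test = nm, statistic = g$statistic, null = g$null,
               u_observed = g$u_observed, p_value = g$p_value,
               n_sim = g$n_sim, threshold = thr, reject = g$p_value <= thr,
               stringsAsFactors = FALSE)
  }))
  class(out) <- c("test_battery", "data.frame")
  attr(out, "alpha") <- alpha
  out
}

#' Export a goodness-of-fit result as JSON
#'
#' @param x A `gof_result`.
#' @param path Output path.
#' @export
write_gof_result <- function(x, path) {
  jsonlite::write_json(list(u_observed = x$u_observed, p_value = x$p_value,
                            n_sim = x$n_sim, r_max = x$r_max, null = x$null,
                            statistic = x$statistic, seed = x$seed),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Post-hoc power against a hard-core alternative
#'
#' Simulates hard-core (simple sequential inhibition) patterns at a given
#' intensity, tests each against the CSR null with the Monte Carlo
#' goodness-of-fit test, and returns the fraction rejected: the power of the
#' test to distinguish hard-core inhibition from randomness at that sample
#' size. With `hardcore_radius = 0` the null is true and the rejection rate
#' estimates the test's size (about `alpha`).
#'
#' @param n Points per pattern.
#' @param window A [plot_window()].
#' @param hardcore_radius Minimum interpoint distance of the alternative (m).
#' @param n_experiments Number of simulated experiments.
#' @param n_sim Simulations per test.
#' @param r_max Tested interval (m).
#' @param alpha Rejection level.
#' @param seed Optional master seed.
#' @return A list: `power` (rejection fraction), `p_values`,
#'   `n_experiments`.
#' @export
power_vs_hardcore <- function(n, window, hardcore_radius, n_experiments = 100,
                              n_sim = 99, r_max = 9, alpha = 0.05,
                              seed = NULL) {
  seeds <- substream_seeds(seed, 2L * n_experiments)
  p <- vapply(seq_len(n_experiments), function(k) {
    pat <- simulate_ssi(n, window, hardcore_radius, seed = seeds[2 * k - 1])
    gof_test(pat, "univariate", "csr", n_sim = n_sim, r_max = r_max,
             seed = seeds[2 * k])$p_value
  }, numeric(1))
  list(power = mean(p <= alpha), p_values = p, n_experiments = n_experiments)
}
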