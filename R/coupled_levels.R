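#' Simulate all pattern levels of one realization with shared randomness
#'
#' A paired Monte Carlo design for comparing the seven pattern levels: the
#' inhibition family (`ssi-*` and `random`) filters one shared uniform
#' proposal stream at different inhibition radii (radius 0 accepts every
#' proposal, which is exactly CSR), and the cluster family (`matern-*`)
#' scales one shared parent/offspring draw to the different cluster radii
#' (parents on the widest dilation thinned to each radius' dilation - a
#' Poisson process restricted to a subregion is again Poisson, so each
#' level's marginal distribution is untouched). Sharing the randomness makes
#' realizations positively correlated across levels, so level contrasts
#' (e.g. differences in mean quadrat-basal-area CV) are estimated with far
#' smaller variance than under independent streams - the same reason paired
#' designs beat unpaired ones.
#'
#' @param levels Subset of [pattern_levels()].
#' @param n Exact point count per pattern.
#' @param window A [plot_window()].
#' @param seed Integer seed for this realization.
#' @param kappa,mu Matern parameters.
#' @param max_attempts Consecutive-rejection budget for the inhibition
#'   family.
#' @param max_retries Regeneration budget for the cluster family.
#' @return Named list of [point_pattern()]s, one per requested level.
#' @export
simulate_coupled_levels <- function(levels, n, window, seed = NULL,
                                    kappa = 0.00055, mu = 5,
                                    max_attempts = 100000L,
                                    max_retries = 100L) {
  stopifnot(all(levels %in% pattern_levels()))
  seeds <- substream_seeds(seed, 2L + length(levels))
  out <- vector("list", length(levels))
  names(out) <- levels

  inh <- levels[startsWith(levels, "ssi") | levels == "random"]
  if (length(inh)) {
    radii <- numeric(length(inh))
    is_ssi <- inh != "random"
    radii[is_ssi] <- as.numeric(sub("^ssi-", "", inh[is_ssi]))
    props <- proposal_stream(seeds[1], window)
    for (i in seq_along(inh)) {
      out[[inh[i]]] <- ssi_filter(props, n, radii[i], window, max_attempts)
    }
  }

  mat <- levels[startsWith(levels, "matern")]
  if (length(mat)) {
    radii <- as.numeric(sub("^matern-", "", mat))
    pats <- matern_coupled(n, window, radii, kappa, mu, seeds[2],
                           max_retries = max_retries)
    for (i in seq_along(mat)) out[[mat[i]]] <- pats[[i]]
  }
  out
}

# A replayable uniform proposal stream: chunk j is generated from a seed
# derived once, so every consumer sees the identical proposal sequence.
proposal_stream <- function(seed, window, chunk = 4096L) {
  chunk_seeds <- substream_seeds(seed, 1024L)
  cache <- new.env(parent = emptyenv())
  function(j) {
    key <- as.character(j)
    if (is.null(cache[[key]])) {
      if (j > length(chunk_seeds)) {
        stop("proposal stream exhausted", call. = FALSE)
      }
      cache[[key]] <- with_seed(chunk_seeds[j], cbind(
        stats::runif(chunk, 0, window$width),
        stats::runif(chunk, 0, window$height)))
    }
    cache[[key]]
  }
}

# Greedy sequential-inhibition filter over a shared proposal stream;
# distributionally identical to simulate_ssi at the same radius.
ssi_filter <- function(props, n, radius, window, max_attempts) {
  x <- numeric(n); y <- numeric(n)
  placed <- 0L; consec <- 0L; r2 <- radius^2
  j <- 1L
  while (placed < n) {
    block <- props(j); j <- j + 1L
    for (k in seq_len(nrow(block))) {
      px <- block[k, 1]; py <- block[k, 2]
      ok <- placed == 0L || r2 == 0 ||
        !any((x[seq_len(placed)] - px)^2 + (y[seq_len(placed)] - py)^2 < r2)
      if (ok) {
        placed <- placed + 1L
        x[placed] <- px; y[placed] <- py
        consec <- 0L
        if (placed == n) break
      } else {
        consec <- consec + 1L
        if (consec >= max_attempts) {
          stop(sprintf(paste0("sequential inhibition packing failed: %d of",
                              " %d points placed at radius %g m"),
                       placed, n, radius), call. = FALSE)
        }
      }
    }
  }
  point_pattern(x, y, window)
}

# One shared Matern parent/offspring draw realized at several cluster radii.
# Each offspring carries a uniform priority score; a level keeps its n
# lowest-priority in-window offspring, which is marginally a uniformly
# random n-subset but shares the selection across radii.
matern_coupled <- function(n, window, radii, kappa, mu, seed, max_retries) {
  W <- window$width; H <- window$height
  Rmax <- max(radii)
  draw_seeds <- substream_seeds(seed, max_retries)
  for (try in seq_len(max_retries)) {
    parts <- with_seed(draw_seeds[try], {
      n_par <- stats::rpois(1, kappa * (W + 2 * Rmax) * (H + 2 * Rmax))
      if (n_par == 0) NULL else {
        px <- stats::runif(n_par, -Rmax, W + Rmax)
        py <- stats::runif(n_par, -Rmax, H + Rmax)
        n_off <- stats::rpois(n_par, mu)
        total <- sum(n_off)
        list(px = px, py = py, n_off = n_off,
             u = stats::runif(total), theta = stats::runif(total, 0, 2 * pi),
             prio = stats::runif(total))
      }
    })
    if (is.null(parts)) next
    pats <- vector("list", length(radii))
    ok <- TRUE
    for (i in seq_along(radii)) {
      R <- radii[i]
      keep_par <- parts$px >= -R & parts$px <= W + R &
        parts$py >= -R & parts$py <= H + R
      off_par <- rep(seq_along(parts$n_off), parts$n_off)
      keep_off <- keep_par[off_par]
      rho <- R * sqrt(parts$u[keep_off])
      th <- parts$theta[keep_off]
      ox <- parts$px[off_par][keep_off] + rho * cos(th)
      oy <- parts$py[off_par][keep_off] + rho * sin(th)
      prio <- parts$prio[keep_off]
      inside <- ox >= 0 & ox <= W & oy >= 0 & oy <= H
      ox <- ox[inside]; oy <- oy[inside]; prio <- prio[inside]
      if (length(ox) < n) { ok <- FALSE; break }
      pick <- order(prio)[seq_len(n)]
      pats[[i]] <- point_pattern(ox[pick], oy[pick], window)
    }
    if (ok) return(pats)
  }
  stop(sprintf(paste0("Matern simulation could not reach %d in-window ",
                      "points in %d attempts (kappa = %g, mu = %g)"),
               n, max_retries, kappa, mu), call. = FALSE)
}
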