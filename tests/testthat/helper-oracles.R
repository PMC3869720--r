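# Independent oracles used across the suite. These deliberately avoid the
# package's fast paths: edge weights by numeric arc integration, K by a
# double loop, toroidal distances from first principles.

# In-window circumference fraction by dense arc sampling (independent of
# the package's analytic geometry).
arc_fraction_oracle <- function(x, y, d, W, H, n_arc = 20000L) {
  theta <- (seq_len(n_arc) - 0.5) * 2 * pi / n_arc
  px <- x + d * cos(theta)
  py <- y + d * sin(theta)
  mean(px >= 0 & px <= W & py >= 0 & py <= H)
}

# O(n^2 * n_r) Ripley K with oracle edge weights.
brute_force_K <- function(pp, r_values) {
  n <- length(pp$x)
  W <- pp$window$width
  H <- pp$window$height
  A <- W * H
  vapply(r_values, function(r) {
    s <- 0
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      d <- sqrt((pp$x[i] - pp$x[j])^2 + (pp$y[i] - pp$y[j])^2)
      if (d <= r && d > 0) {
        s <- s + 1 / arc_fraction_oracle(pp$x[i], pp$y[i], d, W, H)
      }
    }
    A * s / (n * (n - 1))
  }, numeric(1))
}

# Toroidal pairwise distance matrix.
toroidal_dist <- function(x, y, W, H) {
  dx <- abs(outer(x, x, "-")); dy <- abs(outer(y, y, "-"))
  dx <- pmin(dx, W - dx); dy <- pmin(dy, H - dy)
  sqrt(dx^2 + dy^2)
}

# Mean nearest-neighbor distance of a pattern.
mean_nn <- function(pp) {
  D <- as.matrix(stats::dist(cbind(pp$x, pp$y)))
  diag(D) <- Inf
  mean(apply(D, 1, min))
}

# A small hand-built valid stem table.
tiny_stems <- function() {
  data.frame(
    tag = c("t1", "t2", "t3"),
    species = c("TSHE", "TSHE", "PSME"),
    x = c(10, 50, 90), y = c(10, 25, 40),
    dbh = c(5, 40, 120), status = "live",
    stringsAsFactors = FALSE)
}
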