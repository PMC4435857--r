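# Independent brute-force oracles for the vectorized implementations.

# Higuchi normalized curve length for one lag, straight from the defining
# nested sums.
higuchi_brute <- function(x, k) {
  n <- length(x)
  l_m <- numeric(k)
  for (m in seq_len(k)) {
    ni <- floor((n - m) / k)
    s <- 0
    for (i in seq_len(ni)) {
      s <- s + abs(x[m + i * k] - x[m + (i - 1) * k])
    }
    l_m[m] <- s * (n - 1) / (ni * k)
  }
  mean(l_m) / k
}

# ICC(2,1) with mean squares taken from stats::aov on the long-format
# two-way layout.
icc21_aov <- function(y1, y2) {
  n <- length(y1)
  d <- data.frame(y = c(y1, y2),
                  subj = factor(rep(seq_len(n), 2)),
                  sess = factor(rep(1:2, each = n)))
  ms <- summary(stats::aov(y ~ subj + sess, data = d))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  k <- 2
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# Polar area by Riemann sum of 0.5 * r(phi)^2 over a dense angle grid.
outline_area_quadrature <- function(outline, n_grid = 1e5) {
  phi <- seq(0, 2 * pi, length.out = n_grid + 1)[-(n_grid + 1)]
  r <- outline_radius(outline, phi)
  0.5 * sum(r^2) * (2 * pi / n_grid)
}

# Extreme radius per angular bin by direct scan over all points.
extreme_points_brute <- function(ml, ap, n_intervals, center) {
  dx <- ml - center[1]; dy <- ap - center[2]
  ang <- atan2(dy, dx) %% (2 * pi)
  r <- sqrt(dx^2 + dy^2)
  width <- 2 * pi / n_intervals
  out <- list()
  for (b in seq_len(n_intervals)) {
    idx <- which(ang >= (b - 1) * width & ang < b * width)
    if (!length(idx)) next
    out[[length(out) + 1]] <- c(bin = b, radius = max(r[idx]))
  }
  do.call(rbind, out)
}
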