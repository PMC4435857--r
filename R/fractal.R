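#' Default lag grid for Higuchi curve lengths
#'
#' Dense integer lags where they are cheap (every k with k/fs inside the
#' short regime) and ~25 log-spaced unique integers spanning the long
#' regime, matching the log/log geometry of the fractal regression. Lags
#' are capped at `floor((n - 1) / 4)` so every offset keeps several
#' increments.
#'
#' @param sampling_rate_hz sampling rate (Hz).
#' @param n series length.
#' @param short_window,long_window regime windows in seconds (lag duration).
#' @param n_long target number of log-spaced lags in the long regime.
#' @return increasing integer vector of lags.
#' @export
default_k_grid <- function(sampling_rate_hz = 50, n = 3000,
                           short_window = c(0, 0.3), long_window = c(0.8, 12),
                           n_long = 25) {
  k_cap <- max(2L, floor((n - 1) / 4))
  k_short <- seq_len(min(floor(short_window[2L] * sampling_rate_hz), k_cap))
  lo <- max(1, ceiling(long_window[1L] * sampling_rate_hz))
  hi <- min(floor(long_window[2L] * sampling_rate_hz), k_cap)
  k_long <- if (hi >= lo) {
    unique(round(exp(seq(log(lo), log(hi), length.out = n_long))))
  } else integer(0)
  sort(unique(c(k_short, k_long)))
}

#' Higuchi normalized curve lengths
#'
#' For each lag k, the mean over offsets m = 1..k of the normalized curve
#' length
#' `L_m(k) = [sum_i |x(m + i k) - x(m + (i-1) k)|] * (n - 1) / (floor((n - m)/k) * k)`,
#' divided by k:  `L(k) = mean_m L_m(k) / k`. On a log/log plot L(k) falls
#' as `k^(-D)` with D the fractal dimension of the series' graph (D = 1 for
#' a smooth ramp, 2 for white noise, 2 - H for fractional Brownian motion).
#'
#' @param series numeric vector (finite).
#' @param sampling_rate_hz sampling rate, carried along so lags can be
#'   expressed as durations.
#' @param k_set increasing positive integer lags, each `<= floor((n-1)/2)`.
#' @return object of class `curve_lengths`: list with `k_values`, `lengths`,
#'   `sampling_rate_hz` and `constant` (TRUE when the series has no
#'   variation, in which case all lengths are 0 and the regression refuses
#'   to fit).
#' @export
higuchi_lengths <- function(series, sampling_rate_hz = 50,
                            k_set = default_k_grid(sampling_rate_hz,
                                                   length(series))) {
  x <- as.numeric(series)
  n <- length(x)
  if (!all(is.finite(x))) stop("series must be finite")
  k_set <- sort(unique(as.integer(k_set)))
  if (any(k_set < 1L)) stop("lags must be positive integers")
  if (n < 2L * max(k_set)) {
    stop("series too short: need n >= 2 * max(k) = ", 2L * max(k_set),
         ", got ", n)
  }
  lengths <- vapply(k_set, function(k) {
    d <- abs(x[(k + 1L):n] - x[1:(n - k)])          # all lag-k increments
    m_of <- ((seq_len(n - k) - 1L) %% k) + 1L        # offset of each increment
    s_m <- as.numeric(rowsum(d, m_of))               # per-offset sums, m = 1..k
    n_m <- floor((n - seq_len(k)) / k)               # increments per offset
    mean(s_m * (n - 1) / (n_m * k)) / k
  }, 0)
  structure(list(k_values = k_set, lengths = lengths,
                 sampling_rate_hz = sampling_rate_hz,
                 constant = all(lengths == 0)),
            class = "curve_lengths")
}

#' Fractal dimension from a lag window of curve lengths
#'
#' Unweighted least-squares line of `log L(k)` on `log k` restricted to
#' lags whose duration k/fs lies in `window_s` (boundaries inclusive); the
#' fractal dimension is minus the slope.
#'
#' @param lengths a [higuchi_lengths()] result.
#' @param window_s length-2 numeric, lag-duration window in seconds.
#' @param axis,regime optional labels stored on the fit (e.g. "ML",
#'   "short").
#' @return object of class `fractal_fit`: list with `axis`, `regime`,
#'   `window_s`, `slope`, `fd` (= -slope), `r_squared`, `n_points`.
#' @export
fit_fd <- function(lengths, window_s, axis = NA_character_,
                   regime = NA_character_) {
  stopifnot(inherits(lengths, "curve_lengths"), length(window_s) == 2L)
  tol <- 1e-9
  dur <- lengths$k_values / lengths$sampling_rate_hz
  in_win <- dur >= window_s[1L] - tol & dur <= window_s[2L] + tol
  k <- lengths$k_values[in_win]
  L <- lengths$lengths[in_win]
  if (length(k) < 2L) {
    stop(sprintf("insufficient window: only %d lag(s) in [%g, %g] s",
                 length(k), window_s[1L], window_s[2L]))
  }
  if (any(L <= 0)) {
    stop("non-positive curve length in window (constant or degenerate series)")
  }
  lx <- log(k); ly <- log(L)
  slope <- sum((lx - mean(lx)) * (ly - mean(ly))) / sum((lx - mean(lx))^2)
  fitted <- mean(ly) + slope * (lx - mean(lx))
  ss_res <- sum((ly - fitted)^2)
  ss_tot <- sum((ly - mean(ly))^2)
  structure(
    list(axis = axis, regime = regime, window_s = as.numeric(window_s),
         slope = slope, fd = -slope,
         r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
         n_points = length(k)),
    class = "fractal_fit")
}

#' @export
print.fractal_fit <- function(x, ...) {
  cat(sprintf("Higuchi FD %s/%s [%g, %g] s: fd = %.3f (R2 = %.3f, %d lags)\n",
              x$axis, x$regime, x$window_s[1L], x$window_s[2L],
              x$fd, x$r_squared, x$n_points))
  invisible(x)
}

#' Four fractal dimensions of a trial
#'
#' Higuchi curve lengths once per axis over the default lag grid, then a
#' regression per regime: ML/AP x short (0-0.3 s) / long (0.8-12 s). The
#' interval between the regimes is excluded as a transition region.
#'
#' @param trial a [cop_trial].
#' @param k_set lag grid; default [default_k_grid()].
#' @param short_window,long_window regime windows in seconds.
#' @return list of four `fractal_fit` objects, in order ML/short, ML/long,
#'   AP/short, AP/long.
#' @export
fd_all <- function(trial, k_set = default_k_grid(trial$sampling_rate_hz,
                                                 length(trial$ml_cm),
                                                 short_window, long_window),
                   short_window = c(0, 0.3), long_window = c(0.8, 12)) {
  stopifnot(inherits(trial, "cop_trial"))
  fits <- list()
  for (axis in c("ML", "AP")) {
    x <- if (axis == "ML") trial$ml_cm else trial$ap_cm
    cl <- higuchi_lengths(x, trial$sampling_rate_hz, k_set)
    fits[[length(fits) + 1L]] <- fit_fd(cl, short_window, axis, "short")
    fits[[length(fits) + 1L]] <- fit_fd(cl, long_window, axis, "long")
  }
  fits
}
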