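#' 95% PCA confidence ellipse of the CoP cloud
#'
#' Eigen-decomposition of the 2x2 sample covariance matrix of (ML, AP). The
#' principal-axis standard deviations s0 are the square roots of the
#' eigenvalues; the 95% ellipse has semi-axes 1.96 s0 and area
#' `pi * 1.96^2 * s0_major * s0_minor`.
#'
#' @param trial a [cop_trial] (or any object with `ml_cm`, `ap_cm`).
#' @param multiplier semi-axis multiplier in SD units; 1.96 gives the
#'   conventional 95% ellipse.
#' @return object of class `ellipse_model`: list with `center_ml_cm`,
#'   `center_ap_cm`, `s0_major_cm`, `s0_minor_cm`, `orientation_rad`
#'   (major-axis angle from the ML axis) and `area_cm2`.
#' @export
fit_pca_ellipse <- function(trial, multiplier = 1.96) {
  ml <- trial$ml_cm; ap <- trial$ap_cm
  if (length(ml) < 3L) stop("need at least 3 samples for a covariance ellipse")
  S <- stats::cov(cbind(ml, ap))
  if (all(abs(S) < .Machine$double.eps)) {
    warning("all CoP points identical: zero-area ellipse")
    ev <- list(values = c(0, 0), vectors = diag(2))
  } else {
    ev <- eigen(S, symmetric = TRUE)
  }
  lam <- pmax(ev$values, 0)  # clip tiny negative eigenvalues from roundoff
  s0 <- sqrt(lam)
  structure(
    list(center_ml_cm = mean(ml), center_ap_cm = mean(ap),
         s0_major_cm = s0[1L], s0_minor_cm = s0[2L],
         orientation_rad = atan2(ev$vectors[2L, 1L], ev$vectors[1L, 1L]),
         multiplier = multiplier,
         area_cm2 = pi * multiplier^2 * s0[1L] * s0[2L]),
    class = "ellipse_model")
}

#' @export
print.ellipse_model <- function(x, ...) {
  cat(sprintf(
    "PCA ellipse: centre (%.3f, %.3f) cm, s0 = (%.3f, %.3f) cm, area %.3f cm2\n",
    x$center_ml_cm, x$center_ap_cm, x$s0_major_cm, x$s0_minor_cm, x$area_cm2))
  invisible(x)
}

#' Extreme CoP radii in angular bins
#'
#' Partitions [0, 2*pi) into `n_intervals` equal bins by the polar angle of
#' each CoP sample about `center` (default: centroid) and returns, per
#' non-empty bin, the most distant sample. Ties for the extreme radius go to
#' the first occurrence.
#'
#' @param trial a [cop_trial].
#' @param n_intervals number of angular bins (>= 8; default 100).
#' @param center length-2 numeric (ML, AP) centre; default the centroid.
#' @return data.frame with one row per non-empty bin: `bin`, `angle_bin_rad`
#'   (bin-centre angle), `angle_point_rad` (angle of the extreme sample,
#'   used by default in the outline fit) and `radius_cm`.
#' @export
extreme_points <- function(trial, n_intervals = 100, center = NULL) {
  if (n_intervals < 8L) stop("n_intervals must be at least 8")
  ml <- trial$ml_cm; ap <- trial$ap_cm
  if (is.null(center)) center <- c(mean(ml), mean(ap))
  dx <- ml - center[1L]; dy <- ap - center[2L]
  ang <- atan2(dy, dx) %% (2 * pi)
  r <- sqrt(dx^2 + dy^2)
  width <- 2 * pi / n_intervals
  bin <- pmin(floor(ang / width), n_intervals - 1L) + 1L
  keep <- integer(0)
  for (b in sort(unique(bin))) {
    idx <- which(bin == b)
    keep <- c(keep, idx[which.max(r[idx])])
  }
  if (length(keep) < 3L) {
    stop("degenerate outline: fewer than 3 non-empty angular bins")
  }
  data.frame(bin = bin[keep],
             angle_bin_rad = (bin[keep] - 0.5) * width,
             angle_point_rad = ang[keep],
             radius_cm = r[keep])
}

#' Fit a Fourier-series outline to polar samples
#'
#' Ordinary least-squares fit of the radius function
#' `r(phi) = A0 + sum_{m=1..m_max} (Am cos(m phi) + Bm sin(m phi))`
#' to (angle, radius) pairs, typically the output of [extreme_points()].
#' The constant term A0 is included so a closed outline of nonzero mean
#' radius is representable.
#'
#' @param polar_samples data.frame with columns `angle_point_rad` (or
#'   `angle_rad`) and `radius_cm`, or a 2-column matrix (angle, radius).
#' @param m_max Fourier order (default 20); needs at least `2 * m_max + 1`
#'   samples.
#' @param use_bin_centre fit at bin-centre angles (`angle_bin_rad`) instead
#'   of the extreme-point angles; default `FALSE`.
#' @return object of class `outline_model`: list with `coeff_a` (A0..Amax),
#'   `coeff_b` (B1..Bmax), `m_max`, `n_samples`, `residual_rms_cm`,
#'   `center_ml_cm`/`center_ap_cm` (carried through when present) and
#'   `area_cm2` (closed-form polar area, see [outline_area()]).
#' @export
fit_outline <- function(polar_samples, m_max = 20, use_bin_centre = FALSE) {
  if (is.matrix(polar_samples)) {
    phi <- polar_samples[, 1L]; r <- polar_samples[, 2L]
  } else {
    acol <- if (use_bin_centre && "angle_bin_rad" %in% names(polar_samples)) {
      "angle_bin_rad"
    } else if ("angle_point_rad" %in% names(polar_samples)) {
      "angle_point_rad"
    } else "angle_rad"
    phi <- polar_samples[[acol]]; r <- polar_samples[["radius_cm"]]
  }
  n <- length(phi)
  if (n < 2 * m_max + 1) {
    stop("underdetermined outline fit: ", n, " samples for order ", m_max,
         "; lower m_max (need at least ", 2 * m_max + 1, ")")
  }
  X <- matrix(1, n, 2 * m_max + 1)
  for (m in seq_len(m_max)) {
    X[, 2 * m] <- cos(m * phi)
    X[, 2 * m + 1] <- sin(m * phi)
  }
  fit <- stats::lm.fit(X, r)
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  a <- beta[c(1L, 2L * seq_len(m_max))]
  b <- beta[2L * seq_len(m_max) + 1L]
  out <- structure(
    list(coeff_a = unname(a), coeff_b = unname(b), m_max = m_max,
         n_samples = n, residual_rms_cm = sqrt(mean(fit$residuals^2)),
         center_ml_cm = NA_real_, center_ap_cm = NA_real_,
         area_cm2 = NA_real_),
    class = "outline_model")
  out$area_cm2 <- outline_area(out)
  out
}

#' Fitted radius of an outline model
#'
#' @param outline an `outline_model`.
#' @param phi angles (radians) at which to evaluate the fitted radius.
#' @return numeric vector of radii.
#' @export
outline_radius <- function(outline, phi) {
  r <- rep(outline$coeff_a[1L], length(phi))
  for (m in seq_len(outline$m_max)) {
    r <- r + outline$coeff_a[m + 1L] * cos(m * phi) +
      outline$coeff_b[m] * sin(m * phi)
  }
  r
}

#' Area enclosed by a Fourier outline
#'
#' Closed-form polar area `0.5 * integral r(phi)^2 dphi
#' = pi * A0^2 + (pi/2) * sum (Am^2 + Bm^2)`, valid for a non-negative
#' radius function. Non-negativity is checked on a 1000-point angle grid.
#'
#' @param outline an `outline_model`.
#' @param n_check grid size for the non-negativity check.
#' @return area in cm^2.
#' @export
outline_area <- function(outline, n_check = 1000) {
  grid <- seq(0, 2 * pi, length.out = n_check + 1L)[-(n_check + 1L)]
  rg <- outline_radius(outline, grid)
  bad <- which(rg < -1e-12)
  if (length(bad)) {
    stop(sprintf(
      "invalid outline: fitted radius negative (%.4g) at angle %.4f rad",
      rg[bad[1L]], grid[bad[1L]]))
  }
  a <- outline$coeff_a; b <- outline$coeff_b
  pi * a[1L]^2 + (pi / 2) * (sum(a[-1L]^2) + sum(b^2))
}

#' @export
print.outline_model <- function(x, ...) {
  cat(sprintf(
    "Fourier outline: order %d, %d samples, A0 = %.3f cm, area %.3f cm2, residual RMS %.4f cm\n",
    x$m_max, x$n_samples, x$coeff_a[1L], x$area_cm2, x$residual_rms_cm))
  invisible(x)
}

#' Sway area by the Fourier-analysis outline (FAO)
#'
#' Convenience wrapper: extreme radii in `n_intervals` angular bins about
#' the CoP centroid, order-`m_max` Fourier fit, closed-form area.
#'
#' @inheritParams extreme_points
#' @inheritParams fit_outline
#' @return the fitted `outline_model` with `center_ml_cm`/`center_ap_cm` set.
#' @export
fao_area <- function(trial, n_intervals = 100, m_max = 20,
                     use_bin_centre = FALSE) {
  center <- c(mean(trial$ml_cm), mean(trial$ap_cm))
  pts <- extreme_points(trial, n_intervals = n_intervals, center = center)
  out <- fit_outline(pts, m_max = m_max, use_bin_centre = use_bin_centre)
  out$center_ml_cm <- center[1L]
  out$center_ap_cm <- center[2L]
  out
}
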