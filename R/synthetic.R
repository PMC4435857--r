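#' Configuration for the synthetic cohort generator
#'
#' Defines a two-group, four-condition, two-session cohort of CoP trials
#' with a known variance-components structure. Each subject j draws a
#' between-subject log-scale effect `u_j ~ N(0, sigma_subject^2)`; each
#' session s adds `v_js ~ N(0, sigma_session^2)`; the trial's per-axis sway
#' scale is `base_group * mult_condition * exp(u_j + v_js)`. The designed
#' test-retest ICC on the log sway-scale is therefore
#' `sigma_subject^2 / (sigma_subject^2 + sigma_session^2)`.
#'
#' Defaults mirror a young (n = 26) and an elderly (n = 15) cohort with
#' firm/compliant x eyes open/closed conditions whose difficulty ordering
#' FO < FC < CO < CC is encoded in the condition multipliers.
#'
#' @param n_subjects named integer vector, subjects per group.
#' @param base_scale_ml,base_scale_ap named numeric vectors, per-group base
#'   sway SD (cm) on each axis in the easiest condition.
#' @param condition_mult named numeric vector, per-condition multiplier of
#'   the sway scale.
#' @param sigma_subject between-subject SD of the log sway-scale.
#' @param sigma_session within-subject, between-session SD of the log
#'   sway-scale.
#' @param trace_model `"ou"` (Ornstein-Uhlenbeck, stationary, exact unit
#'   variance), `"fgn"` (integrated fractional Gaussian noise, sample-
#'   standardized; fractal dimension 2 - hurst) or `"mixture"` (equal-power
#'   sum of the two).
#' @param hurst Hurst exponent for the fgn/mixture trace (0 < H < 1).
#' @param ou_theta OU mean-reversion rate (1/s).
#' @param axis_correlation correlation between the ML and AP innovations
#'   (default 0, independent axes).
#' @param sampling_rate_hz,duration_s acquisition convention (50 Hz, 60 s).
#' @param seed integer seed; together with the config it fully determines
#'   the generated cohort.
#' @return list of class `synthetic_config` with a `designed_icc` field.
#' @export
synthetic_config <- function(n_subjects = c(young = 26L, elderly = 15L),
                             base_scale_ml = c(young = 0.44, elderly = 0.57),
                             base_scale_ap = c(young = 0.51, elderly = 0.62),
                             condition_mult = c(FO = 1, FC = 1.2, CO = 1.5, CC = 2.7),
                             sigma_subject = 0.5, sigma_session = 1 / 6,
                             trace_model = c("ou", "fgn", "mixture"),
                             hurst = 0.8, ou_theta = 2, axis_correlation = 0,
                             sampling_rate_hz = 50, duration_s = 60,
                             seed = 1L) {
  trace_model <- match.arg(trace_model)
  stopifnot(all(n_subjects >= 1), sigma_subject >= 0, sigma_session >= 0,
            hurst > 0, hurst < 1, ou_theta > 0,
            abs(axis_correlation) <= 1,
            sampling_rate_hz > 0, duration_s > 0)
  if (is.null(names(n_subjects))) stop("n_subjects must be named by group")
  cfg <- list(n_subjects = n_subjects, base_scale_ml = base_scale_ml,
              base_scale_ap = base_scale_ap, condition_mult = condition_mult,
              sigma_subject = sigma_subject, sigma_session = sigma_session,
              trace_model = trace_model, hurst = hurst, ou_theta = ou_theta,
              axis_correlation = axis_correlation,
              sampling_rate_hz = sampling_rate_hz, duration_s = duration_s,
              seed = as.integer(seed))
  cfg$designed_icc <- if (sigma_subject + sigma_session == 0) NA_real_ else
    sigma_subject^2 / (sigma_subject^2 + sigma_session^2)
  class(cfg) <- "synthetic_config"
  cfg
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort config: %s subjects, %d conditions x 2 sessions\n",
    paste(sprintf("%d %s", x$n_subjects, names(x$n_subjects)), collapse = " + "),
    length(x$condition_mult)))
  cat(sprintf("  trace %s, designed log-scale ICC %.3f, seed %d\n",
              x$trace_model, x$designed_icc, x$seed))
  invisible(x)
}

#' Fractional Gaussian noise by Davies-Harte circulant embedding
#'
#' Exact (to machine precision) stationary fGn of unit variance: the target
#' autocovariance `0.5 (|h+1|^{2H} - 2|h|^{2H} + |h-1|^{2H})` is embedded
#' in a circulant matrix whose eigenvalues, obtained by FFT, scale
#' independent complex Gaussian spectral amplitudes. The cumulative sum of
#' the output is fractional Brownian motion with graph fractal dimension
#' 2 - H.
#'
#' @param n length of the series.
#' @param hurst Hurst exponent, 0 < H < 1 (H = 0.5 gives white noise).
#' @param seed optional integer seed (set when not `NULL`).
#' @return numeric vector of length `n`.
#' @export
generate_fgn <- function(n, hurst, seed = NULL) {
  if (!(hurst > 0 && hurst < 1)) stop("hurst must be in (0, 1)")
  if (n < 1L) stop("n must be positive")
  if (!is.null(seed)) set.seed(seed)
  if (n == 1L) return(stats::rnorm(1))
  h2 <- 2 * hurst
  g <- 0.5 * (abs(seq(0, n) + 1)^h2 - 2 * abs(seq(0, n))^h2 +
                abs(seq(0, n) - 1)^h2)          # gamma(0..n)
  circ <- c(g[1:n], g[n + 1L], g[n:2])           # first row, length 2n
  lam <- Re(stats::fft(circ))
  if (any(lam < -1e-8 * max(lam))) {
    stop("circulant embedding failed: negative eigenvalue")
  }
  lam <- pmax(lam, 0)
  m <- 2L * n
  z1 <- stats::rnorm(n + 1L)                     # real parts, j = 1..n+1
  z2 <- stats::rnorm(n - 1L)                     # imaginary parts, j = 2..n
  v <- complex(length.out = m)
  v[1L] <- sqrt(lam[1L]) * z1[1L]
  v[n + 1L] <- sqrt(lam[n + 1L]) * z1[n + 1L]
  j <- 2:n
  v[j] <- sqrt(lam[j] / 2) * complex(real = z1[j], imaginary = z2[j - 1L])
  v[m - j + 2L] <- Conj(v[j])
  x <- Re(stats::fft(v)) / sqrt(m)
  x[1:n]
}

# Unit-SD trace of the configured model; the workhorse behind
# generate_trial. OU uses the exact discrete-time AR(1) form initialized
# from the stationary law, so the marginal variance is exactly 1; the fgn
# trace is an integrated fGn standardized by its sample SD.
unit_trace <- function(n, config) {
  dt <- 1 / config$sampling_rate_hz
  ou <- function() {
    phi <- exp(-config$ou_theta * dt)
    innov <- stats::rnorm(n, sd = sqrt(1 - phi^2))
    innov[1L] <- stats::rnorm(1)                 # stationary start
    as.numeric(stats::filter(innov, phi, method = "recursive"))
  }
  fgn_int <- function() {
    z <- cumsum(generate_fgn(n, config$hurst))
    z <- z - mean(z)
    s <- stats::sd(z)
    if (s > 0) z / s else z
  }
  switch(config$trace_model,
         ou = ou(),
         fgn = fgn_int(),
         mixture = (ou() + fgn_int()) / sqrt(2))
}

#' Generate one synthetic CoP trial
#'
#' Per-axis trace from the configured process (unit SD by construction or
#' standardization), multiplied by the requested sway scale so the trial's
#' expected positional SD equals the scale. Axes share no randomness unless
#' `axis_correlation` is nonzero, in which case the AP trace mixes in the
#' ML trace with the requested correlation.
#'
#' @param scale_ml,scale_ap target positional SD (cm) per axis (>= 0).
#' @param config a [synthetic_config()].
#' @param seed optional integer seed (set when not `NULL`; pass `NULL`
#'   inside [generate_cohort()], which manages one RNG stream).
#' @param subject_id,group,condition,session trial metadata.
#' @return a [cop_trial].
#' @export
generate_trial <- function(scale_ml, scale_ap, config = synthetic_config(),
                           seed = NULL, subject_id = "synthetic",
                           group = "young", condition = "FO", session = 1L) {
  stopifnot(scale_ml >= 0, scale_ap >= 0)
  if (!is.null(seed)) set.seed(seed)
  n <- round(config$duration_s * config$sampling_rate_hz)
  z_ml <- unit_trace(n, config)
  z_ap <- unit_trace(n, config)
  rho <- config$axis_correlation
  if (rho != 0) z_ap <- rho * z_ml + sqrt(1 - rho^2) * z_ap
  cop_trial(z_ml * scale_ml, z_ap * scale_ap,
            subject_id = subject_id, group = group, condition = condition,
            session = session, sampling_rate_hz = config$sampling_rate_hz)
}

#' Generate a full synthetic cohort with ground truth
#'
#' For each subject: a between-subject log-scale effect; for each session:
#' a session effect; for each condition: one trial per session with scale
#' `base_group * mult_condition * exp(u_j + v_js)` per axis. The default
#' configuration yields (26 + 15) subjects x 4 conditions x 2 sessions =
#' 328 trials. The RNG stream is fully determined by `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @return list with `trials` (a [trial_set]) and `truth` (data.frame of
#'   per-trial scale factors and effects, plus the config's designed ICC
#'   and, for fgn-type traces, the nominal fractal dimension 2 - hurst).
#' @export
generate_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  trials <- list()
  truth <- list()
  for (grp in names(config$n_subjects)) {
    for (j in seq_len(config$n_subjects[[grp]])) {
      sid <- sprintf("%s%02d", toupper(substr(grp, 1, 1)), j)
      u <- stats::rnorm(1, sd = config$sigma_subject)
      for (s in 1:2) {
        v <- stats::rnorm(1, sd = config$sigma_session)
        for (cond in names(config$condition_mult)) {
          fac <- config$condition_mult[[cond]] * exp(u + v)
          s_ml <- config$base_scale_ml[[grp]] * fac
          s_ap <- config$base_scale_ap[[grp]] * fac
          trials[[length(trials) + 1L]] <- generate_trial(
            s_ml, s_ap, config, seed = NULL, subject_id = sid, group = grp,
            condition = cond, session = s)
          truth[[length(truth) + 1L]] <- data.frame(
            subject_id = sid, group = grp, condition = cond, session = s,
            u = u, v = v, scale_ml = s_ml, scale_ap = s_ap,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  truth <- do.call(rbind, truth)
  attr(truth, "designed_icc") <- config$designed_icc
  attr(truth, "nominal_fd") <- if (config$trace_model == "fgn")
    2 - config$hurst else NA_real_
  list(trials = trial_set(trials, provenance = sprintf(
         "synthetic cohort (seed %d, designed ICC %.3f)",
         config$seed, config$designed_icc)),
       truth = truth)
}
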