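#' Positional variability of the CoP
#'
#' Sample standard deviation (n-1 denominator) of the medio-lateral and
#' antero-posterior CoP position series, in cm. These are the "variability"
#' variables of the standard stabilometric set.
#'
#' @param trial a [cop_trial].
#' @return named numeric vector `c(sd_ml_cm =, sd_ap_cm =)`.
#' @export
positional_variability <- function(trial) {
  stopifnot(inherits(trial, "cop_trial"))
  if (length(trial$ml_cm) < 2L) stop("insufficient data: need at least 2 samples")
  c(sd_ml_cm = stats::sd(trial$ml_cm), sd_ap_cm = stats::sd(trial$ap_cm))
}

#' CoP path lengths
#'
#' Total variation of each coordinate and the Euclidean length of the 2-D
#' CoP trajectory: `path_ml = sum |d ml|`, `path_ap = sum |d ap|`,
#' `path_total = sum sqrt(d ml^2 + d ap^2)` over successive samples.
#'
#' @param trial a [cop_trial].
#' @return named numeric vector `c(path_ml_cm =, path_ap_cm =, path_total_cm =)`.
#' @export
path_lengths <- function(trial) {
  stopifnot(inherits(trial, "cop_trial"))
  if (length(trial$ml_cm) < 2L) stop("insufficient data: need at least 2 samples")
  dml <- diff(trial$ml_cm)
  dap <- diff(trial$ap_cm)
  c(path_ml_cm = sum(abs(dml)),
    path_ap_cm = sum(abs(dap)),
    path_total_cm = sum(sqrt(dml^2 + dap^2)))
}

#' Mean CoP velocity
#'
#' Total path length divided by the trial duration (cm/s). For a standard
#' 60-s trial this is the mean of the absolute CoP speed over the
#' acquisition interval; velocity times 60 s reproduces the total path
#' exactly.
#'
#' @param trial a [cop_trial].
#' @return mean velocity in cm/s.
#' @export
mean_velocity <- function(trial) {
  dur <- trial_duration(trial)
  if (dur <= 0) stop("trial duration must be positive")
  unname(path_lengths(trial)[["path_total_cm"]] / dur)
}

#' All twelve sway variables for one trial
#'
#' Computes the full stabilometric variable set: ML/AP positional
#' variability, the three path lengths, mean velocity, sway area by the
#' Fourier-analysis outline (FAO) and by the 95% PCA ellipse, and the four
#' Higuchi fractal dimensions (ML/AP x short/long lag regime).
#'
#' @param trial a [cop_trial].
#' @param n_intervals angular bins for the FAO outline (default 100).
#' @param m_max Fourier order of the outline fit (default 20).
#' @param short_window,long_window lag windows in seconds for the two
#'   fractal regimes (defaults 0-0.3 s and 0.8-12 s).
#' @param k_set integer lag grid for the Higuchi curve lengths; default
#'   [default_k_grid()] for the trial's sampling rate.
#' @return one-row data.frame with the trial metadata and the twelve
#'   variables: `sd_ml_cm, sd_ap_cm, path_ml_cm, path_ap_cm, path_total_cm,
#'   mean_velocity_cm_s, area_fao_cm2, area_pca_cm2, fd_ml_short,
#'   fd_ml_long, fd_ap_short, fd_ap_long`.
#' @examples
#' set.seed(1)
#' tr <- generate_trial(0.44, 0.51, synthetic_config(), seed = 1)
#' sway_metrics(tr)
#' @export
sway_metrics <- function(trial, n_intervals = 100, m_max = 20,
                         short_window = c(0, 0.3), long_window = c(0.8, 12),
                         k_set = default_k_grid(trial$sampling_rate_hz,
                                                length(trial$ml_cm),
                                                short_window, long_window)) {
  stopifnot(inherits(trial, "cop_trial"))
  pv <- positional_variability(trial)
  pl <- path_lengths(trial)
  vel <- mean_velocity(trial)
  ell <- fit_pca_ellipse(trial)
  fao <- fao_area(trial, n_intervals = n_intervals, m_max = m_max)
  fits <- fd_all(trial, k_set = k_set,
                 short_window = short_window, long_window = long_window)
  fd_of <- function(axis, regime) {
    for (f in fits) if (f$axis == axis && f$regime == regime) return(f$fd)
    NA_real_
  }
  data.frame(
    subject_id = trial$subject_id, group = trial$group,
    condition = trial$condition, session = trial$session,
    sd_ml_cm = unname(pv[["sd_ml_cm"]]), sd_ap_cm = unname(pv[["sd_ap_cm"]]),
    path_ml_cm = unname(pl[["path_ml_cm"]]), path_ap_cm = unname(pl[["path_ap_cm"]]),
    path_total_cm = unname(pl[["path_total_cm"]]),
    mean_velocity_cm_s = vel,
    area_fao_cm2 = fao$area_cm2, area_pca_cm2 = ell$area_cm2,
    fd_ml_short = fd_of("ML", "short"), fd_ml_long = fd_of("ML", "long"),
    fd_ap_short = fd_of("AP", "short"), fd_ap_long = fd_of("AP", "long"),
    stringsAsFactors = FALSE)
}

#' Names of the twelve sway variables
#'
#' @param display if `TRUE`, return the human-readable labels used in the
#'   rendered reliability tables instead of the column names.
#' @return character vector of length 12.
#' @export
sway_variable_names <- function(display = FALSE) {
  cols <- c("sd_ml_cm", "sd_ap_cm", "path_ml_cm", "path_ap_cm",
            "path_total_cm", "mean_velocity_cm_s", "area_fao_cm2",
            "area_pca_cm2", "fd_ml_short", "fd_ml_long", "fd_ap_short",
            "fd_ap_long")
  if (!display) return(cols)
  c("Medio-lateral variability (cm)", "Antero-posterior variability (cm)",
    "Medio-lateral path length (cm)", "Antero-posterior path length (cm)",
    "Total path length (cm)", "Mean velocity (cm/s)",
    "Sway area FAO (cm2)", "Sway area PCA (cm2)",
    "Fractal dimension ML short interval", "Fractal dimension ML long interval",
    "Fractal dimension AP short interval", "Fractal dimension AP long interval")
}
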