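#' ICC(2,1): two-way random effects, absolute agreement, single measures
#'
#' Shrout-Fleiss ICC(2,1) from the two-way ANOVA mean squares of an
#' n-subject x k-session score matrix:
#' `(MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`, with the
#' approximate F-based 95% confidence interval of Shrout & Fleiss.
#'
#' @param session1,session2 numeric scores, one per subject, pairwise
#'   complete (the two-session layout of a test-retest design).
#' @param alpha confidence level is `1 - alpha` (default 0.05).
#' @return list with `icc`, `ci_low`, `ci_high` and the mean squares
#'   (`ms_rows`, `ms_cols`, `ms_error`).
#' @examples
#' s1 <- c(9, 6, 8, 7, 10, 6)
#' s2 <- c(10, 6, 7, 8, 9, 7)
#' icc_2_1(s1, s2)
#' @export
icc_2_1 <- function(session1, session2, alpha = 0.05) {
  y <- cbind(as.numeric(session1), as.numeric(session2))
  if (any(!is.finite(y))) stop("scores must be finite and pairwise complete")
  n <- nrow(y); k <- ncol(y)
  if (n < 3L) stop("need at least 3 subjects, got ", n)
  grand <- mean(y)
  row_m <- rowMeans(y); col_m <- colMeans(y)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((y - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  if (ss_tot <= 0) stop("undefined ICC: zero total variance")
  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  if (mse <= 0 && msc <= msr) {
    # perfect agreement: sessions identical
    return(list(icc = 1, ci_low = 1, ci_high = 1,
                ms_rows = msr, ms_cols = msc, ms_error = mse))
  }
  # Shrout & Fleiss approximate CI for ICC(2,1)
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- stats::qf(1 - alpha / 2, df1 = n - 1, df2 = v)
  f_u <- stats::qf(1 - alpha / 2, df1 = v, df2 = n - 1)
  ci_low <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  ci_high <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  list(icc = icc, ci_low = ci_low, ci_high = ci_high,
       ms_rows = msr, ms_cols = msc, ms_error = mse)
}

#' Standard error of measurement
#'
#' `SEM = sd_pooled * sqrt(1 - icc)`: the within-subject measurement noise
#' scale implied by a reliability coefficient. A negative ICC is permitted
#' (the argument of the square root is then > 1).
#'
#' @param sd_pooled pooled between-subject SD (>= 0); for a two-session
#'   design, `sqrt((sd1^2 + sd2^2) / 2)`.
#' @param icc reliability coefficient (<= 1).
#' @return SEM, same units as `sd_pooled`.
#' @export
sem_measurement <- function(sd_pooled, icc) {
  stopifnot(sd_pooled >= 0, icc <= 1)
  sd_pooled * sqrt(1 - icc)
}

#' Standard error of the mean
#'
#' `sd / sqrt(n)`: the parenthetical precision figure printed next to group
#' means in stabilometric reliability tables. Distinct from the standard
#' error of measurement ([sem_measurement()]).
#'
#' @param sd standard deviation (>= 0).
#' @param n sample size (>= 1).
#' @return SE of the mean.
#' @export
se_of_mean <- function(sd, n) {
  stopifnot(sd >= 0, n >= 1)
  sd / sqrt(n)
}

#' Romberg quotient
#'
#' Per-subject ratio of a sway variable with eyes closed to the same
#' variable with eyes open, summarised as mean and SD across subjects
#' (mean-of-ratios). RQ > 1 indicates visual dependence of balance.
#'
#' @param eo_values per-subject values, eyes open (all > 0).
#' @param ec_values per-subject values, eyes closed (paired, same order).
#' @param variable,group optional labels stored on the result.
#' @return list with `variable`, `group`, `n`, `mean_rq`, `sd_rq` and the
#'   per-subject `ratios`.
#' @export
romberg_quotient <- function(eo_values, ec_values, variable = NA_character_,
                             group = NA_character_) {
  if (length(eo_values) != length(ec_values)) {
    stop("eyes-open and eyes-closed values must be paired")
  }
  bad <- which(eo_values <= 0)
  if (length(bad)) {
    stop("non-positive eyes-open value for subject(s) ",
         paste(bad, collapse = ", "))
  }
  ratios <- ec_values / eo_values
  list(variable = variable, group = group, n = length(ratios),
       mean_rq = mean(ratios),
       sd_rq = if (length(ratios) > 1L) stats::sd(ratios) else 0,
       ratios = ratios)
}

#' Test-retest reliability table from per-trial metrics
#'
#' For every variable x condition x group cell with at least 3 subjects
#' measured in both sessions: session means, SDs and SEs of the mean,
#' ICC(2,1) with its 95% CI, and the standard error of measurement from the
#' pooled SD. Subjects missing one session in a condition are excluded from
#' that condition's cells with a warning listing them.
#'
#' @param metrics data.frame as returned by row-binding [sway_metrics()]
#'   over trials: columns `subject_id`, `group`, `condition`, `session` and
#'   one column per variable.
#' @param variables variable columns to analyse; default the twelve sway
#'   variables present in `metrics`.
#' @param log_transform analyse `log(value)`; used for recovery tests
#'   against the synthetic generator, whose variance components live on the
#'   log scale. Default `FALSE` (raw values, as in reported tables).
#' @param alpha CI level is `1 - alpha`.
#' @return data.frame with one row per variable x condition x group:
#'   `variable, condition, group, n, mean1, sd1, se1, mean2, sd2, se2, icc,
#'   ci_low, ci_high, sem_measurement`.
#' @export
reliability_table <- function(metrics, variables = NULL, log_transform = FALSE,
                              alpha = 0.05) {
  stopifnot(is.data.frame(metrics),
            all(c("subject_id", "group", "condition", "session") %in% names(metrics)))
  if (is.null(variables)) {
    variables <- intersect(sway_variable_names(), names(metrics))
  }
  if (!length(variables)) stop("no variable columns found in metrics")
  rows <- list()
  excluded <- character(0)
  for (cond in unique(metrics$condition)) {
    mc <- metrics[metrics$condition == cond, , drop = FALSE]
    for (grp in unique(mc$group)) {
      mg <- mc[mc$group == grp, , drop = FALSE]
      s1 <- mg[mg$session == 1L, , drop = FALSE]
      s2 <- mg[mg$session == 2L, , drop = FALSE]
      common <- intersect(s1$subject_id, s2$subject_id)
      dropped <- setdiff(unique(mg$subject_id), common)
      if (length(dropped)) {
        excluded <- c(excluded, paste0(dropped, " (", cond, "/", grp, ")"))
      }
      if (length(common) < 3L) {
        stop("fewer than 3 complete subject pairs for condition ", cond,
             ", group ", grp)
      }
      s1 <- s1[match(common, s1$subject_id), , drop = FALSE]
      s2 <- s2[match(common, s2$subject_id), , drop = FALSE]
      n <- length(common)
      for (v in variables) {
        y1 <- s1[[v]]; y2 <- s2[[v]]
        if (log_transform) { y1 <- log(y1); y2 <- log(y2) }
        fit <- icc_2_1(y1, y2, alpha = alpha)
        sd1 <- stats::sd(y1); sd2 <- stats::sd(y2)
        rows[[length(rows) + 1L]] <- data.frame(
          variable = v, condition = cond, group = grp, n = n,
          mean1 = mean(y1), sd1 = sd1, se1 = se_of_mean(sd1, n),
          mean2 = mean(y2), sd2 = sd2, se2 = se_of_mean(sd2, n),
          icc = fit$icc, ci_low = fit$ci_low, ci_high = fit$ci_high,
          sem_measurement = sem_measurement(sqrt((sd1^2 + sd2^2) / 2), fit$icc),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(excluded)) {
    warning("excluded subjects missing a session: ",
            paste(excluded, collapse = "; "))
  }
  do.call(rbind, rows)
}

#' Romberg quotients for a cohort
#'
#' Per-subject eyes-closed / eyes-open ratios of selected variables,
#' by group. Pairs the firm-surface conditions (FO as eyes open, FC as
#' eyes closed) by default; set `pair = c("CO", "CC")` for the compliant
#' surface.
#'
#' @param metrics per-trial metrics data.frame (see [reliability_table()]).
#' @param variables variables to form quotients of; default total path
#'   length and PCA sway area.
#' @param pair length-2 character, (eyes-open condition, eyes-closed
#'   condition).
#' @param session which session's trials to use (default 1).
#' @return data.frame with `variable, group, n, mean_rq, sd_rq`.
#' @export
romberg_table <- function(metrics, variables = c("path_total_cm", "area_pca_cm2"),
                          pair = c("FO", "FC"), session = 1L) {
  rows <- list()
  m <- metrics[metrics$session == session, , drop = FALSE]
  for (grp in unique(m$group)) {
    eo <- m[m$group == grp & m$condition == pair[1L], , drop = FALSE]
    ec <- m[m$group == grp & m$condition == pair[2L], , drop = FALSE]
    common <- intersect(eo$subject_id, ec$subject_id)
    if (length(common) < 2L) next
    eo <- eo[match(common, eo$subject_id), , drop = FALSE]
    ec <- ec[match(common, ec$subject_id), , drop = FALSE]
    for (v in variables) {
      rq <- romberg_quotient(eo[[v]], ec[[v]], variable = v, group = grp)
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, group = grp, n = rq$n, mean_rq = rq$mean_rq,
        sd_rq = rq$sd_rq, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
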