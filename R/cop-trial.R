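#' Centre-of-pressure trial
#'
#' Container for one stabilogram: the medio-lateral (ML) and antero-posterior
#' (AP) coordinates of the centre of pressure sampled at a fixed rate, plus
#' the metadata the reliability analysis needs (subject, group, sensory
#' condition, session). The canonical acquisition is 60 s at 50 Hz, stored
#' under the half-open time convention as N = 3000 samples at
#' t = 0, 0.02, ..., 59.98 s, so that N = rate x duration exactly.
#'
#' @param ml_cm numeric vector, medio-lateral CoP position in cm.
#' @param ap_cm numeric vector, antero-posterior CoP position in cm, same
#'   length as `ml_cm`.
#' @param subject_id subject label (coerced to character).
#' @param group group label, one of `"young"` or `"elderly"`.
#' @param condition sensory condition: `"FO"` (firm surface, eyes open),
#'   `"FC"` (firm, eyes closed), `"CO"` (compliant, eyes open) or `"CC"`
#'   (compliant, eyes closed).
#' @param session session number, 1 or 2.
#' @param sampling_rate_hz sampling rate in Hz (positive; nominal 50).
#' @return An object of class `cop_trial`.
#' @examples
#' tr <- cop_trial(sin(seq(0, 2 * pi, length.out = 100)) * 0.4,
#'                 cos(seq(0, 2 * pi, length.out = 100)) * 0.5,
#'                 subject_id = "S1", group = "young",
#'                 condition = "FO", session = 1, sampling_rate_hz = 50)
#' trial_duration(tr)
#' @export
cop_trial <- function(ml_cm, ap_cm, subject_id = "anon", group = c("young", "elderly"),
                      condition = c("FO", "FC", "CO", "CC"), session = 1L,
                      sampling_rate_hz = 50) {
  ml_cm <- as.numeric(ml_cm)
  ap_cm <- as.numeric(ap_cm)
  if (length(ml_cm) != length(ap_cm)) {
    stop("ml_cm and ap_cm must have the same length (got ",
         length(ml_cm), " and ", length(ap_cm), ")")
  }
  if (length(ml_cm) < 2L) {
    stop("empty trial: a CoP trial needs at least 2 samples, got ", length(ml_cm))
  }
  if (!all(is.finite(ml_cm)) || !all(is.finite(ap_cm))) {
    stop("non-finite CoP samples present")
  }
  if (!is.numeric(sampling_rate_hz) || length(sampling_rate_hz) != 1L ||
      !is.finite(sampling_rate_hz) || sampling_rate_hz <= 0) {
    stop("sampling_rate_hz must be a positive number")
  }
  group <- match.arg(group)
  condition <- match.arg(condition)
  session <- as.integer(session)
  if (!session %in% c(1L, 2L)) stop("session must be 1 or 2")
  structure(
    list(ml_cm = ml_cm, ap_cm = ap_cm,
         subject_id = as.character(subject_id), group = group,
         condition = condition, session = session,
         sampling_rate_hz = as.numeric(sampling_rate_hz)),
    class = "cop_trial")
}

#' @export
print.cop_trial <- function(x, ...) {
  cat(sprintf("CoP trial: subject %s (%s), condition %s, session %d\n",
              x$subject_id, x$group, x$condition, x$session))
  cat(sprintf("  %d samples @ %g Hz (%.2f s), ML sd %.3f cm, AP sd %.3f cm\n",
              length(x$ml_cm), x$sampling_rate_hz, trial_duration(x),
              stats::sd(x$ml_cm), stats::sd(x$ap_cm)))
  invisible(x)
}

#' Trial duration in seconds
#'
#' Duration under the half-open convention, `N / sampling_rate`: a standard
#' 3000-sample, 50-Hz trial covers exactly 60 s.
#'
#' @param trial a [cop_trial].
#' @return duration in seconds.
#' @export
trial_duration <- function(trial) {
  stopifnot(inherits(trial, "cop_trial"))
  length(trial$ml_cm) / trial$sampling_rate_hz
}

#' Read a CoP trial from delimited text
#'
#' Accepts comma- or tab-delimited text (autodetected) with two numeric
#' columns (ML, AP in cm) or three (time in s, ML, AP). When a time column
#' is present, the sampling rate is inferred from the median time step and
#' the steps are checked for uniformity; otherwise `sampling_rate_hz` is
#' used. An optional header line is skipped automatically.
#'
#' @param path file to read.
#' @param subject_id,group,condition,session trial metadata, passed to
#'   [cop_trial()].
#' @param sampling_rate_hz fallback sampling rate when the file has no time
#'   column.
#' @param dt_tolerance maximal relative deviation of any time step from the
#'   median step before the file is rejected as non-uniformly sampled.
#' @param trim_leading_s seconds to drop from the start of the recording
#'   (settling period); default 0, i.e. files are assumed already trimmed.
#' @return a [cop_trial].
#' @seealso [write_cop_trial()]
#' @export
read_cop_trial <- function(path, subject_id = "anon", group = "young",
                           condition = "FO", session = 1L,
                           sampling_rate_hz = 50, dt_tolerance = 0.01,
                           trim_leading_s = 0) {
  if (!file.exists(path)) stop("trial file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty trial file: ", path)
  sep <- if (grepl("\t", lines[[1]])) "\t" else ","
  first_data <- 1L
  fields1 <- strsplit(lines[[1]], sep, fixed = TRUE)[[1]]
  if (any(is.na(suppressWarnings(as.numeric(fields1))))) first_data <- 2L
  if (length(lines) < first_data) stop("empty trial file: ", path)
  rows <- strsplit(lines[first_data:length(lines)], sep, fixed = TRUE)
  ncol <- length(rows[[1]])
  if (ncol < 2L) stop("need at least 2 numeric columns, found ", ncol, " in ", path)
  mat <- matrix(NA_real_, nrow = length(rows), ncol = ncol)
  for (i in seq_along(rows)) {
    v <- suppressWarnings(as.numeric(rows[[i]]))
    if (length(v) != ncol || any(is.na(v))) {
      stop("parse error in ", path, " at line ", i + first_data - 1L,
           ": non-numeric or ragged row")
    }
    mat[i, ] <- v
  }
  if (ncol >= 3L) {
    tm <- mat[, 1L]
    dts <- diff(tm)
    dt <- stats::median(dts)
    if (dt <= 0) stop("sampling error in ", path, ": non-increasing time column")
    if (any(abs(dts - dt) > dt_tolerance * dt)) {
      stop("sampling error in ", path, ": non-uniform time steps beyond tolerance")
    }
    rate <- 1 / dt
    ml <- mat[, 2L]; ap <- mat[, 3L]
  } else {
    rate <- sampling_rate_hz
    ml <- mat[, 1L]; ap <- mat[, 2L]
  }
  if (trim_leading_s > 0) {
    drop <- round(trim_leading_s * rate)
    if (drop >= length(ml) - 1L) stop("leading trim removes the whole trial")
    if (drop > 0) { ml <- ml[-seq_len(drop)]; ap <- ap[-seq_len(drop)] }
  }
  cop_trial(ml, ap, subject_id = subject_id, group = group,
            condition = condition, session = session, sampling_rate_hz = rate)
}

#' Write a CoP trial to delimited text
#'
#' Writes a comma-separated file with header `time,ml_cm,ap_cm`; time runs
#' 0, 1/rate, 2/rate, ... Values are printed to 12 significant digits so a
#' write/read round trip preserves the series to better than 1e-9.
#'
#' @param trial a [cop_trial].
#' @param path destination file.
#' @return invisibly, `path`.
#' @export
write_cop_trial <- function(trial, path) {
  stopifnot(inherits(trial, "cop_trial"))
  n <- length(trial$ml_cm)
  tm <- (seq_len(n) - 1L) / trial$sampling_rate_hz
  lines <- c("time,ml_cm,ap_cm",
             paste(format(tm, digits = 12, trim = TRUE, scientific = FALSE),
                   format(trial$ml_cm, digits = 12, trim = TRUE),
                   format(trial$ap_cm, digits = 12, trim = TRUE), sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Validate a trial against the expected acquisition convention
#'
#' Non-throwing checks; findings are returned as a character vector, empty
#' when the trial matches the expected sampling rate and duration within
#' `tolerance` (relative) and all samples are finite.
#'
#' @param trial a [cop_trial].
#' @param expected_rate_hz expected sampling rate (default 50 Hz).
#' @param expected_duration_s expected duration (default 60 s).
#' @param tolerance relative tolerance on rate and duration.
#' @return character vector of findings (possibly empty).
#' @export
validate_cop_trial <- function(trial, expected_rate_hz = 50,
                               expected_duration_s = 60, tolerance = 0.01) {
  stopifnot(inherits(trial, "cop_trial"))
  findings <- character()
  if (abs(trial$sampling_rate_hz - expected_rate_hz) > tolerance * expected_rate_hz) {
    findings <- c(findings, sprintf(
      "sampling rate %g Hz differs from expected %g Hz",
      trial$sampling_rate_hz, expected_rate_hz))
  }
  dur <- trial_duration(trial)
  if (abs(dur - expected_duration_s) > tolerance * expected_duration_s) {
    findings <- c(findings, sprintf(
      "duration %.3f s differs from expected %g s", dur, expected_duration_s))
  }
  # cop_trial() enforces finiteness at construction, but trials built by
  # other code paths are still checked here
  if (!all(is.finite(trial$ml_cm)) || !all(is.finite(trial$ap_cm))) {
    findings <- c(findings, "non-finite samples present")
  }
  findings
}

#' Collect trials into a validated set
#'
#' @param trials list of [cop_trial] objects.
#' @param provenance free-text description of where the trials came from.
#' @return object of class `trial_set` (a list with elements `trials`,
#'   `provenance`).
#' @export
trial_set <- function(trials, provenance = "") {
  stopifnot(is.list(trials), all(vapply(trials, inherits, TRUE, "cop_trial")))
  key <- vapply(trials, function(tr)
    paste(tr$subject_id, tr$condition, tr$session, sep = "|"), "")
  if (anyDuplicated(key)) {
    stop("duplicate (subject, condition, session) combinations: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  structure(list(trials = trials, provenance = provenance), class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf("Trial set: %d trials (%s)\n", length(x$trials), x$provenance))
  invisible(x)
}

#' @export
length.trial_set <- function(x) length(x$trials)

#' Read a manifest of trial files
#'
#' The manifest is a CSV with columns `path, subject, group, condition,
#' session`; paths are resolved relative to the manifest's directory unless
#' absolute. Unreadable trial files are skipped with a warning naming the
#' file, so one bad recording does not abort a batch.
#'
#' @param path manifest CSV.
#' @param sampling_rate_hz fallback rate for files without a time column.
#' @return a [trial_set].
#' @export
read_manifest <- function(path, sampling_rate_hz = 50) {
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("path", "subject", "group", "condition", "session")
  if (!all(need %in% names(man))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  }
  base <- dirname(normalizePath(path))
  trials <- list()
  for (i in seq_len(nrow(man))) {
    p <- man$path[i]
    if (!file.exists(p)) p <- file.path(base, man$path[i])
    tr <- tryCatch(
      read_cop_trial(p, subject_id = man$subject[i], group = man$group[i],
                     condition = man$condition[i], session = man$session[i],
                     sampling_rate_hz = sampling_rate_hz),
      error = function(e) {
        warning("skipping trial ", man$path[i], ": ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
    if (!is.null(tr)) trials[[length(trials) + 1L]] <- tr
  }
  trial_set(trials, provenance = paste0("manifest: ", path))
}
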