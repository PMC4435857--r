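# Fixtures built in code: small trials and the published group summaries
# used as arithmetic inputs for identity checks.

make_trial <- function(ml, ap, rate = 50, ...) {
  cop_trial(ml, ap, sampling_rate_hz = rate, ...)
}

# Random correlated-walkish trial (bounded), for round-trip and property
# tests; nothing about its dynamics matters.
random_trial <- function(n = 200, rate = 50, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  make_trial(cumsum(rnorm(n, sd = 0.02)), cumsum(rnorm(n, sd = 0.02)),
             rate = rate, ...)
}

ou_trial <- function(n = 3000, rate = 50, theta = 2, scale = 0.5,
                     seed = NULL, ...) {
  cfg <- synthetic_config(ou_theta = theta, sampling_rate_hz = rate,
                          duration_s = n / rate)
  generate_trial(scale, scale, cfg, seed = seed, ...)
}

# Published mSIT group summaries (firm/compliant x eyes open/closed, two
# groups, two sessions), used as *inputs*: mean total path with its printed
# mean velocity, and SD/n pairs with their printed SE-of-the-mean.
ref_velocity_rows <- data.frame(
  condition = c("FO", "FO", "FC", "CO"),
  group = c("young", "elderly", "young", "young"),
  path_total_cm = c(77.52, 111.60, 115.68, 144.63),
  printed_velocity = c(1.29, 1.86, 1.93, 2.41))

ref_se_rows <- data.frame(
  sd = c(0.1, 0.13, 0.16, 0.18, 8.78, 10.22, 9.28, 12.85, 15.03, 1.19,
         0.08, 17.55, 21.69, 15.67, 21.33, 26.43, 0.36, 2.04),
  n = c(rep(26, 10), rep(15, 8)),
  printed_se = c(0.02, 0.03, 0.03, 0.04, 1.72, 2.00, 1.82, 2.52, 2.95, 0.23,
                 0.02, 4.53, 5.60, 4.05, 5.51, 6.82, 0.09, 0.53))

# Printed group means of ML variability, AP variability and PCA sway area,
# per condition x group x session (4 tables x 2 groups x 2 sessions).
ref_pca_rows <- data.frame(
  condition = rep(c("FO", "FC", "CO", "CC"), each = 4),
  group = rep(rep(c("young", "elderly"), each = 2), 4),
  session = rep(1:2, 8),
  sd_ml = c(0.44, 0.47, 0.57, 0.56,
            0.53, 0.55, 0.62, 0.64,
            0.65, 0.65, 0.92, 0.89,
            1.18, 1.16, 1.51, 1.46),
  sd_ap = c(0.51, 0.49, 0.62, 0.61,
            0.56, 0.51, 0.62, 0.66,
            0.78, 0.81, 0.97, 1.00,
            1.33, 1.21, 1.54, 1.49),
  area_pca = c(2.61, 2.81, 4.11, 4.09,
               3.68, 3.46, 4.72, 5.19,
               6.24, 6.26, 10.76, 10.75,
               19.14, 17.17, 28.03, 26.32))
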