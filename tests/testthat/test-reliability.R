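test_that("ICC(2,1) matches brute-force ANOVA mean squares", {
  set.seed(71)
  for (i in 1:20) {
    n <- sample(4:12, 1)
    y1 <- rnorm(n, sd = 2) + rnorm(n)
    y2 <- y1 + rnorm(n) + 0.3
    fit <- icc_2_1(y1, y2)
    expect_equal(fit$icc, icc21_aov(y1, y2), tolerance = 1e-10)
    expect_lte(fit$ci_low, fit$icc)
    expect_gte(fit$ci_high, fit$icc)
  }
})

test_that("ICC edge cases: perfect agreement, too few subjects, no variance", {
  y <- c(3, 5, 9, 2, 7)
  fit <- icc_2_1(y, y)
  expect_equal(fit$icc, 1)
  expect_equal(fit$ci_high, 1)
  expect_error(icc_2_1(c(1, 2), c(1, 2)), "at least 3")
  expect_error(icc_2_1(rep(2, 5), rep(2, 5)), "zero total variance")
})

test_that("ICC is invariant to common affine rescaling", {
  set.seed(72)
  y1 <- rnorm(10); y2 <- y1 + rnorm(10, sd = 0.5)
  f0 <- icc_2_1(y1, y2)
  f1 <- icc_2_1(-2.5 * y1 + 4, -2.5 * y2 + 4)
  expect_equal(f1$icc, f0$icc, tolerance = 1e-12)
  expect_equal(f1$ci_low, f0$ci_low, tolerance = 1e-10)
})

test_that("raising between-subject spread never lowers the ICC", {
  set.seed(73)
  u <- rnorm(30); e1 <- rnorm(30); e2 <- rnorm(30)
  iccs <- vapply(c(0.5, 1, 2, 4, 8), function(su) {
    icc_2_1(su * u + e1, su * u + e2)$icc
  }, 0)
  expect_true(all(diff(iccs) > 0))
})

test_that("ICC estimate and CI coverage behave under a known truth", {
  # sigma_u^2 / (sigma_u^2 + sigma_e^2) = 0.8, n = 30
  set.seed(74)
  reps <- 300
  est <- numeric(reps); cover <- logical(reps)
  for (r in seq_len(reps)) {
    u <- rnorm(30, sd = 2)
    f <- icc_2_1(u + rnorm(30), u + rnorm(30))
    est[r] <- f$icc
    cover[r] <- f$ci_low <= 0.8 && 0.8 <= f$ci_high
  }
  expect_lt(abs(mean(est) - 0.8), 0.05)
  expect_gt(mean(cover), 0.9)
})

test_that("SEM and SE-of-mean arithmetic", {
  expect_equal(sem_measurement(4, 1), 0)
  expect_equal(sem_measurement(4, 0), 4)
  expect_equal(sem_measurement(10, 0.75), 5)
  expect_equal(sem_measurement(1, -0.5), sqrt(1.5))  # negative ICC allowed
  expect_equal(se_of_mean(0.1, 26), 0.1 / sqrt(26))
  expect_equal(se_of_mean(0, 10), 0)
})

test_that("Romberg quotient is the mean and SD of per-subject ratios", {
  eq <- romberg_quotient(c(2, 3, 4), c(2, 3, 4))
  expect_equal(eq$mean_rq, 1)
  expect_equal(eq$sd_rq, 0)

  rq <- romberg_quotient(c(100, 50), c(150, 100))
  expect_equal(rq$mean_rq, 1.75)
  expect_equal(rq$sd_rq, sd(c(1.5, 2)))

  expect_error(romberg_quotient(c(1, 0), c(2, 2)), "subject")

  set.seed(75)
  eo <- exp(rnorm(200, sd = 0.3))
  ec <- eo * 1.5 * exp(rnorm(200, sd = 0.1) - 0.1^2 / 2)
  mc <- romberg_quotient(eo, ec)
  expect_lt(abs(mc$mean_rq - 1.5), 3 * mc$sd_rq / sqrt(200))
})

test_that("reliability_table recovers a designed ICC from score data", {
  set.seed(76)
  n <- 50
  make_scores <- function(u, v1, v2) {
    rows <- list()
    for (s in 1:2) {
      v <- if (s == 1) v1 else v2
      rows[[s]] <- data.frame(
        subject_id = sprintf("S%02d", 1:n), group = "young",
        condition = "FO", session = s,
        sd_ml_cm = exp(u + v), path_total_cm = 60 * exp(u + v))
    }
    do.call(rbind, rows)
  }
  # designed ICC 0.9: sigma_u = 0.3, sigma_v = 0.1
  m <- make_scores(rnorm(n, sd = 0.3), rnorm(n, sd = 0.1), rnorm(n, sd = 0.1))
  rel <- reliability_table(m, variables = c("sd_ml_cm", "path_total_cm"),
                           log_transform = TRUE)
  expect_equal(nrow(rel), 2)
  expect_lt(abs(rel$icc[rel$variable == "sd_ml_cm"] - 0.9), 0.1)
  expect_equal(rel$se1, rel$sd1 / sqrt(rel$n), tolerance = 1e-12)

  # duplicated sessions: all ICC 1
  dup <- m
  dup$session[dup$session == 2] <- 2L
  dup[dup$session == 2, c("sd_ml_cm", "path_total_cm")] <-
    dup[dup$session == 1, c("sd_ml_cm", "path_total_cm")]
  rel_dup <- reliability_table(dup, variables = c("sd_ml_cm", "path_total_cm"))
  expect_true(all(rel_dup$icc == 1))

  # two subjects only: refuse
  expect_error(reliability_table(m[m$subject_id %in% c("S01", "S02"), ],
                                 variables = "sd_ml_cm"), "fewer than 3")

  # subject missing session 2 is excluded with a warning
  miss <- m[!(m$subject_id == "S01" & m$session == 2), ]
  expect_warning(rel_miss <- reliability_table(miss, variables = "sd_ml_cm"),
                 "S01")
  expect_equal(rel_miss$n, n - 1)
})
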