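test_that("fGn generator: white-noise limit, unit variance, determinism", {
  x <- generate_fgn(5000, 0.5, seed = 81)
  expect_lt(abs(cor(x[-1], x[-5000])), 3 / sqrt(5000))  # lag-1 autocorr ~ 0
  expect_lt(abs(var(x) - 1), 0.1)
  expect_identical(generate_fgn(1000, 0.8, seed = 82),
                   generate_fgn(1000, 0.8, seed = 82))
  expect_error(generate_fgn(100, 1.2), "hurst")

  # persistent fGn has positive lag-1 autocorrelation 2^(2H-1) - 1
  y <- generate_fgn(5000, 0.8, seed = 83)
  expect_equal(cor(y[-1], y[-5000]), 2^(2 * 0.8 - 1) - 1, tolerance = 0.05)
})

test_that("generated trials hit the requested positional SD in expectation", {
  cfg <- synthetic_config()
  one <- generate_trial(0.44, 0.51, cfg, seed = 84)
  expect_lt(abs(sd(one$ml_cm) / 0.44 - 1), 0.2)

  sds <- vapply(1:100, function(s)
    sd(generate_trial(0.44, 0.51, cfg, seed = 1000 + s)$ml_cm), 0)
  expect_lt(abs(mean(sds) / 0.44 - 1), 0.02)

  flat <- generate_trial(0, 0, cfg, seed = 85)
  expect_equal(sd(flat$ml_cm), 0)
  expect_equal(sd(flat$ap_cm), 0)
})

test_that("stiffer OU dynamics raise velocity at fixed sway SD", {
  vels <- vapply(c(0.5, 2, 8), function(th) {
    cfg <- synthetic_config(ou_theta = th)
    mean(vapply(1:5, function(s)
      mean_velocity(generate_trial(0.5, 0.5, cfg, seed = 100 + s)), 0))
  }, 0)
  expect_true(all(diff(vels) > 0))
})

test_that("fgn-model traces carry the designed fractal dimension", {
  cfg <- synthetic_config(trace_model = "fgn", hurst = 0.8)
  tr <- generate_trial(0.5, 0.5, cfg, seed = 86)
  expect_equal(fit_fd(higuchi_lengths(tr$ml_cm, 50), c(0, 0.3))$fd,
               2 - 0.8, tolerance = 0.1)
  # per-trial SD is exact for the sample-standardized fgn trace
  expect_equal(sd(tr$ml_cm), 0.5, tolerance = 1e-12)
})

test_that("cohort generation is deterministic and correctly sized", {
  cfg <- synthetic_config(seed = 87)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$truth, b$truth)
  expect_identical(a$trials$trials[[50]]$ml_cm, b$trials$trials[[50]]$ml_cm)
  expect_length(a$trials, (26 + 15) * 4 * 2)
  expect_equal(nrow(a$truth), 328)
  expect_equal(attr(a$truth, "designed_icc"), cfg$designed_icc)
})

test_that("zero session variance makes the two sessions' scales identical", {
  cfg <- synthetic_config(n_subjects = c(young = 10L),
                          condition_mult = c(FO = 1),
                          sigma_session = 0, seed = 88)
  co <- generate_cohort(cfg)
  tr1 <- co$truth[co$truth$session == 1, ]
  tr2 <- co$truth[co$truth$session == 2, ]
  expect_equal(tr1$scale_ml[order(tr1$subject_id)],
               tr2$scale_ml[order(tr2$subject_id)])
  sds <- vapply(co$trials$trials, function(t) sd(t$ml_cm), 0)
  meta <- co$truth
  y1 <- log(sds[meta$session == 1][order(meta$subject_id[meta$session == 1])])
  y2 <- log(sds[meta$session == 2][order(meta$subject_id[meta$session == 2])])
  expect_gt(icc_2_1(y1, y2)$icc, 0.85)  # only within-trial noise remains
})

test_that("designed ICC is recovered on average across the design grid", {
  designs <- c(0.4, 0.6, 0.8, 0.95)
  reps <- 200
  su <- 0.5
  for (d in designs) {
    sv <- su * sqrt(1 / d - 1)
    est <- numeric(reps)
    for (r in seq_len(reps)) {
      cfg <- synthetic_config(n_subjects = c(young = 26L),
                              condition_mult = c(FO = 1),
                              sigma_subject = su, sigma_session = sv,
                              seed = 10000 + round(1000 * d) + r)
      co <- generate_cohort(cfg)
      sds <- vapply(co$trials$trials, function(t) sd(t$ml_cm), 0)
      s1 <- co$truth$session == 1
      ord1 <- order(co$truth$subject_id[s1])
      ord2 <- order(co$truth$subject_id[!s1])
      est[r] <- icc_2_1(log(sds[s1][ord1]), log(sds[!s1][ord2]))$icc
    }
    expect_lt(abs(mean(est) - d), 0.05)
  }
})

test_that("condition multipliers order the mean path lengths", {
  cfg <- synthetic_config(n_subjects = c(young = 8L), seed = 89)
  co <- generate_cohort(cfg)
  paths <- vapply(co$trials$trials,
                  function(t) path_lengths(t)[["path_total_cm"]], 0)
  cond <- co$truth$condition
  means <- tapply(paths, cond, mean)[c("FO", "FC", "CO", "CC")]
  expect_true(all(diff(means) > 0))
})
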