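test_that("PCA ellipse recovers known covariance structure", {
  # exact sample moments: centroid 0, cov diag(4, 1)
  x <- sqrt(8); y <- sqrt(2)
  tr <- make_trial(c(x, -x, 0, 0, 0), c(0, 0, y, -y, 0))
  ell <- fit_pca_ellipse(tr)
  expect_equal(ell$area_cm2, pi * 1.96^2 * 2 * 1, tolerance = 1e-9)
  expect_equal(ell$s0_major_cm, 2, tolerance = 1e-9)
  expect_equal(ell$orientation_rad %% pi, 0, tolerance = 1e-9)

  set.seed(21)
  cloud <- make_trial(rnorm(1e5), rnorm(1e5))
  expect_lt(abs(fit_pca_ellipse(cloud)$area_cm2 / (pi * 1.96^2) - 1), 0.01)

  line <- make_trial(1:10, 2 * (1:10))
  expect_equal(fit_pca_ellipse(line)$area_cm2, 0)

  expect_warning(z <- fit_pca_ellipse(make_trial(rep(1, 5), rep(1, 5))),
                 "identical")
  expect_equal(z$area_cm2, 0)
})

test_that("extreme points pick the farthest sample per angular bin", {
  th <- seq(0, 2 * pi, length.out = 401)[-401]
  circ <- make_trial(2 * cos(th), 2 * sin(th))
  pts <- extreme_points(circ, n_intervals = 100, center = c(0, 0))
  expect_equal(pts$radius_cm, rep(2, nrow(pts)))

  quad <- make_trial(c(1, -2, -1, 3), c(1, 2, -1, -4))
  pq <- extreme_points(quad, n_intervals = 8, center = c(0, 0))
  expect_equal(nrow(pq), 4)  # one occupied bin per point
  expect_equal(sort(pq$radius_cm),
               sort(sqrt(c(2, 8, 2, 25))), tolerance = 1e-12)

  set.seed(31)
  ml <- rnorm(500); ap <- rnorm(500)
  ctr <- c(mean(ml), mean(ap))
  got <- extreme_points(make_trial(ml, ap), n_intervals = 37, center = ctr)
  want <- extreme_points_brute(ml, ap, 37, ctr)
  expect_equal(got$bin, unname(want[, "bin"]))
  expect_equal(got$radius_cm, unname(want[, "radius"]), tolerance = 1e-12)

  expect_error(extreme_points(make_trial(c(1, 1.1), c(0, 0)), 100, c(0, 0)),
               "degenerate")
})

test_that("Fourier outline fit recovers exact basis shapes", {
  phi <- seq(0, 2 * pi, length.out = 101)[-101]
  circ <- fit_outline(cbind(phi, rep(3, 100)), m_max = 20)
  expect_equal(circ$coeff_a[1], 3, tolerance = 1e-9)
  expect_lt(max(abs(c(circ$coeff_a[-1], circ$coeff_b))), 1e-9)
  expect_equal(circ$area_cm2, 9 * pi, tolerance = 1e-8)

  lobed <- fit_outline(cbind(phi, 2 + cos(phi)), m_max = 20)
  expect_equal(lobed$coeff_a[1], 2, tolerance = 1e-9)
  expect_equal(lobed$coeff_a[2], 1, tolerance = 1e-9)
  expect_lt(max(abs(c(lobed$coeff_a[-(1:2)], lobed$coeff_b))), 1e-9)

  # true ellipse boundary, semi-axes 2 and 1
  r_ell <- function(p) 2 * 1 / sqrt((1 * cos(p))^2 + (2 * sin(p))^2)
  fit <- fit_outline(cbind(phi, r_ell(phi)), m_max = 20)
  test_phi <- seq(0, 2 * pi, length.out = 1000)
  rel_err <- abs(outline_radius(fit, test_phi) - r_ell(test_phi)) / r_ell(test_phi)
  expect_lt(max(rel_err), 0.005)

  expect_error(fit_outline(cbind(phi[1:30], rep(1, 30)), m_max = 20),
               "lower m_max")
})

test_that("outline area equals quadrature and rejects negative radii", {
  set.seed(41)
  for (i in 1:10) {
    a <- c(5, rnorm(20, sd = 0.1))  # dominant A0 keeps r > 0
    b <- rnorm(20, sd = 0.1)
    out <- structure(list(coeff_a = a, coeff_b = b, m_max = 20),
                     class = "outline_model")
    expect_equal(outline_area(out), outline_area_quadrature(out),
                 tolerance = 1e-8)
  }

  zero <- structure(list(coeff_a = rep(0, 21), coeff_b = rep(0, 20),
                         m_max = 20), class = "outline_model")
  expect_equal(outline_area(zero), 0)

  dipped <- structure(list(coeff_a = c(0.5, 1, rep(0, 19)),
                           coeff_b = rep(0, 20), m_max = 20),
                      class = "outline_model")
  expect_error(outline_area(dipped), "negative.*angle")
})

test_that("sway areas are translation/rotation invariant and scale as c^2", {
  tr <- ou_trial(n = 2000, seed = 51)
  base_fao <- fao_area(tr)$area_cm2
  base_pca <- fit_pca_ellipse(tr)$area_cm2

  shifted <- make_trial(tr$ml_cm + 3.7, tr$ap_cm - 1.2)
  expect_equal(fao_area(shifted)$area_cm2, base_fao, tolerance = 1e-9)
  expect_equal(fit_pca_ellipse(shifted)$area_cm2, base_pca, tolerance = 1e-9)

  # rigid rotation: PCA exactly; FAO when the rotation is a whole number of
  # angular bins (so the same extreme samples are selected)
  for (rot in c(0.7, 2 * pi * 13 / 100)) {
    ml <- cos(rot) * tr$ml_cm - sin(rot) * tr$ap_cm
    ap <- sin(rot) * tr$ml_cm + cos(rot) * tr$ap_cm
    expect_equal(fit_pca_ellipse(make_trial(ml, ap))$area_cm2, base_pca,
                 tolerance = 1e-9)
  }
  rot <- 2 * pi * 13 / 100
  ml <- cos(rot) * tr$ml_cm - sin(rot) * tr$ap_cm
  ap <- sin(rot) * tr$ml_cm + cos(rot) * tr$ap_cm
  expect_equal(fao_area(make_trial(ml, ap))$area_cm2, base_fao,
               tolerance = 1e-9)

  scaled <- make_trial(2.5 * tr$ml_cm, 2.5 * tr$ap_cm)
  expect_equal(fao_area(scaled)$area_cm2, 2.5^2 * base_fao, tolerance = 1e-9)
  expect_equal(fit_pca_ellipse(scaled)$area_cm2, 2.5^2 * base_pca,
               tolerance = 1e-9)
})

test_that("per-trial PCA area never exceeds the axis-SD bound", {
  for (seed in 1:20) {
    tr <- random_trial(n = 300, seed = seed)
    pv <- positional_variability(tr)
    expect_lte(fit_pca_ellipse(tr)$area_cm2,
               pi * 1.96^2 * pv[["sd_ml_cm"]] * pv[["sd_ap_cm"]] + 1e-12)
  }
})
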