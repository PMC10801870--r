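# Cell-type presets and quenched threshold disorder.

test_that("presets carry the published cell-type constants", {
  rs <- izh_params("rs")
  expect_equal(rs$C, 100)
  expect_equal(rs$k, 0.7)
  expect_equal(rs$vr, -60)
  expect_equal(rs$vtheta_bar, -40)
  expect_equal(rs$g, 1)
  expect_equal(rs$E, 0)
  expect_equal(rs$tau_u, 33.33, tolerance = 1e-3)
  expect_equal(rs$tau_s, 6)
  expect_equal(rs$kappa, 10)
  expect_equal(rs$b, -2)
  expect_equal(rs$J, 15)
  expect_equal(rs$delta_v, 0.5)

  fs <- izh_params("fs")
  expect_equal(fs$C, 20)
  expect_equal(fs$vr, -55)
  expect_equal(fs$E, -65)
  expect_equal(fs$kappa, 0)
  expect_equal(fs$b, 0.025)
  expect_equal(fs$J, 5)

  lts <- izh_params("lts")
  expect_equal(lts$C, 100)
  expect_equal(lts$vr, -56)
  expect_equal(lts$vtheta_bar, -42)
  expect_equal(lts$b, 8)
  expect_equal(lts$kappa, 20)

  rs_adapt <- izh_params("rs", kappa = 100)
  expect_equal(rs_adapt$kappa, 100)
  expect_equal(rs_adapt$J, rs$J)
  expect_error(izh_params("chattering"))

  for (p in list(rs, fs, lts)) {
    expect_gt(p$C, 0)
    expect_gt(p$k, 0)
    expect_gt(p$tau_u, 0)
    expect_gt(p$tau_s, 0)
    expect_gt(p$vtheta_bar, p$vr)
  }
})

test_that("default truncation is symmetric about the center with lower bound at rest", {
  expect_equal(unname(default_truncation(rs_params)), c(-60, -20))
  expect_equal(unname(default_truncation(fs_params)), c(-55, -25))
  tr <- default_truncation(rs_params, margin = 2)
  expect_equal(unname(tr), c(-58, -22))
  degenerate <- rs_params
  degenerate$vtheta_bar <- degenerate$vr
  expect_error(default_truncation(degenerate), "resting")
})

test_that("Gaussian width conversion matches the Lorentzian interquartile range", {
  expect_equal(gaussian_equivalent_width(0), 0)
  expect_equal(gaussian_equivalent_width(qnorm(0.75)), 1)
  expect_equal(gaussian_equivalent_width(1), 1 / qnorm(0.75), tolerance = 1e-12)
  # IQR matching realized in samples
  n <- 1e5
  dl <- disorder_spec("lorentzian", -40, 1, -80, 0, seed = 3)
  dg <- disorder_spec("gaussian", -40, gaussian_equivalent_width(1), -80, 0,
                      seed = 3)
  expect_equal(unname(diff(quantile(sample_thresholds(dl, n), c(.25, .75)))),
               unname(diff(quantile(sample_thresholds(dg, n), c(.25, .75)))),
               tolerance = 0.03)
})

test_that("threshold sampling is reproducible, bounded, and zero-width degenerates", {
  spec <- disorder_for(rs_params, seed = 11)
  x1 <- sample_thresholds(spec, 1000)
  x2 <- sample_thresholds(spec, 1000)
  expect_identical(x1, x2)
  expect_true(all(x1 > spec$truncation_low & x1 < spec$truncation_high))

  z <- sample_thresholds(disorder_spec("lorentzian", -40, 0, -60, -20), 5)
  expect_equal(z, rep(-40, 5))
  zg <- sample_thresholds(disorder_spec("gaussian", -40, 0, -60, -20), 4)
  expect_equal(zg, rep(-40, 4))

  expect_error(disorder_spec("lorentzian", -40, 0.5, -41, -20), "symmetric")
  expect_error(disorder_spec("lorentzian", -40, 0.5, -39, -20), "bracket")
})

test_that("truncated Lorentzian sampler matches analytic CDF, median, and IQR", {
  spec <- disorder_spec("lorentzian", -40, 0.5, -60, -20, seed = 5)
  n <- 1e5
  x <- sample_thresholds(spec, n)
  # Kolmogorov-Smirnov against the analytic truncated CDF
  xs <- sort(x)
  ks <- max(abs(truncated_cdf(spec, xs) - (seq_len(n) - 0.5) / n))
  expect_lt(ks, 0.01)
  expect_equal(median(x), -40, tolerance = 0.05)
  iqr <- unname(diff(quantile(x, c(0.25, 0.75))))
  expect_equal(iqr, 2 * spec$width, tolerance = 0.05 * 2 * spec$width)
})

test_that("truncated Gaussian sampler reproduces mean and SD under wide truncation", {
  spec <- disorder_spec("gaussian", -40, 1, -60, -20, seed = 6)
  x <- sample_thresholds(spec, 1e5)
  expect_equal(mean(x), -40, tolerance = 0.02)
  expect_equal(sd(x), 1, tolerance = 0.02)
})
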