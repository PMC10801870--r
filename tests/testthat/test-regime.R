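# Regime classification and ramp-based bifurcation detection.

test_that("fold detection interpolates the threshold crossing of a ramp", {
  cfg <- bif_detect_config()
  t <- seq(0, 2000, by = 1)
  rate <- t / 100          # Hz, crosses 10 Hz at t = 1000
  input <- t / 10          # pA
  expect_equal(detect_fold_by_ramp(rate, input, cfg), 100)
  # decreasing ramp: downward crossing
  expect_equal(detect_fold_by_ramp(rev(rate), rev(input), cfg), 100)
  # flat subthreshold trace -> no crossing
  expect_true(is.na(detect_fold_by_ramp(rep(1, 100), seq_len(100), cfg)))
})

test_that("Hopf detection returns the input interval sustaining large cycles", {
  cfg <- bif_detect_config()
  t <- seq(0, 4000, by = 1)
  input <- 20 + t / 50  # 20 -> 100 pA
  amp <- ifelse(input >= 40 & input <= 60, 12, 1)  # qualifying only in [40, 60]
  rate <- 30 + amp * sin(2 * pi * t / 100)
  h <- detect_hopf_by_ramp(rate, input, cfg)
  expect_equal(unname(h[1]), 40, tolerance = 2)
  expect_equal(unname(h[2]), 60, tolerance = 2)
  # four qualifying cycles only -> below min_cycles -> none
  t4 <- seq(0, 420, by = 1)
  rate4 <- 30 + 12 * sin(2 * pi * t4 / 100)
  expect_null(detect_hopf_by_ramp(rate4, 20 + t4 / 10, cfg))
})

test_that("classifier separates the known regimes of the adapting population", {
  cfg <- bif_detect_config(settle_time = 1000, measure_time = 2000)
  rs100 <- izh_params("rs", kappa = 100)
  expect_equal(classify_mf_regime(rs100, 0.1, 40, cfg), "quiescent_mono")
  expect_equal(classify_mf_regime(rs100, 0.1, 58, cfg), "oscillatory")
  expect_equal(classify_mf_regime(rs100, 0.1, 75, cfg), "active_mono")
  expect_equal(classify_mf_regime(rs_params, 0.5, 30, cfg), "bistable")
})

test_that("degenerate single-cell maps produce one label and no boundaries", {
  cfg <- bif_detect_config(settle_time = 400, measure_time = 600)
  m <- map_regimes(rs_params, 60, 0.5, cfg)
  expect_equal(nrow(m$cells), 1)
  expect_equal(nrow(m$boundaries), 0)
  expect_equal(regime_band_width(m, "bistable")$width, 0)
})

test_that("classification is invariant to doubling the settle time", {
  base <- bif_detect_config(settle_time = 1000, measure_time = 2000)
  long <- bif_detect_config(settle_time = 2000, measure_time = 2000)
  for (I in c(30, 45, 60)) {
    expect_equal(classify_mf_regime(rs_params, 0.5, I, base),
                 classify_mf_regime(rs_params, 0.5, I, long))
  }
})

test_that("ramp-based fold converges to the grid boundary as the ramp slows", {
  cfg_grid <- bif_detect_config(settle_time = 1000, measure_time = 2000)
  m <- map_regimes(rs_params, seq(40, 60, 2), 0.5, cfg_grid)
  upper_fold <- max(m$boundaries$I_boundary)
  est <- sapply(c(0.02, 0.005), function(rr) {
    cfg <- bif_detect_config(ramp_rate = rr, settle_time = 500)
    rp <- mf_ramp(rs_params, 0.5, 35, 60, cfg)
    detect_fold_by_ramp(rp$rate_hz, rp$input, cfg, sample_dt = 0.5)
  })
  expect_lt(abs(est[2] - upper_fold), abs(est[1] - upper_fold) + 0.25)
  expect_lt(abs(est[2] - upper_fold), 3)  # slow-passage lag at 0.005 pA/ms
})
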