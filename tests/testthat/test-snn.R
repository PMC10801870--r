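# Spiking-network engine: Euler dynamics, rates, smoothing, stimulation.

test_that("stimulus segments evaluate to the declared waveforms", {
  stim <- stim_protocol(10, list(
    stim_segment(100, 200, 30),
    stim_segment(300, 400, 20, waveform = "ramp"),
    stim_segment(500, 600, 4, waveform = "sinusoid", omega = 10)))
  t <- c(0, 150, 350, 525)
  expect_equal(stim_current(stim, t),
               c(10, 40, 10 + 20 * 0.5, 10 + 4 * sin(2 * pi * 10 * 0.025)))
  expect_error(stim_segment(200, 100, 1))
})

test_that("a neuron initialized at rest with no input stays at rest", {
  out <- run_snn(rs_params, thresholds = -40, stim = 0, duration = 50)
  expect_equal(nrow(out$raster), 0)
  expect_equal(out$state_final$v, -60, tolerance = 1e-12)
  expect_equal(out$state_final$u, 0, tolerance = 1e-12)
  expect_equal(max(abs(out$vbar + 60)), 0, tolerance = 1e-12)
})

test_that("single-neuron inter-spike interval converges under step refinement", {
  isi_at <- function(dt) {
    integ <- integrator_config(rs_params, dt = dt)
    out <- run_snn(rs_params, thresholds = -40, stim = 200, duration = 500,
                   integ = integ)
    d <- diff(out$raster$time)
    mean(d[-1])  # drop the first interval (transient from rest)
  }
  isi_coarse <- isi_at(0.01)
  isi_fine <- isi_at(0.001)
  expect_equal(isi_coarse, isi_fine, tolerance = 0.01)
})

test_that("population rate counts spikes per bin per neuron, in spikes/ms and Hz", {
  raster <- data.frame(neuron = c(1L, 2L, 2L), time = c(5, 5, 15))
  pr <- population_rate(raster, bin = 10, duration = 20, n_neurons = 2)
  expect_equal(pr$r, c(0.1, 0.05))
  expect_equal(pr$r_hz, c(100, 50))

  empty <- data.frame(neuron = integer(0), time = numeric(0))
  expect_equal(population_rate(empty, 10, 100, 5)$r, rep(0, 10))

  one <- data.frame(neuron = rep(1L, 10), time = seq(10, 100, by = 10))
  expect_equal(population_rate(one, bin = 100, duration = 100,
                               n_neurons = 1)$r, 0.1)
})

test_that("rate smoothing is the unit-area kernel response to single spikes", {
  r1 <- data.frame(neuron = 1L, time = 50)
  sm <- smooth_rates(r1, n_neurons = 1, fs = 10, sigma = 20, t_start = 0,
                     t_end = 100)
  expect_equal(ncol(sm), 1000)
  expect_equal(sum(sm), 1, tolerance = 1e-6)             # unit integral
  expect_equal(which.max(sm[1, ]), 501, tolerance = 1)   # peak at the spike
  # no spikes -> zero row
  sm0 <- smooth_rates(data.frame(neuron = integer(0), time = numeric(0)),
                      n_neurons = 2, fs = 10, sigma = 20, t_start = 0,
                      t_end = 50)
  expect_equal(sm0, matrix(0, 2, 500))
  # two far-separated spikes -> additive kernels with integral 2
  r2 <- data.frame(neuron = 1L, time = c(100, 400))  # 30 sigma apart
  sm2 <- smooth_rates(r2, n_neurons = 1, fs = 10, sigma = 100, t_start = 0,
                      t_end = 500)
  expect_equal(sum(sm2), 2, tolerance = 1e-3)
  # windowed average agrees with the closed-form spike-mass computation
  wm <- getFromNamespace("window_mean_rates", "hetspike")(
    r2, 1, 50, 450, fs = 10, sigma = 100)
  expect_equal(wm, mean(sm2[1, 501:4500]), tolerance = 1e-6)
})

test_that("identical neurons under all-to-all coupling stay identical", {
  n <- 10
  cm <- build_connectivity(connectivity_spec(n, "all_to_all"), J = 15)
  out <- run_snn(rs_params, thresholds = rep(-40, n), coupling = cm,
                 stim = 100, duration = 200)
  expect_gt(nrow(out$raster), 0)
  counts <- table(factor(out$raster$neuron, levels = 1:n))
  expect_equal(length(unique(as.numeric(counts))), 1)
  # all spike times shared across neurons
  by_time <- table(out$raster$time)
  expect_true(all(by_time == n))
})

test_that("recorded rate trace integrates to the raster spike count", {
  net <- tiny_net(50, seed = 2)
  out <- run_snn(rs_params, net$thresholds, net$coupling, stim = 70,
                 duration = 300, record_dt = 1)
  total_from_rate <- sum(out$rate$r) * 1 * 50  # r * bin * N
  expect_equal(total_from_rate, nrow(out$raster))
  expect_true(all(diff(out$raster$time[out$raster$neuron == out$raster$neuron[1]]) > 0))
})

test_that("halving dt shifts the asynchronous steady rate by under 2 percent", {
  net <- tiny_net(100, seed = 4)
  rate_at <- function(dt) {
    integ <- integrator_config(rs_params, dt = dt)
    out <- run_snn(rs_params, net$thresholds, net$coupling, stim = 70,
                   duration = 1000, integ = integ, record_raster = FALSE)
    mean(out$rate$r_hz[out$rate$time > 500])
  }
  expect_equal(rate_at(0.01), rate_at(0.005), tolerance = 0.02)
})

test_that("masked stimulation reaches only the targeted neurons", {
  n <- 40
  stim <- stim_protocol(0, list(stim_segment(0, 300, 200, mask = 1:10)))
  out <- run_snn(rs_params, rep(-40, n), coupling = NULL, stim = stim,
                 duration = 300)
  spikers <- unique(out$raster$neuron)
  expect_true(all(spikers <= 10))
  expect_gt(length(spikers), 0)
})

test_that("blow-up is reported with the offending step", {
  # a huge hyperpolarizing current pins the neuron far below rest, where the
  # quadratic makes the Euler map unstable (no reset catches the divergence)
  expect_error(
    run_snn(rs_params, thresholds = -40, stim = -1e13, duration = 10),
    "blew up")
})
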