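# Ring-network bump retention metrics and protocol.

test_that("bump RMSE has its closed-form values on degenerate profiles", {
  n <- 200
  mask <- numeric(n)
  mask[1:50] <- 1  # p_in = 0.25
  expect_equal(bump_rmse(mask, mask), 0)
  expect_equal(bump_rmse(rep(1, n), mask), sqrt(0.75))
  expect_equal(bump_rmse(rep(0, n), mask), sqrt(0.25))
})

test_that("the RMSE is invariant under ring rotation", {
  n <- 100
  mask <- numeric(n); mask[1:25] <- 1
  set.seed(1)
  profile <- runif(n)
  for (shift in c(10, 37, 80)) {
    idx <- ((seq_len(n) - 1 + shift) %% n) + 1
    expect_equal(bump_rmse(profile, mask), bump_rmse(profile[idx], mask[idx]))
  }
})

test_that("a silent test window is flagged with the all-zero profile", {
  proto <- bump_protocol(n_neurons = 100, duration = 500, stim_on = 100,
                         stim_off = 200, test_window = 100,
                         I_base = -50, I_stim = -40)  # strongly hyperpolarized
  tr <- run_bump_trial(rs_params, 0.2, proto, seed = 1)
  expect_true(tr$flagged)
  expect_equal(tr$profile, rep(0, 100))
  expect_equal(tr$rmse, sqrt(0.25), tolerance = 1e-10)
  expect_equal(tr$off_bump_mean, 0)
})

test_that("stimulated trials normalize to a unit-max profile", {
  proto <- bump_protocol(n_neurons = 200, duration = 900, stim_on = 200,
                         stim_off = 500, test_window = 200)
  tr <- run_bump_trial(rs_params, 0.2, proto, seed = 2)
  expect_false(tr$flagged)
  expect_equal(max(tr$profile), 1)
  expect_true(all(tr$profile >= 0))
  expect_equal(sum(tr$mask), ceiling(0.25 * 200))
})

test_that("null stimulation leaves no arc preference", {
  # I_stim = I_base: the mask is immaterial, so profile overlap with the arc
  # should sit at chance across seeds
  proto <- bump_protocol(n_neurons = 150, duration = 800, stim_on = 200,
                         stim_off = 400, test_window = 200,
                         I_base = 60, I_stim = 60)
  overlaps <- sapply(1:4, function(sd) {
    tr <- run_bump_trial(rs_params, 0.5, proto, seed = sd)
    mean(tr$profile[tr$mask == 1]) - mean(tr$profile[tr$mask == 0])
  })
  expect_lt(abs(mean(overlaps)), 0.15)
})

test_that("reduced-scale trials preserve the heterogeneity ordering of retention", {
  proto <- bump_protocol(n_neurons = 400, duration = 1500, stim_on = 300,
                         stim_off = 600, test_window = 200)
  sw <- bump_sweep(rs_params, proto, p_in_grid = 0.25,
                   delta_grid = c(0.2, 1.5), seeds = 1:2)
  m <- aggregate(cbind(rmse, off_bump_mean) ~ delta_v, sw, mean)
  expect_lt(m$rmse[m$delta_v == 0.2], m$rmse[m$delta_v == 1.5])
  expect_lt(m$off_bump_mean[m$delta_v == 0.2],
            m$off_bump_mean[m$delta_v == 1.5])
})
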