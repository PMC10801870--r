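# Mean-field equations: derivatives, integration, fixed points, scaling.

test_that("the quiescent state is an exact equilibrium at zero input", {
  d <- mf_derivative(c(0, rs_params$vr, 0, 0), rs_params, I = 0)
  expect_equal(unname(d), rep(0, 4))
})

test_that("r = 0 nullcline fixed points match the closed-form quadratic roots", {
  # with r = 0, s = 0, u = b (v - vr): the v-equation reduces to
  # k (v - vr)(v - vtheta) - b (v - vr) = 0 shifted by I; at I = 0 for the
  # regular-spiking constants the roots are v = -60 and v = -30/0.7
  fp1 <- find_fixed_point(rs_params, delta_v = 0, I = 0,
                          guess = c(0, -60, 0, 0))
  expect_equal(unname(fp1$state[["v"]]), -60, tolerance = 1e-9)
  expect_equal(unname(fp1$state[["r"]]), 0, tolerance = 1e-12)
  expect_true(fp1$stable)

  root2 <- -30 / 0.7
  fp2 <- find_fixed_point(rs_params, delta_v = 0, I = 0,
                          guess = c(0, -42.5, -35, 0))
  expect_equal(unname(fp2$state[["v"]]), root2, tolerance = 1e-9)
  expect_equal(unname(fp2$state[["r"]]), 0, tolerance = 1e-12)
  expect_false(fp2$stable)  # the saddle separating the two attractors
})

test_that("zero heterogeneity removes the disorder terms", {
  d <- mf_derivative(c(0, -50, 0, 0), rs_params, delta_v = 0, I = 0)
  expect_equal(unname(d[["r"]]), 0)
  d2 <- mf_derivative(c(0.01, -50, 0, 0), rs_params, delta_v = 0, I = 0)
  d2b <- mf_derivative(c(0.01, -50, 0, 0), rs_params, delta_v = 1, I = 0)
  # with r > 0 the delta_v term in the v-equation matters
  expect_false(isTRUE(all.equal(d2[["v"]], d2b[["v"]])))
})

test_that("integrating from the quiescent fixed point stays put", {
  tr <- run_meanfield(rs_params, stim = 0, duration = 100)
  expect_lt(max(abs(tr$r)), 1e-10)
  expect_lt(max(abs(tr$v + 60)), 1e-8)
})

test_that("trajectories agree between dt = 0.01 and dt = 0.001 to 0.5 percent", {
  r_at <- function(dt) {
    tr <- run_meanfield(rs_params, stim = 60, duration = 1000, dt = dt,
                        record_dt = 1)
    tail(tr$r[, 1], 1)
  }
  expect_equal(r_at(0.01), r_at(0.001), tolerance = 0.005)
})

test_that("fixed points found by Newton are stationary under integration", {
  fp <- find_fixed_point(rs_params, delta_v = 0.5, I = 60,
                         guess = c(0.03, -45, 30, 2))
  expect_gt(fp$state[["r"]], 0)
  expect_true(fp$stable)
  tr <- run_meanfield(rs_params, delta_v = 0.5, stim = 60, duration = 100,
                      init = fp$state)
  drift <- abs(tail(tr$r[, 1], 1) - fp$state[["r"]])
  expect_lt(drift, 1e-8)
})

test_that("a guess far outside any basin surfaces as a convergence error", {
  expect_error(
    find_fixed_point(rs_params, delta_v = 0.5, I = 60,
                     guess = c(1e3, 1e4, -1e4, 1e3), max_iter = 8),
    "converge|singular")
})

test_that("step input into the bistable band leaves a persistent memory", {
  # 30 pA baseline (bistable), transient excursion to 60 pA, back to 40 pA
  # (inside the band): the population must remain on the high branch
  stim <- stim_protocol(30, list(stim_segment(500, 1000, 30),
                                 stim_segment(1000, 2500, 10)))
  tr <- run_meanfield(rs_params, delta_v = 0.5, stim = stim, duration = 2500,
                      record_dt = 1)
  before <- 1000 * mean(tr$r[tr$time < 450, 1])
  after <- 1000 * mean(tr$r[tr$time > 2300, 1])
  expect_lt(before, 5)
  expect_gt(after, 10)
})

test_that("current-scale invariance: scaling charge units rescales u only", {
  # multiplying (C, kappa, b, g) and all currents by a > 0 leaves (r, v, s)
  # trajectories invariant while u scales by a
  a <- 3.7
  scaled <- rs_params
  scaled$C <- a * scaled$C
  scaled$kappa <- a * scaled$kappa
  scaled$b <- a * scaled$b
  scaled$g <- a * scaled$g
  scaled$k <- a * scaled$k
  tr1 <- run_meanfield(rs_params, delta_v = 0.5, stim = 60, duration = 500,
                       record_dt = 1)
  tr2 <- run_meanfield(scaled, delta_v = 0.5, stim = 60 * a, duration = 500,
                       record_dt = 1)
  expect_equal(tr1$r, tr2$r, tolerance = 1e-10)
  expect_equal(tr1$v, tr2$v, tolerance = 1e-10)
  expect_equal(tr1$s, tr2$s, tolerance = 1e-10)
  expect_equal(a * tr1$u, tr2$u, tolerance = 1e-10)
})

test_that("two-population graphs wire conductance currents by source type", {
  g <- population_graph(
    list(list(params = rs_params, delta_v = 0.5, stim = 60),
         list(params = fs_params, delta_v = 1, stim = 20)),
    synapses = list(list(pre = 1, post = 1, J = 16),
                    list(pre = 2, post = 1, J = 16),
                    list(pre = 1, post = 2, J = 4),
                    list(pre = 2, post = 2, J = 4)))
  expect_equal(g$synapses[[2]]$E, -65)  # inhibitory source
  expect_equal(g$synapses[[3]]$E, 0)    # excitatory source
  expect_equal(g$synapses[[2]]$tau_s, 8)
  tr <- run_meanfield_graph(g, 500, record_dt = 1)
  expect_equal(ncol(tr$r), 2)
  expect_true(all(is.finite(tr$r)))
  df <- as.data.frame(tr)
  expect_setequal(unique(df$population), c(1, 2))
})
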