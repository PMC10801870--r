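# Connectivity construction: uniform, sparse random, power-law ring.

test_that("all-to-all coupling is uniform with weight J/N", {
  cm <- build_connectivity(connectivity_spec(4, "all_to_all"), J = 8)
  W <- as.matrix(cm)
  expect_equal(diag(W), rep(0, 4))
  expect_equal(W[upper.tri(W) | lower.tri(W)], rep(2, 12))
  cm_self <- build_connectivity(connectivity_spec(4, "all_to_all",
                                                  allow_self = TRUE), J = 8)
  expect_equal(as.matrix(cm_self), matrix(2, 4, 4))
})

test_that("sparse rows have exactly floor(pN) inputs of weight J/(pN)", {
  cm <- build_connectivity(connectivity_spec(100, "random_sparse", 0.2,
                                             seed = 3), J = 15)
  expect_equal(cm$in_degree, rep(20, 100))
  expect_equal(unique(cm$w), 15 / 20)
  W <- as.matrix(cm)
  expect_equal(unname(rowSums(W != 0)), rep(20, 100))
  expect_equal(diag(W), rep(0, 100))
  # deterministic given seed
  cm2 <- build_connectivity(connectivity_spec(100, "random_sparse", 0.2,
                                              seed = 3), J = 15)
  expect_identical(cm$tgt, cm2$tgt)
  expect_error(build_connectivity(connectivity_spec(3, "random_sparse", 0.2),
                                  J = 1), "at least one")
})

test_that("ring kernel probabilities normalize the circular power law", {
  ring_probs <- getFromNamespace("ring_probs", "hetspike")
  # N = 5, d = 1: circular distances from neuron 1 are {1, 2, 2, 1}
  p <- ring_probs(1, 5, 1)
  expect_equal(p, c(0, 1/3, 1/6, 1/6, 1/3))
  # d = 0 reduces to uniform over the others
  expect_equal(ring_probs(2, 5, 0), c(1/4, 0, 1/4, 1/4, 1/4))
})

test_that("ring sampling reproduces the distance kernel and keeps in-degree", {
  N <- 1000
  cm <- build_connectivity(connectivity_spec(N, "ring_power_law", 0.2,
                                             ring_exponent = 1.5, seed = 9),
                           J = 15)
  expect_equal(cm$in_degree, rep(200, N))
  src <- rep(seq_len(N), diff(cm$src_ptr))
  tgt <- cm$tgt + 1L
  dd <- pmin(abs(src - tgt), N - abs(src - tgt))
  expect_true(all(dd > 0))  # no self-connections
  # empirical tail mass of connection distances tracks the analytic kernel
  ring_probs <- getFromNamespace("ring_probs", "hetspike")
  ring_distance <- getFromNamespace("ring_distance", "hetspike")
  p_ref <- ring_probs(1, N, 1.5)
  d_ref <- ring_distance(1, N)
  for (x in c(25, 100, 400)) {
    expect_equal(mean(dd > x), sum(p_ref[d_ref > x]), tolerance = 0.25)
  }
})
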