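# Reservoir readout, dimensionality, and kernel statistics.

test_that("target signals evaluate to their closed forms", {
  t <- 0:249
  y1 <- make_target("product_sines", t)
  expect_equal(y1[1], 0)                      # sin(0) = 0
  expect_equal(y1[t == 25], 0, tolerance = 1e-12)  # second factor sin(pi) = 0
  expect_equal(y1[t == 100],
               sin(2 * pi * 5 * 0.1) * sin(2 * pi * 20 * 0.1),
               tolerance = 1e-12)
  y2 <- make_target("smoothed_delta", t)
  expect_equal(t[which.max(y2)], 150)
  expect_equal(sum(y2) * 1, 1, tolerance = 1e-4)  # unit integral on ms grid
})

test_that("ridge weights solve the regularized normal equations", {
  # identity features reproduce the target exactly at gamma = 0
  y <- sin(seq_len(8))
  m <- fit_readout(diag(8), y, gamma = 0)
  expect_equal(m$w, y, tolerance = 1e-10)
  expect_equal(test_mse(m, diag(8), y), 0, tolerance = 1e-18)

  # random case against an explicit solve
  X <- toy_X(5, 8)
  y <- cos(seq_len(8))
  m <- fit_readout(X, y, gamma = 0.1)
  w_ref <- solve(X %*% t(X) + 0.1 * diag(5), X %*% y)
  expect_equal(m$w, as.numeric(w_ref), tolerance = 1e-10)

  # shrinkage: the weight norm decreases monotonically in gamma
  norms <- sapply(c(0.01, 1, 100, 1e4), function(g) {
    sqrt(sum(fit_readout(X, y, gamma = g)$w^2))
  })
  expect_true(all(diff(norms) < 0))

  # rank-deficient X at gamma = 0 must error with advice
  Xr <- matrix(1, 4, 6)
  expect_error(fit_readout(Xr, seq_len(6), gamma = 0), "gamma > 0")
})

test_that("test error reduces to hand-computed values", {
  X1 <- rbind(c(1, 0), c(0, 1))
  X2 <- rbind(c(2, 0), c(0, 0))
  y <- c(1, 1)
  model <- structure(list(w = c(1, 1), gamma = 0), class = "readout_model")
  # trial 1: yhat = (1, 1), mse 0; trial 2: yhat = (2, 0), mse mean(1, 1) = 1
  expect_equal(test_mse(model, list(X1, X2), y), 0.5)
  null_model <- structure(list(w = c(0, 0), gamma = 0),
                          class = "readout_model")
  expect_equal(test_mse(null_model, list(X1), y), mean(y^2))
})

test_that("participation ratio matches eigenvalue closed forms", {
  expect_equal(pr_from_eigenvalues(rep(1, 7)), 7)
  expect_equal(pr_from_eigenvalues(c(2, 1, 1)), 16 / 6)
  expect_equal(pr_from_eigenvalues(c(5, 0, 0)), 1)

  # rank-1 matrix -> dimensionality 1
  X <- outer(c(1, 2, 3), sin(1:40))
  expect_equal(participation_ratio(X, center = FALSE), 1, tolerance = 1e-10)
  # orthogonal rows of equal power -> dimensionality = row count
  t <- seq(0, 2 * pi, length.out = 256)[-256]
  Xo <- rbind(sin(t), cos(t), sin(2 * t))
  expect_equal(participation_ratio(Xo, center = FALSE), 3, tolerance = 1e-10)
  expect_error(participation_ratio(matrix(0, 3, 5)), "all-zero")
  X2 <- toy_X(6, 30, seed = 2)
  pr <- participation_ratio(X2)
  expect_gte(pr, 1)
  expect_lte(pr, 6)
})

test_that("the response kernel is the ridge hat map restricted to a trial", {
  # orthonormal rows, gamma = 0: K is the identity on the spanned space
  Q <- qr.Q(qr(toy_X(6, 6, seed = 3)))
  X <- t(Q)  # 6 orthonormal rows of length 6
  K <- response_kernel(X, X, gamma = 0)
  expect_equal(K, diag(6), tolerance = 1e-10)
  y <- sin(1:6)
  expect_equal(as.numeric(y %*% K), y, tolerance = 1e-10)

  # explicit arithmetic on a small case
  Xt <- toy_X(3, 4, seed = 4)
  Xc <- cbind(Xt, toy_X(3, 4, seed = 5))
  K2 <- response_kernel(Xt, Xc, gamma = 0.2)
  K_ref <- t(Xt) %*% solve(Xc %*% t(Xc) + 0.2 * diag(3)) %*% Xt
  expect_equal(K2, K_ref, tolerance = 1e-10)

  # consistency with the readout: yhat on the training concatenation
  y4 <- cos(1:8)
  m <- fit_readout(Xc, y4, gamma = 0.2)
  Kc <- response_kernel(Xc, Xc, gamma = 0.2)
  expect_equal(as.numeric(m$w %*% Xc), as.numeric(y4 %*% Kc),
               tolerance = 1e-10)

  # large gamma shrinks the kernel toward zero
  K_big <- response_kernel(Xt, Xc, gamma = 1e8)
  expect_lt(max(abs(K_big)), 1e-4)
})

test_that("kernel variance averages absolute pairwise differences", {
  K <- diag(3)
  expect_equal(kernel_variance(list(K, K, K))$q, 0)
  ones <- matrix(1, 3, 3)
  kv <- kernel_variance(list(K, K + ones))
  expect_equal(kv$Q, ones)
  expect_equal(kv$q, 9)
  expect_equal(kv$q_norm, 1)
  # three trials with pairwise differences {0, c, c} entrywise
  cc <- 0.6
  kv3 <- kernel_variance(list(K, K, K + cc * ones))
  expect_equal(kv3$Q, (2 * cc / 3) * ones, tolerance = 1e-12)
  expect_error(kernel_variance(list(K)), "2 trials")
})

test_that("training error is non-increasing as gamma decreases", {
  X <- toy_X(10, 15, seed = 6)
  y <- sin(seq_len(15))
  train_err <- sapply(c(100, 1, 0.01, 1e-6), function(g) {
    m <- fit_readout(X, y, gamma = g)
    test_mse(m, X, y)
  })
  expect_true(all(diff(train_err) <= 1e-12))
})

test_that("onset responses are deterministic and kernel variance vanishes for identical trials", {
  proto <- onset_protocol(n_onsets = 4, n_train = 3, n_test = 1,
                          burn_in = 200, post_onset = 80, n_neurons = 60)
  resp1 <- collect_responses(rs_params, 0.5, proto, regime_input = 45,
                             seed = 3)
  resp2 <- collect_responses(rs_params, 0.5, proto, regime_input = 45,
                             seed = 3)
  expect_identical(resp1$X, resp2$X)
  expect_equal(length(resp1$X), 4)
  expect_equal(dim(resp1$X[[1]]), c(60, 80))
  # duplicated trials produce a zero-variance kernel set
  Xc <- do.call(cbind, resp1$X[resp1$train_idx])
  K <- response_kernel(resp1$X[[1]], Xc, gamma = 1)
  expect_equal(kernel_variance(list(K, K))$q, 0)
})
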