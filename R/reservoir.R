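# Reservoir-computing analysis: stimulation-onset protocol, ridge readout,
# participation-ratio dimensionality, and response-kernel variance.

#' Stimulation-onset protocol for the function-generation experiment
#'
#' A ring network is driven at a constant regime-selecting current; after a
#' burn-in the final network state becomes the shared initial condition. A
#' short extrinsic pulse is then delivered to a small arc of the ring at
#' `n_onsets` distinct onset times (equally spaced across one intrinsic
#' oscillation cycle in the oscillatory regime, or across `onset_span` ms in
#' asynchronous regimes), and the Gaussian-smoothed single-neuron rates over
#' the `post_onset` window after each onset form the feature matrices `X`.
#'
#' @param n_onsets number of onset times (default 50).
#' @param n_train,n_test train/test split (defaults 40/10; must sum to
#'   `n_onsets`; test onsets are chosen at random).
#' @param burn_in initial settling period (ms, default 2000). In the
#'   oscillatory regime the burn-in is extended to the next trough of the
#'   population-rate oscillation, so that all onset phases are measured from
#'   a trough.
#' @param post_onset response window after each onset (ms, default 250).
#' @param onset_span span of onset times in asynchronous regimes (ms,
#'   default 250); in the oscillatory regime the span is one measured
#'   intrinsic cycle.
#' @param n_neurons ring size (default 2000).
#' @param coupling_prob coupling probability (default 0.2).
#' @param ring_exponent ring kernel exponent (default 0.75).
#' @param pulse_amp pulse amplitude (pA, default 30).
#' @param pulse_dur pulse duration (ms, default 20).
#' @param pulse_frac stimulated fraction of the ring (default 0.25).
#' @param feature_sigma Gaussian SD (ms) of the rate smoothing that builds
#'   `X` (default 10).
#' @param feature_dt sample spacing of `X` columns (ms, default 1).
#' @return An object of class `onset_protocol`.
#' @export
onset_protocol <- function(n_onsets = 50, n_train = 40, n_test = 10,
                           burn_in = 2000, post_onset = 250,
                           onset_span = 250, n_neurons = 2000,
                           coupling_prob = 0.2, ring_exponent = 0.75,
                           pulse_amp = 30, pulse_dur = 20, pulse_frac = 0.25,
                           feature_sigma = 10, feature_dt = 1) {
  stopifnot(n_train + n_test == n_onsets, n_train >= 1, n_test >= 1,
            burn_in > 0, post_onset > 0, onset_span > 0,
            pulse_frac > 0, pulse_frac <= 1)
  structure(list(n_onsets = as.integer(n_onsets),
                 n_train = as.integer(n_train), n_test = as.integer(n_test),
                 burn_in = burn_in, post_onset = post_onset,
                 onset_span = onset_span, n_neurons = as.integer(n_neurons),
                 coupling_prob = coupling_prob,
                 ring_exponent = ring_exponent, pulse_amp = pulse_amp,
                 pulse_dur = pulse_dur, pulse_frac = pulse_frac,
                 feature_sigma = feature_sigma, feature_dt = feature_dt),
            class = "onset_protocol")
}

#' Target signals for function generation
#'
#' `"product_sines"` is the product of two sines at 5 Hz and 20 Hz,
#' `y(t) = sin(2 pi 5 t) sin(2 pi 20 t)` with `t` in seconds;
#' `"smoothed_delta"` is a unit-integral Gaussian of SD 15 ms centered at
#' 150 ms (a delta pulse convolved with a Gaussian kernel).
#'
#' @param kind `"product_sines"` or `"smoothed_delta"`.
#' @param times uniform time grid (ms), starting at the response onset.
#' @return numeric vector of target values on `times`.
#' @export
#' @examples
#' y1 <- make_target("product_sines", 0:249)
make_target <- function(kind = c("product_sines", "smoothed_delta"), times) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(times), length(times) >= 2)
  switch(kind,
    product_sines = sin(2 * pi * 5 * times / 1000) *
      sin(2 * pi * 20 * times / 1000),
    smoothed_delta = stats::dnorm(times, mean = 150, sd = 15)
  )
}

# Measure the intrinsic oscillation period (ms) from the tail of a rate trace
# sampled at `sample_dt`; NULL when fewer than 3 peaks are found.
trace_period <- function(r_hz, sample_dt, min_amp = 1) {
  cyc <- oscillation_cycles(r_hz)
  cyc <- cyc[cyc$amplitude >= min_amp, , drop = FALSE]
  if (nrow(cyc) < 3) return(NULL)
  stats::median(diff(cyc$peak)) * sample_dt
}

#' Collect stimulus-onset response matrices from a spiking network
#'
#' Runs the burn-in, extends it to the next population-rate trough when the
#' network oscillates, and then simulates one run per onset from the shared
#' initial state: a pulse of `pulse_amp` pA is applied to a contiguous arc of
#' `ceiling(pulse_frac * N)` neurons for `pulse_dur` ms starting at the onset
#' time, and the smoothed single-neuron rates over the following `post_onset`
#' ms form the `N x T` response matrix of that trial.
#'
#' @param params an [izh_params()] object.
#' @param delta_v heterogeneity half-width (mV).
#' @param protocol an [onset_protocol()].
#' @param regime_input constant background current selecting the dynamical
#'   regime (pA).
#' @param seed integer seed (thresholds, wiring, test-onset choice).
#' @param family disorder family.
#' @return list with `X` (list of `N x T` matrices), `train_idx`,
#'   `test_idx`, `onsets` (ms, relative to the shared initial state),
#'   `oscillatory`, `period` (ms or NA).
#' @export
collect_responses <- function(params, delta_v = NULL,
                              protocol = onset_protocol(), regime_input,
                              seed = 1L, family = "lorentzian") {
  validate_params(params)
  if (is.null(delta_v)) delta_v <- params$delta_v
  N <- protocol$n_neurons

  dspec <- disorder_for(params, family = family, width = delta_v,
                        seed = derive_seed(seed, 11))
  thresholds <- sample_thresholds(dspec, N)
  cm <- build_connectivity(
    connectivity_spec(N, "ring_power_law", protocol$coupling_prob,
                      protocol$ring_exponent, seed = derive_seed(seed, 12)),
    J = params$J)

  # stage 1: burn-in at the regime-selecting current
  burn <- run_snn(params, thresholds, cm, stim = regime_input,
                  duration = protocol$burn_in, record_dt = 1,
                  record_raster = FALSE)
  tail_win <- burn$rate$time > protocol$burn_in / 2
  r_tail <- gaussian_smooth_series(burn$rate$r_hz[tail_win], 3)
  period <- trace_period(r_tail, 1, min_amp = 10)
  oscillatory <- !is.null(period)
  state <- list(v = burn$state_final$v, u = burn$state_final$u,
                s = burn$state_final$s)

  # stage 2 (oscillatory only): continue to the next rate trough so that
  # onset phases are measured from a trough of the intrinsic cycle
  if (oscillatory) {
    tt <- burn$rate$time[tail_win]
    troughs <- oscillation_cycles(r_tail)$trough
    if (length(troughs)) {
      t_tr <- tt[troughs[length(troughs)]]
      extra <- (t_tr + ceiling((protocol$burn_in - t_tr) / period + 1e-9) *
                  period) - protocol$burn_in
      if (extra > 0.5) {
        cont <- run_snn(params, thresholds, cm, stim = regime_input,
                        duration = extra, record_dt = 1,
                        record_raster = FALSE,
                        init = list(v = state$v, u = state$u, s = state$s))
        state <- list(v = cont$state_final$v, u = cont$state_final$u,
                      s = cont$state_final$s)
      }
    }
  }

  span <- if (oscillatory) period else protocol$onset_span
  onsets <- (seq_len(protocol$n_onsets) - 1) / protocol$n_onsets * span
  arc <- ring_arc(N, protocol$pulse_frac, center = 1L)

  X <- lapply(onsets, function(t_on) {
    stim <- stim_protocol(regime_input, list(
      stim_segment(t_on, t_on + protocol$pulse_dur, protocol$pulse_amp,
                   mask = arc)))
    run_dur <- t_on + protocol$post_onset
    out <- run_snn(params, thresholds, cm, stim, run_dur, record_dt = 5,
                   init = list(v = state$v, u = state$u, s = state$s))
    fs <- 1 / protocol$feature_dt
    smooth_rates(out$raster, N, fs = fs,
                 sigma = protocol$feature_sigma / protocol$feature_dt,
                 t_start = t_on, t_end = run_dur)
  })

  test_idx <- with_seed(derive_seed(seed, 13),
                        sort(sample.int(protocol$n_onsets, protocol$n_test)))
  list(X = X, train_idx = setdiff(seq_len(protocol$n_onsets), test_idx),
       test_idx = test_idx, onsets = onsets, oscillatory = oscillatory,
       period = if (oscillatory) period else NA_real_)
}

# Default scale-relative ridge penalty: 1e-4 * trace(X X^T) / N.
default_gamma <- function(Xc) {
  1e-4 * sum(Xc^2) / nrow(Xc)
}

#' Choose the ridge penalty by leave-one-trial-out cross-validation
#'
#' For each candidate penalty (a log-spaced grid relative to
#' `trace(X X^T) / N`), every training trial is held out in turn, the readout
#' is fitted on the remaining trials, and the held-out mean-squared error is
#' recorded; the penalty minimizing the summed CV error over all supplied
#' targets is returned.
#'
#' @param X_train list of `N x T` training matrices (at least 2).
#' @param targets a target vector, or a list of target vectors (the CV error
#'   of each is normalized by the target variance before summing).
#' @param rel_grid candidate penalties relative to `trace(X X^T) / N`.
#' @return the selected penalty (absolute scale).
#' @export
cv_gamma <- function(X_train, targets, rel_grid = 10^seq(-6, 2)) {
  stopifnot(is.list(X_train), length(X_train) >= 2)
  if (!is.list(targets)) targets <- list(targets)
  Xc <- do.call(cbind, X_train)
  base <- sum(Xc^2) / nrow(Xc)
  G <- tcrossprod(Xc)
  err <- numeric(length(rel_grid))
  for (j in seq_along(X_train)) {
    Xj <- X_train[[j]]
    eg <- eigen(G - tcrossprod(Xj), symmetric = TRUE)
    rest <- do.call(cbind, X_train[-j])
    for (y in targets) {
      y_rest <- rep(y, length(X_train) - 1)
      rhs_v <- crossprod(eg$vectors, rest %*% y_rest)  # U^T X y
      Ux <- crossprod(eg$vectors, Xj)
      for (gi in seq_along(rel_grid)) {
        w_v <- rhs_v / (eg$values + rel_grid[gi] * base)
        yhat <- as.numeric(crossprod(w_v, Ux))
        err[gi] <- err[gi] + mean((yhat - y)^2) / stats::var(y)
      }
    }
  }
  rel_grid[which.min(err)] * base
}

#' Fit the ridge readout
#'
#' Solves `w = y X^T (X X^T + gamma I)^{-1}` where `X` is the horizontal
#' concatenation of the training-trial matrices and `y` is tiled to match.
#'
#' @param X_train list of `N x T` training matrices (or one matrix).
#' @param y target vector of length `T` (tiled across trials).
#' @param gamma ridge penalty; `NULL` uses the scale-relative default
#'   `1e-4 * trace(X X^T) / N`.
#' @return list of class `readout_model`: `w` (length-`N` weights), `gamma`.
#' @export
fit_readout <- function(X_train, y, gamma = NULL) {
  if (is.matrix(X_train)) X_train <- list(X_train)
  stopifnot(length(X_train) >= 1)
  Tt <- ncol(X_train[[1]])
  stopifnot(length(y) == Tt)
  Xc <- do.call(cbind, X_train)
  if (is.null(gamma)) gamma <- default_gamma(Xc)
  stopifnot(gamma >= 0)
  y_tiled <- rep(y, length(X_train))
  A <- tcrossprod(Xc) + diag(gamma, nrow(Xc))
  rhs <- Xc %*% y_tiled
  w <- tryCatch(solve(A, rhs), error = function(e) {
    stop("ridge system is singular; use gamma > 0 (", conditionMessage(e), ")")
  })
  structure(list(w = as.numeric(w), gamma = gamma), class = "readout_model")
}

#' Test mean-squared error of a readout
#'
#' @param model a [fit_readout()] result.
#' @param X_test list of `N x T` test matrices (or one matrix).
#' @param y target vector of length `T`.
#' @return mean over test trials of the time-averaged squared error between
#'   `w X` and `y`.
#' @export
test_mse <- function(model, X_test, y) {
  if (is.matrix(X_test)) X_test <- list(X_test)
  mean(vapply(X_test, function(X) {
    yhat <- as.numeric(model$w %*% X)
    mean((yhat - y)^2)
  }, numeric(1)))
}

#' Participation-ratio dimensionality
#'
#' `d = (sum lambda)^2 / sum lambda^2` over the eigenvalues of the covariance
#' of the (row-centered) activity matrix `X`; always between 1 and
#' `min(N, T)`.
#'
#' @param X `N x T` activity matrix.
#' @param center center each neuron's time course before computing the
#'   covariance (default `TRUE`).
#' @return the participation ratio.
#' @export
participation_ratio <- function(X, center = TRUE) {
  stopifnot(is.matrix(X))
  if (center) X <- X - rowMeans(X)
  sv <- svd(X, nu = 0, nv = 0)$d
  lam2 <- sv^2  # proportional to covariance eigenvalues
  if (sum(lam2) == 0) stop("participation ratio undefined for all-zero X")
  sum(lam2)^2 / sum(lam2^2)
}

#' Participation ratio from covariance eigenvalues
#'
#' @param lambda non-negative eigenvalues.
#' @return `(sum lambda)^2 / sum lambda^2`.
#' @export
pr_from_eigenvalues <- function(lambda) {
  stopifnot(all(lambda >= 0), sum(lambda) > 0)
  sum(lambda)^2 / sum(lambda^2)
}

#' Network response kernel of one trial
#'
#' `K = X_trial^T (X_train X_train^T + gamma I)^{-1} X_trial`, the `T x T`
#' ridge hat-matrix restricted to one trial: for any target `y`, the readout
#' trained on `X_train` reproduces `y K` on that trial.
#'
#' @param X_trial `N x T` response matrix of the trial.
#' @param X_train_concat `N x (n_train T)` concatenated training matrix.
#' @param gamma ridge penalty (`NULL`: scale-relative default).
#' @return `T x T` kernel matrix.
#' @export
response_kernel <- function(X_trial, X_train_concat, gamma = NULL) {
  stopifnot(nrow(X_trial) == nrow(X_train_concat))
  if (is.null(gamma)) gamma <- default_gamma(X_train_concat)
  A <- tcrossprod(X_train_concat) + diag(gamma, nrow(X_train_concat))
  B <- tryCatch(solve(A, X_trial), error = function(e) {
    stop("ridge system is singular; use gamma > 0 (", conditionMessage(e), ")")
  })
  crossprod(X_trial, B)
}

#' Trial-to-trial kernel variance
#'
#' `Q_ij` is the mean absolute difference of `K_ij` over all unordered trial
#' pairs; `q = sum_ij Q_ij^2`. A normalized copy `q / T^2` supports
#' comparisons across response lengths.
#'
#' @param K_list list of at least two `T x T` kernels.
#' @return list with `Q`, `q`, `q_norm`.
#' @export
kernel_variance <- function(K_list) {
  stopifnot(is.list(K_list))
  if (length(K_list) < 2) {
    stop("kernel variance needs at least 2 trials")
  }
  Tt <- nrow(K_list[[1]])
  n <- length(K_list)
  Q <- matrix(0, Tt, Tt)
  n_pairs <- 0
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      Q <- Q + abs(K_list[[a]] - K_list[[b]])
      n_pairs <- n_pairs + 1
    }
  }
  Q <- Q / n_pairs
  q <- sum(Q^2)
  list(Q = Q, q = q, q_norm = q / Tt^2)
}

#' Full function-generation sweep
#'
#' For each (regime input, heterogeneity, seed) combination: collect onset
#' responses, fit the ridge readout on the training trials for both target
#' signals, evaluate the test MSE, and compute the participation ratio of the
#' concatenated training activity and the kernel variance across training
#' trials.
#'
#' @param params an [izh_params()] object.
#' @param regime_inputs background currents (pA), e.g. `c(45, 55, 70)`.
#' @param delta_grid heterogeneity values (mV).
#' @param protocol an [onset_protocol()].
#' @param seeds integer seeds (network realizations).
#' @param family disorder family.
#' @return data.frame with one row per `(I, delta_v, seed)`:
#'   `mse_sines`, `mse_delta`, `mse` (their mean), `dimensionality`,
#'   `q`, `q_norm`, `oscillatory`.
#' @export
function_generation_sweep <- function(params, regime_inputs, delta_grid,
                                      protocol = onset_protocol(), seeds = 1L,
                                      family = "lorentzian") {
  grid <- expand.grid(I = regime_inputs, delta_v = delta_grid, seed = seeds,
                      KEEP.OUT.ATTRS = FALSE)
  times <- (seq_len(round(protocol$post_onset / protocol$feature_dt)) - 1) *
    protocol$feature_dt
  y1 <- make_target("product_sines", times)
  y2 <- make_target("smoothed_delta", times)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    resp <- collect_responses(params, grid$delta_v[i], protocol,
                              regime_input = grid$I[i], seed = grid$seed[i],
                              family = family)
    X_train <- resp$X[resp$train_idx]
    X_test <- resp$X[resp$test_idx]
    Xc <- do.call(cbind, X_train)
    gamma <- cv_gamma(X_train, list(y1, y2))
    m1 <- fit_readout(X_train, y1, gamma)
    m2 <- fit_readout(X_train, y2, gamma)
    mse1 <- test_mse(m1, X_test, y1)
    mse2 <- test_mse(m2, X_test, y2)
    K_list <- lapply(X_train, response_kernel, X_train_concat = Xc,
                     gamma = gamma)
    kv <- kernel_variance(K_list)
    data.frame(I = grid$I[i], delta_v = grid$delta_v[i], seed = grid$seed[i],
               mse_sines = mse1, mse_delta = mse2, mse = (mse1 + mse2) / 2,
               dimensionality = participation_ratio(Xc), q = kv$q,
               q_norm = kv$q_norm, oscillatory = resp$oscillatory)
  })
  do.call(rbind, res)
}
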