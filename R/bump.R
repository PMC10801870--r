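# Ring-network persistent-activity ("bump") protocol and retention metrics.

#' Protocol for the ring-network bump-retention experiment
#'
#' A ring network of regular-spiking neurons is held at a baseline current in
#' its bistable regime; during the stimulation window a contiguous arc of
#' `ceiling(p_in * N)` neurons receives the elevated stimulation current.
#' After stimulus offset the network runs freely; single-neuron rates are
#' smoothed (Gaussian kernel, `smooth_sigma` samples at `fs` samples/ms),
#' averaged over the final `test_window` ms, and normalized by the maximum
#' average rate. Retention is quantified by the RMSE between this normalized
#' profile and the binary input mask, and by the mean normalized activity
#' outside the stimulated arc.
#'
#' @param n_neurons ring size (default 2000).
#' @param coupling_prob coupling probability (default 0.2).
#' @param ring_exponent distance exponent `d` of the ring kernel
#'   (default 1.5).
#' @param I_base baseline current (pA, default 30).
#' @param I_stim total current received by stimulated neurons during the
#'   stimulation window (pA, default 60); the masked extra input is
#'   `I_stim - I_base`.
#' @param p_in stimulated fraction of the ring (default 0.25).
#' @param stim_on,stim_off stimulation window (ms; defaults 500 and 1000).
#' @param duration recording duration (ms, default 3000).
#' @param fs sampling rate for rate smoothing (samples/ms, default 10).
#' @param smooth_sigma Gaussian kernel SD in samples (default 200, i.e.
#'   20 ms).
#' @param test_window final analysis window (ms, default 200).
#' @param n_repeats default number of network realizations in sweeps
#'   (default 10).
#' @return An object of class `bump_protocol`.
#' @export
bump_protocol <- function(n_neurons = 2000, coupling_prob = 0.2,
                          ring_exponent = 1.5, I_base = 30, I_stim = 60,
                          p_in = 0.25, stim_on = 500, stim_off = 1000,
                          duration = 3000, fs = 10, smooth_sigma = 200,
                          test_window = 200, n_repeats = 10) {
  stopifnot(p_in > 0, p_in <= 1, stim_on < stim_off, stim_off < duration,
            test_window <= duration, fs > 0, smooth_sigma > 0)
  structure(list(n_neurons = as.integer(n_neurons),
                 coupling_prob = coupling_prob,
                 ring_exponent = ring_exponent, I_base = I_base,
                 I_stim = I_stim, p_in = p_in, stim_on = stim_on,
                 stim_off = stim_off, duration = duration, fs = fs,
                 smooth_sigma = smooth_sigma, test_window = test_window,
                 n_repeats = as.integer(n_repeats)),
            class = "bump_protocol")
}

#' RMSE between a normalized activity profile and the binary input mask
#'
#' @param profile normalized per-neuron activity in `[0, 1]`.
#' @param mask binary input mask (1 where stimulation was applied).
#' @return root-mean-squared error (dimensionless).
#' @export
bump_rmse <- function(profile, mask) {
  stopifnot(length(profile) == length(mask))
  sqrt(mean((profile - mask)^2))
}

#' Run one bump-retention trial
#'
#' Builds a power-law ring network with freshly sampled thresholds and
#' connections (sub-seeds derived from `seed`), applies the baseline current
#' everywhere and the stimulation current to a contiguous arc during the
#' stimulation window, and quantifies persistence over the final test window.
#'
#' @param params an [izh_params()] object (regular-spiking parameters place
#'   the network in its bistable regime at the default currents).
#' @param delta_v heterogeneity half-width (mV).
#' @param protocol a [bump_protocol()].
#' @param seed integer seed (thresholds, wiring).
#' @param family threshold disorder family (`"lorentzian"` or `"gaussian"`).
#' @param p_in stimulated fraction, overriding the protocol value.
#' @param keep_raster return the spike raster (memory-heavy for large rings).
#' @return list with `profile` (normalized per-neuron activity), `rmse`,
#'   `off_bump_mean`, `mask`, `flagged` (TRUE when the test window contained
#'   no spikes), and optionally `raster`.
#' @export
run_bump_trial <- function(params, delta_v = NULL, protocol = bump_protocol(),
                           seed = 1L, family = "lorentzian", p_in = NULL,
                           keep_raster = FALSE) {
  validate_params(params)
  if (is.null(delta_v)) delta_v <- params$delta_v
  if (is.null(p_in)) p_in <- protocol$p_in
  stopifnot(p_in > 0, p_in <= 1)
  N <- protocol$n_neurons

  dspec <- disorder_for(params, family = family, width = delta_v,
                        seed = derive_seed(seed, 1))
  thresholds <- sample_thresholds(dspec, N)
  cm <- build_connectivity(
    connectivity_spec(N, "ring_power_law", protocol$coupling_prob,
                      protocol$ring_exponent, seed = derive_seed(seed, 2)),
    J = params$J)

  arc <- ring_arc(N, p_in, center = 1L)
  mask <- numeric(N)
  mask[arc] <- 1
  stim <- stim_protocol(protocol$I_base, list(
    stim_segment(protocol$stim_on, protocol$stim_off,
                 protocol$I_stim - protocol$I_base, mask = arc)))

  out <- run_snn(params, thresholds, cm, stim, protocol$duration,
                 record_dt = 5)

  t2 <- protocol$duration
  t1 <- t2 - protocol$test_window
  avg <- window_mean_rates(out$raster, N, t1, t2, fs = protocol$fs,
                           sigma = protocol$smooth_sigma)
  flagged <- max(avg) <= 0
  profile <- if (flagged) avg else avg / max(avg)
  res <- list(profile = profile,
              rmse = bump_rmse(profile, mask),
              off_bump_mean = mean(profile[mask == 0]),
              mask = mask, flagged = flagged, delta_v = delta_v,
              p_in = p_in, seed = seed)
  if (keep_raster) res$raster <- out$raster
  res
}

#' Sweep bump retention over input width and heterogeneity
#'
#' Repeats [run_bump_trial()] over a grid of stimulated fractions and
#' heterogeneity values, for several network realizations.
#'
#' @param params an [izh_params()] object.
#' @param protocol a [bump_protocol()].
#' @param p_in_grid stimulated fractions.
#' @param delta_grid heterogeneity values (mV).
#' @param seeds integer seeds (default `1:protocol$n_repeats`).
#' @param family disorder family.
#' @return data.frame with one row per `(p_in, delta_v, seed)`:
#'   `rmse`, `off_bump_mean`, `flagged`.
#' @export
bump_sweep <- function(params, protocol = bump_protocol(), p_in_grid = 0.25,
                       delta_grid = NULL, seeds = NULL,
                       family = "lorentzian") {
  if (is.null(delta_grid)) delta_grid <- params$delta_v
  if (is.null(seeds)) seeds <- seq_len(protocol$n_repeats)
  grid <- expand.grid(p_in = p_in_grid, delta_v = delta_grid, seed = seeds,
                      KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    tr <- run_bump_trial(params, grid$delta_v[i], protocol,
                         seed = grid$seed[i], family = family,
                         p_in = grid$p_in[i])
    data.frame(p_in = grid$p_in[i], delta_v = grid$delta_v[i],
               seed = grid$seed[i], rmse = tr$rmse,
               off_bump_mean = tr$off_bump_mean, flagged = tr$flagged)
  })
  do.call(rbind, res)
}
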