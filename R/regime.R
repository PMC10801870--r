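# Dynamical-regime classification and fold/Hopf detection, on the mean-field
# equations (grid + bisection) and on rate traces from slow input ramps.

#' Detection settings for regime classification and ramp-based bifurcation
#' detection
#'
#' @param rate_threshold rate threshold separating quiescent from persistent
#'   spiking (Hz, default 10).
#' @param osc_amplitude_min minimal trough-to-peak amplitude of a counted
#'   oscillation cycle (Hz, default 10).
#' @param min_cycles minimal number of consecutive qualifying cycles
#'   (default 5).
#' @param ramp_rate input ramp speed used by ramp helpers (pA/ms,
#'   default 0.01).
#' @param settle_time transient discarded before classification (ms).
#' @param measure_time post-transient window used for classification (ms).
#' @param smooth_sigma_ms Gaussian SD (ms) applied to a rate trace before
#'   cycle detection (0 = none; use a few ms for finite-size network traces).
#' @return An object of class `bif_detect_config`.
#' @export
bif_detect_config <- function(rate_threshold = 10, osc_amplitude_min = 10,
                              min_cycles = 5, ramp_rate = 0.01,
                              settle_time = 1000, measure_time = 1000,
                              smooth_sigma_ms = 0) {
  stopifnot(rate_threshold > 0, osc_amplitude_min > 0, min_cycles > 0,
            ramp_rate > 0, settle_time > 0, measure_time > 0,
            smooth_sigma_ms >= 0)
  structure(list(rate_threshold = rate_threshold,
                 osc_amplitude_min = osc_amplitude_min,
                 min_cycles = min_cycles, ramp_rate = ramp_rate,
                 settle_time = settle_time, measure_time = measure_time,
                 smooth_sigma_ms = smooth_sigma_ms),
            class = "bif_detect_config")
}

# Gaussian smoothing of a regularly sampled series (SD in samples).
gaussian_smooth_series <- function(x, sigma) {
  if (sigma <= 0) return(x)
  half <- ceiling(4 * sigma)
  kern <- stats::dnorm(-half:half, sd = sigma)
  kern <- kern / sum(kern)
  n <- length(x)
  xp <- c(rep(x[1], half), x, rep(x[n], half))
  as.numeric(stats::filter(xp, kern, sides = 2))[(half + 1):(half + n)]
}

# Local maxima / minima indices of a series (strict sign change of the
# forward difference; plateaus contribute their first point).
local_extrema <- function(x) {
  s_nz <- sign(diff(x))
  # propagate the previous nonzero slope through flat segments
  for (i in seq_along(s_nz)) {
    if (s_nz[i] == 0 && i > 1) s_nz[i] <- s_nz[i - 1]
  }
  turn <- diff(s_nz)
  peaks <- which(turn < 0) + 1L
  troughs <- which(turn > 0) + 1L
  list(peaks = peaks, troughs = troughs)
}

# Oscillation cycles of a rate trace: consecutive trough -> peak pairs with
# their amplitudes (in the units of the trace) and index positions.
oscillation_cycles <- function(x) {
  ex <- local_extrema(x)
  if (!length(ex$peaks) || !length(ex$troughs)) {
    return(data.frame(trough = integer(0), peak = integer(0),
                      amplitude = numeric(0)))
  }
  # pair each trough with the first following peak
  pk <- ex$peaks
  cycles <- lapply(ex$troughs, function(tr) {
    nxt <- pk[pk > tr]
    if (!length(nxt)) return(NULL)
    c(tr, nxt[1])
  })
  cycles <- do.call(rbind, cycles)
  if (is.null(cycles)) {
    return(data.frame(trough = integer(0), peak = integer(0),
                      amplitude = numeric(0)))
  }
  cycles <- cycles[!duplicated(cycles[, 2]), , drop = FALSE]
  data.frame(trough = cycles[, 1], peak = cycles[, 2],
             amplitude = x[cycles[, 2]] - x[cycles[, 1]])
}

# Longest run of consecutive qualifying cycles; returns list(len, first, last)
# with row indices into the cycles frame.
longest_cycle_run <- function(cycles, amp_min) {
  ok <- cycles$amplitude >= amp_min
  if (!any(ok)) return(list(len = 0L, first = NA_integer_, last = NA_integer_))
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  list(len = r$lengths[best], first = starts[best], last = ends[best])
}

# TRUE when the trace (Hz) sustains >= min_cycles consecutive cycles of
# trough-to-peak amplitude >= osc_amplitude_min.
is_oscillatory_trace <- function(r_hz, config, sample_dt = 1) {
  x <- r_hz
  if (config$smooth_sigma_ms > 0) {
    x <- gaussian_smooth_series(x, config$smooth_sigma_ms / sample_dt)
  }
  cyc <- oscillation_cycles(x)
  run <- longest_cycle_run(cyc, config$osc_amplitude_min)
  run$len >= config$min_cycles
}

#' Classify the dynamical regime of a mean-field population
#'
#' Integrates the mean-field equations from two initial conditions — the
#' quiescent state `(0, vr, 0, 0)` and an excited state consistent with a
#' high-rate attractor — discards `settle_time`, and labels the condition:
#' `"oscillatory"` when either trajectory sustains at least `min_cycles`
#' consecutive cycles of trough-to-peak amplitude `osc_amplitude_min`;
#' `"bistable"` when the two trajectories settle on non-oscillatory states
#' whose rates differ by more than `rate_threshold`; otherwise
#' `"active_mono"` or `"quiescent_mono"` depending on whether the common
#' steady rate exceeds `rate_threshold`.
#'
#' @param params an [izh_params()] object.
#' @param delta_v heterogeneity half-width (mV).
#' @param I constant input current (pA).
#' @param config a [bif_detect_config()].
#' @param dt Euler step (ms).
#' @return one of `"quiescent_mono"`, `"active_mono"`, `"bistable"`,
#'   `"oscillatory"`.
#' @export
classify_mf_regime <- function(params, delta_v = NULL, I = 0,
                               config = bif_detect_config(), dt = 0.01) {
  validate_params(params)
  if (is.null(delta_v)) delta_v <- params$delta_v
  duration <- config$settle_time + config$measure_time
  record_dt <- 0.1
  tr_q <- run_meanfield(params, delta_v, stim = I, duration = duration,
                        dt = dt, record_dt = record_dt)
  tr_e <- run_meanfield(params, delta_v, stim = I, duration = duration,
                        dt = dt, init = excited_init(params),
                        record_dt = record_dt)
  post <- tr_q$time > config$settle_time
  rq <- 1000 * tr_q$r[post, 1]
  re <- 1000 * tr_e$r[post, 1]
  if (is_oscillatory_trace(rq, config, record_dt) ||
      is_oscillatory_trace(re, config, record_dt)) {
    return("oscillatory")
  }
  tail_win <- max(1, floor(0.2 * length(rq)))
  r1 <- mean(rq[(length(rq) - tail_win + 1):length(rq)])
  r2 <- mean(re[(length(re) - tail_win + 1):length(re)])
  if (abs(r1 - r2) > config$rate_threshold) return("bistable")
  if (mean(c(r1, r2)) > config$rate_threshold) return("active_mono")
  "quiescent_mono"
}

#' Map dynamical regimes over an (input, heterogeneity) grid
#'
#' Classifies every `(I, delta_v)` grid cell with [classify_mf_regime()] and
#' refines the regime boundaries between differently labeled neighbors by
#' three bisection steps.
#'
#' @param params an [izh_params()] object.
#' @param input_grid input currents (pA), increasing.
#' @param delta_grid heterogeneity values (mV).
#' @param config a [bif_detect_config()].
#' @param dt Euler step (ms).
#' @param bisect_steps bisection refinements per boundary (default 3).
#' @return An object of class `regime_map`: data.frame `cells`
#'   (`I`, `delta_v`, `label`), data.frame `boundaries` (`delta_v`,
#'   `I_boundary`, `left_label`, `right_label`), and the grids.
#' @export
map_regimes <- function(params, input_grid, delta_grid,
                        config = bif_detect_config(), dt = 0.01,
                        bisect_steps = 3) {
  stopifnot(length(input_grid) >= 1, length(delta_grid) >= 1)
  input_grid <- sort(input_grid)
  cells <- expand.grid(I = input_grid, delta_v = delta_grid,
                       KEEP.OUT.ATTRS = FALSE)
  cells$label <- vapply(seq_len(nrow(cells)), function(i) {
    classify_mf_regime(params, cells$delta_v[i], cells$I[i], config, dt)
  }, character(1))

  boundaries <- list()
  for (dv in delta_grid) {
    row <- cells[cells$delta_v == dv, ]
    row <- row[order(row$I), ]
    if (nrow(row) < 2) next
    for (j in seq_len(nrow(row) - 1)) {
      if (row$label[j] == row$label[j + 1]) next
      lo <- row$I[j]; hi <- row$I[j + 1]
      lab_lo <- row$label[j]
      for (step in seq_len(bisect_steps)) {
        mid <- (lo + hi) / 2
        lab_mid <- classify_mf_regime(params, dv, mid, config, dt)
        if (lab_mid == lab_lo) lo <- mid else hi <- mid
      }
      boundaries[[length(boundaries) + 1]] <- data.frame(
        delta_v = dv, I_boundary = (lo + hi) / 2,
        left_label = row$label[j], right_label = row$label[j + 1])
    }
  }
  boundaries <- if (length(boundaries)) {
    do.call(rbind, boundaries)
  } else {
    data.frame(delta_v = numeric(0), I_boundary = numeric(0),
               left_label = character(0), right_label = character(0))
  }
  structure(list(cells = cells, boundaries = boundaries,
                 input_grid = input_grid, delta_grid = delta_grid),
            class = "regime_map")
}

#' Width (pA) of a regime band per heterogeneity value
#'
#' Total input-range occupied by the given label along each row of a
#' [map_regimes()] result, using the bisection-refined boundaries where
#' available (grid edges otherwise).
#'
#' @param map a `regime_map`.
#' @param label regime label, e.g. `"bistable"` or `"oscillatory"`.
#' @return data.frame with columns `delta_v` and `width`.
#' @export
regime_band_width <- function(map, label) {
  stopifnot(inherits(map, "regime_map"))
  dI <- if (length(map$input_grid) > 1) diff(map$input_grid) else 0
  out <- lapply(map$delta_grid, function(dv) {
    row <- map$cells[map$cells$delta_v == dv, ]
    row <- row[order(row$I), ]
    inb <- row$label == label
    if (!any(inb)) return(data.frame(delta_v = dv, width = 0))
    bd <- map$boundaries[map$boundaries$delta_v == dv, ]
    # runs of consecutive in-band cells
    r <- rle(inb)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    width <- 0
    for (k in which(r$values)) {
      i0 <- starts[k]; i1 <- ends[k]
      left <- if (i0 == 1) row$I[1] else {
        cand <- bd$I_boundary[bd$right_label == label &
                                bd$I_boundary <= row$I[i0] &
                                bd$I_boundary >= row$I[i0 - 1]]
        if (length(cand)) max(cand) else (row$I[i0 - 1] + row$I[i0]) / 2
      }
      right <- if (i1 == nrow(row)) row$I[nrow(row)] else {
        cand <- bd$I_boundary[bd$left_label == label &
                                bd$I_boundary >= row$I[i1] &
                                bd$I_boundary <= row$I[i1 + 1]]
        if (length(cand)) min(cand) else (row$I[i1] + row$I[i1 + 1]) / 2
      }
      width <- width + (right - left)
    }
    data.frame(delta_v = dv, width = width)
  })
  do.call(rbind, out)
}

#' Fold-bifurcation estimate from a slow input ramp
#'
#' Returns the input value at which a slowly ramped population first crosses
#' the rate threshold `rate_threshold` (upward for an increasing ramp,
#' downward for a decreasing one), linearly interpolated between samples.
#'
#' @param rate_hz population rate trace (Hz), aligned with `input_pa`.
#' @param input_pa input current trace (pA).
#' @param config a [bif_detect_config()]; `smooth_sigma_ms_samples` smoothing
#'   is applied first when the config's `smooth_sigma_ms > 0` (the caller
#'   supplies the sample spacing via `sample_dt`).
#' @param sample_dt spacing of trace samples (ms), used to convert the
#'   smoothing width to samples.
#' @return the fold input estimate (pA), or `NA` when the rate never crosses
#'   the threshold.
#' @export
detect_fold_by_ramp <- function(rate_hz, input_pa, config = bif_detect_config(),
                                sample_dt = 1) {
  stopifnot(length(rate_hz) == length(input_pa))
  if (config$smooth_sigma_ms > 0) {
    rate_hz <- gaussian_smooth_series(rate_hz,
                                      config$smooth_sigma_ms / sample_dt)
  }
  rT <- config$rate_threshold
  increasing <- utils::tail(input_pa, 1) >= input_pa[1]
  above <- if (increasing) rate_hz >= rT else rate_hz <= rT
  if (above[1] || !any(above)) {
    # already past threshold at start, or never crossing
    if (!any(above)) return(NA_real_)
    return(input_pa[1])
  }
  i <- which(above)[1]
  f <- (rT - rate_hz[i - 1]) / (rate_hz[i] - rate_hz[i - 1])
  input_pa[i - 1] + f * (input_pa[i] - input_pa[i - 1])
}

#' Hopf-bifurcation interval estimate from a slow input ramp
#'
#' Detects oscillation cycles (trough-to-peak pairs) along the ramped rate
#' trace, keeps the longest run of consecutive cycles with amplitude at least
#' `osc_amplitude_min`, and — provided the run contains at least `min_cycles`
#' cycles — returns the input values at the start and end of that run as the
#' two Hopf-point estimates.
#'
#' @inheritParams detect_fold_by_ramp
#' @return numeric `c(I_on, I_off)`, or `NULL` when no qualifying run exists.
#' @export
detect_hopf_by_ramp <- function(rate_hz, input_pa, config = bif_detect_config(),
                                sample_dt = 1) {
  stopifnot(length(rate_hz) == length(input_pa))
  x <- rate_hz
  if (config$smooth_sigma_ms > 0) {
    x <- gaussian_smooth_series(x, config$smooth_sigma_ms / sample_dt)
  }
  cyc <- oscillation_cycles(x)
  run <- longest_cycle_run(cyc, config$osc_amplitude_min)
  if (run$len < config$min_cycles) return(NULL)
  i_on <- cyc$trough[run$first]
  i_off <- cyc$peak[run$last]
  c(I_on = input_pa[i_on], I_off = input_pa[i_off])
}

#' Mean-field input-ramp trace
#'
#' Integrates a single mean-field population under a linear input ramp from
#' `I_from` to `I_to` at `config$ramp_rate` (after a settling period at
#' `I_from`) and returns aligned time / rate / input vectors for the ramp
#' segment, ready for [detect_fold_by_ramp()] or [detect_hopf_by_ramp()].
#'
#' @param params an [izh_params()] object.
#' @param delta_v heterogeneity half-width (mV).
#' @param I_from,I_to ramp endpoints (pA); a decreasing ramp is allowed.
#' @param config a [bif_detect_config()] (supplies `ramp_rate` and
#'   `settle_time`).
#' @param init optional initial state `c(r, v, u, s)`.
#' @param dt Euler step (ms).
#' @param record_dt trace resolution (ms).
#' @return list with `time`, `rate_hz`, `input` (ramp segment only).
#' @export
mf_ramp <- function(params, delta_v = NULL, I_from, I_to,
                    config = bif_detect_config(), init = NULL, dt = 0.01,
                    record_dt = 0.5) {
  ramp_dur <- abs(I_to - I_from) / config$ramp_rate
  duration <- config$settle_time + ramp_dur
  stim <- stim_protocol(I_from, list(
    stim_segment(config$settle_time, duration, I_to - I_from,
                 waveform = "ramp")))
  tr <- run_meanfield(params, delta_v, stim, duration, dt = dt,
                      init = init, record_dt = record_dt)
  keep <- tr$time >= config$settle_time
  input <- I_from + (tr$time[keep] - config$settle_time) /
    ramp_dur * (I_to - I_from)
  list(time = tr$time[keep], rate_hz = 1000 * tr$r[keep, 1], input = input)
}

#' Spiking-network input-ramp trace
#'
#' Runs a sparse spiking network under the same settling + linear ramp
#' protocol as [mf_ramp()] and returns the binned population-rate trace
#' aligned with the ramped input.
#'
#' @inheritParams mf_ramp
#' @param thresholds per-neuron spike thresholds (mV).
#' @param coupling a [build_connectivity()] result.
#' @param rate_bin population-rate bin (ms).
#' @return list with `time`, `rate_hz`, `input`.
#' @export
snn_ramp <- function(params, thresholds, coupling, I_from, I_to,
                     config = bif_detect_config(), rate_bin = 2) {
  ramp_dur <- abs(I_to - I_from) / config$ramp_rate
  duration <- config$settle_time + ramp_dur
  stim <- stim_protocol(I_from, list(
    stim_segment(config$settle_time, duration, I_to - I_from,
                 waveform = "ramp")))
  out <- run_snn(params, thresholds, coupling, stim, duration,
                 record_dt = rate_bin, record_raster = FALSE)
  keep <- out$rate$time >= config$settle_time
  input <- I_from + (out$rate$time[keep] - config$settle_time) /
    ramp_dur * (I_to - I_from)
  list(time = out$rate$time[keep], rate_hz = out$rate$r_hz[keep],
       input = input)
}
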