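# Entrainment of the mean-field model by sinusoidal forcing: phase-locking
# value between the forcing signal and the firing-rate fluctuations.

# Analytic signal restricted to a frequency band around f0 (Hz): FFT-domain
# band-pass (keep positive frequencies within rel_bw of f0, doubled), inverse
# transform. `fs` is in samples per ms.
band_analytic <- function(x, fs, f0, rel_bw = 0.3) {
  n <- length(x)
  X <- stats::fft(x - mean(x))
  freq_hz <- (seq_len(n) - 1) / n * fs * 1000  # 0 .. fs*1000
  keep <- freq_hz >= f0 * (1 - rel_bw) & freq_hz <= f0 * (1 + rel_bw) &
    freq_hz <= fs * 1000 / 2
  X[!keep] <- 0
  2 * stats::fft(X, inverse = TRUE) / n
}

#' Phase coherence between a periodic forcing and a rate trace
#'
#' Computes the phase-locking value
#' `PLV = |mean(exp(i (phi_r - phi_f)))|` between the instantaneous phases of
#' the two signals, band-passed within `rel_bw` of the forcing frequency
#' (analytic signal via FFT). A rate trace without an oscillatory component
#' at any frequency (numerically constant after detrending) returns 0 with
#' attribute `flagged = TRUE`.
#'
#' @param forcing forcing signal samples.
#' @param r rate trace samples (same length and sampling).
#' @param omega forcing frequency (Hz).
#' @param fs sampling rate (samples per ms).
#' @param rel_bw relative band half-width (default 0.3).
#' @return coherence in `[0, 1]`, with attribute `flagged`.
#' @export
#' @examples
#' t <- seq(0, 1000, by = 0.5)
#' x <- sin(2 * pi * 8 * t / 1000)
#' coherence(x, 3 + 2 * x, omega = 8, fs = 2) # 1
coherence <- function(forcing, r, omega, fs, rel_bw = 0.3) {
  stopifnot(length(forcing) == length(r), omega > 0, fs > 0)
  if (stats::sd(r) < 1e-12 * (abs(mean(r)) + 1)) {
    return(structure(0, flagged = TRUE))
  }
  zf <- band_analytic(forcing, fs, omega, rel_bw)
  zr <- band_analytic(r, fs, omega, rel_bw)
  if (mean(Mod(zr)) < 1e-9 * (stats::sd(r) + 1e-12)) {
    return(structure(0, flagged = TRUE))
  }
  dphi <- Arg(zr) - Arg(zf)
  structure(min(1, Mod(mean(exp(1i * dphi)))), flagged = FALSE)
}

#' Map entrainment coherence over frequency and heterogeneity (or strength)
#'
#' Integrates the single-population mean-field model under additive
#' sinusoidal forcing `I(t) = I0 + alpha sin(2 pi omega t)` for every grid
#' cell, discards the initial transient, and computes the phase coherence
#' between the forcing and the firing-rate fluctuations. Exactly one of
#' `delta_grid` / `alpha_grid` must be supplied; the other dimension is held
#' at `delta_v` / `alpha`.
#'
#' @param params an [izh_params()] object.
#' @param omega_grid forcing frequencies (Hz).
#' @param delta_grid heterogeneity values (mV), varied against `omega`.
#' @param alpha_grid forcing strengths (pA), varied against `omega`.
#' @param alpha forcing strength (pA) when `delta_grid` is used (default 4).
#' @param delta_v heterogeneity (mV) when `alpha_grid` is used.
#' @param I0 baseline current (pA); the default 55 pA places a strongly
#'   adapting regular-spiking population inside its oscillatory regime.
#' @param duration,discard simulation length and discarded transient (ms).
#' @param dt Euler step (ms).
#' @param record_dt trace resolution (ms).
#' @return data.frame with columns `omega`, `delta_v` or `alpha`,
#'   `coherence`, `flagged`.
#' @export
entrainment_map <- function(params, omega_grid, delta_grid = NULL,
                            alpha_grid = NULL, alpha = 4, delta_v = NULL,
                            I0 = 55, duration = 4000, discard = 1000,
                            dt = 0.01, record_dt = 0.5) {
  stopifnot(xor(is.null(delta_grid), is.null(alpha_grid)),
            discard < duration)
  vary_delta <- !is.null(delta_grid)
  grid <- if (vary_delta) {
    expand.grid(omega = omega_grid, delta_v = delta_grid,
                KEEP.OUT.ATTRS = FALSE)
  } else {
    if (is.null(delta_v)) delta_v <- params$delta_v
    expand.grid(omega = omega_grid, alpha = alpha_grid,
                KEEP.OUT.ATTRS = FALSE)
  }
  fs <- 1 / record_dt
  res <- lapply(seq_len(nrow(grid)), function(i) {
    om <- grid$omega[i]
    al <- if (vary_delta) alpha else grid$alpha[i]
    dv <- if (vary_delta) grid$delta_v[i] else delta_v
    if (al == 0) {
      return(cbind(grid[i, , drop = FALSE], coherence = 0, flagged = TRUE))
    }
    stim <- stim_protocol(I0, list(
      stim_segment(0, duration, al, waveform = "sinusoid", omega = om)))
    tr <- run_meanfield(params, dv, stim, duration, dt = dt,
                        init = excited_init(params), record_dt = record_dt)
    keep <- tr$time > discard
    forcing <- al * sin(2 * pi * om * tr$time[keep] / 1000)
    co <- coherence(forcing, 1000 * tr$r[keep, 1], om, fs)
    cbind(grid[i, , drop = FALSE], coherence = as.numeric(co),
          flagged = attr(co, "flagged"))
  })
  do.call(rbind, res)
}

#' Width of the entrained frequency band
#'
#' Number of grid frequencies (and their total span) with coherence above a
#' threshold, per value of the second map dimension.
#'
#' @param map an [entrainment_map()] result.
#' @param threshold coherence threshold (default 0.9).
#' @return data.frame with one row per `delta_v` (or `alpha`): `n_locked`,
#'   `band_width` (Hz, span between first and last locked frequency).
#' @export
entrained_band <- function(map, threshold = 0.9) {
  by_col <- if ("delta_v" %in% names(map)) "delta_v" else "alpha"
  out <- lapply(split(map, map[[by_col]]), function(mm) {
    locked <- mm$omega[mm$coherence > threshold & !mm$flagged]
    data.frame(v = mm[[by_col]][1], n_locked = length(locked),
               band_width = if (length(locked)) diff(range(locked)) else 0)
  })
  out <- do.call(rbind, out)
  names(out)[1] <- by_col
  rownames(out) <- NULL
  out
}
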