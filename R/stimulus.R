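# Time-dependent input protocols: baseline plus step / ramp / sinusoid
# segments, each optionally restricted to a subset of neurons.

#' Build a stimulation protocol
#'
#' A protocol is a baseline current plus a list of segments created with
#' [stim_segment()]. Segments without a `mask` apply to every neuron (and to a
#' mean-field population); masked segments apply only to the indexed neurons.
#'
#' @param baseline baseline current (pA) applied at all times.
#' @param segments list of [stim_segment()] objects.
#' @return An object of class `stim_protocol`.
#' @export
#' @examples
#' stim <- stim_protocol(30, list(stim_segment(500, 1000, amplitude = 30)))
stim_protocol <- function(baseline = 0, segments = list()) {
  stopifnot(is.numeric(baseline), length(baseline) == 1, is.list(segments))
  for (s in segments) stopifnot(inherits(s, "stim_segment"))
  structure(list(baseline = baseline, segments = segments),
            class = "stim_protocol")
}

#' One stimulation segment
#'
#' @param t_on,t_off segment window (ms), `t_on < t_off`.
#' @param amplitude current amplitude (pA): step height, ramp end value
#'   (the ramp rises linearly from 0 at `t_on` to `amplitude` at `t_off`), or
#'   sinusoid strength `alpha`.
#' @param waveform `"step"`, `"ramp"`, or `"sinusoid"`.
#' @param omega sinusoid frequency (Hz), required for `waveform = "sinusoid"`.
#' @param mask integer vector of 1-based neuron indices receiving the segment,
#'   or `NULL` for all neurons.
#' @return An object of class `stim_segment`.
#' @export
stim_segment <- function(t_on, t_off, amplitude,
                         waveform = c("step", "ramp", "sinusoid"),
                         omega = NULL, mask = NULL) {
  waveform <- match.arg(waveform)
  stopifnot(is.numeric(t_on), is.numeric(t_off), t_on < t_off,
            is.numeric(amplitude))
  if (waveform == "sinusoid") stopifnot(is.numeric(omega), omega > 0)
  if (!is.null(mask)) stopifnot(all(mask >= 1), anyDuplicated(mask) == 0)
  structure(list(t_on = t_on, t_off = t_off, amplitude = amplitude,
                 waveform = waveform, omega = omega,
                 mask = if (is.null(mask)) NULL else as.integer(mask)),
            class = "stim_segment")
}

# Evaluate one segment at times `t` (ms); zero outside its window.
segment_current <- function(seg, t) {
  on <- t >= seg$t_on & t < seg$t_off
  out <- numeric(length(t))
  out[on] <- switch(seg$waveform,
    step = seg$amplitude,
    ramp = seg$amplitude * (t[on] - seg$t_on) / (seg$t_off - seg$t_on),
    sinusoid = seg$amplitude * sin(2 * pi * seg$omega * (t[on] - seg$t_on) / 1000)
  )
  out
}

#' Evaluate a protocol's population-wide current
#'
#' Sums the baseline and all unmasked segments at the given times. Masked
#' segments are excluded (they are neuron-specific).
#'
#' @param protocol a [stim_protocol()].
#' @param t times (ms).
#' @return numeric vector of currents (pA).
#' @export
stim_current <- function(protocol, t) {
  stopifnot(inherits(protocol, "stim_protocol"))
  out <- rep(protocol$baseline, length(t))
  for (seg in protocol$segments) {
    if (is.null(seg$mask)) out <- out + segment_current(seg, t)
  }
  out
}

# Split a protocol into the shared current vector and (per masked segment)
# extra current columns + 0/1 masks, on the integration grid.
resolve_stimulus <- function(protocol, n_neurons, t) {
  common <- stim_current(protocol, t)
  masked <- Filter(function(s) !is.null(s$mask), protocol$segments)
  if (!length(masked)) {
    return(list(common = common, extra = NULL, masks = NULL))
  }
  extra <- vapply(masked, segment_current, numeric(length(t)), t = t)
  masks <- vapply(masked, function(s) {
    if (any(s$mask > n_neurons)) stop("stimulus mask index exceeds N")
    m <- numeric(n_neurons)
    m[s$mask] <- 1
    m
  }, numeric(n_neurons))
  list(common = common, extra = extra, masks = masks)
}

# Contiguous arc of ceil(frac * N) neurons centered at ring position `center`.
ring_arc <- function(n_neurons, frac, center = 1L) {
  stopifnot(frac > 0, frac <= 1)
  len <- ceiling(frac * n_neurons)
  idx <- (center - 1L + seq_len(len) - 1L - (len %/% 2L)) %% n_neurons + 1L
  sort(idx)
}
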