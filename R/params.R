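#' Electrophysiological parameter presets for Izhikevich cell types
#'
#' Returns the full parameter set of one of the three shipped cell types:
#' excitatory regular-spiking (`"rs"`), inhibitory fast-spiking (`"fs"`), and
#' inhibitory low-threshold-spiking (`"lts"`) neurons. The parameters enter the
#' membrane equation
#' \deqn{C \dot v_i = k (v_i - v_r)(v_i - v_{\theta,i}) - u + I(t) + g s (E - v_i)}
#' together with a shared recovery variable `u` (time constant `tau_u`,
#' voltage coupling `b`, spike-frequency-adaptation strength `kappa`) and an
#' exponentially filtered synaptic activation `s` (time constant `tau_s`,
#' recurrent coupling `J`).
#'
#' @param cell_type one of `"rs"`, `"fs"`, `"lts"`.
#' @param kappa spike-frequency-adaptation strength (pA) overriding the preset
#'   value, e.g. `kappa = 100` for a strongly adapting regular-spiking
#'   population.
#' @param delta_v heterogeneity half-width (mV) overriding the preset default.
#'
#' @return An object of class `izh_params`: a named list with fields
#'   `C` (pF), `k` (nS/mV), `vr` (mV), `vtheta_bar` (mV), `g` (nS), `E` (mV),
#'   `tau_u` (ms), `tau_s` (ms), `kappa` (pA), `b` (nS), `J` (dimensionless)
#'   and `delta_v` (mV), plus the `cell_type` tag.
#' @export
#' @examples
#' rs <- izh_params("rs")
#' rs_adapt <- izh_params("rs", kappa = 100)
izh_params <- function(cell_type = c("rs", "fs", "lts"), kappa = NULL,
                       delta_v = NULL) {
  cell_type <- match.arg(cell_type)
  p <- switch(cell_type,
    rs = list(C = 100, k = 0.7, vr = -60, vtheta_bar = -40, g = 1, E = 0,
              tau_u = 100 / 3, tau_s = 6, kappa = 10, b = -2, J = 15,
              delta_v = 0.5),
    fs = list(C = 20, k = 1, vr = -55, vtheta_bar = -40, g = 1, E = -65,
              tau_u = 5, tau_s = 8, kappa = 0, b = 0.025, J = 5,
              delta_v = 1),
    lts = list(C = 100, k = 1, vr = -56, vtheta_bar = -42, g = 1, E = -65,
               tau_u = 100 / 3, tau_s = 8, kappa = 20, b = 8, J = 5,
               delta_v = 1)
  )
  if (!is.null(kappa)) {
    stopifnot(is.numeric(kappa), length(kappa) == 1, is.finite(kappa))
    p$kappa <- kappa
  }
  if (!is.null(delta_v)) {
    stopifnot(is.numeric(delta_v), length(delta_v) == 1, delta_v >= 0)
    p$delta_v <- delta_v
  }
  p$cell_type <- cell_type
  structure(p, class = "izh_params")
}

#' @export
print.izh_params <- function(x, ...) {
  cat(sprintf("Izhikevich cell-type parameters ('%s')\n", x$cell_type))
  flds <- c("C", "k", "vr", "vtheta_bar", "g", "E", "tau_u", "tau_s",
            "kappa", "b", "J", "delta_v")
  units <- c("pF", "nS/mV", "mV", "mV", "nS", "mV", "ms", "ms", "pA", "nS",
             "", "mV")
  for (i in seq_along(flds)) {
    cat(sprintf("  %-10s %10.4g %s\n", flds[i], x[[flds[i]]], units[i]))
  }
  invisible(x)
}

validate_params <- function(params) {
  stopifnot(inherits(params, "izh_params") || is.list(params))
  req <- c("C", "k", "vr", "vtheta_bar", "g", "E", "tau_u", "tau_s",
           "kappa", "b", "J", "delta_v")
  miss <- setdiff(req, names(params))
  if (length(miss)) {
    stop("parameter set is missing fields: ", paste(miss, collapse = ", "))
  }
  with(params, stopifnot(C > 0, k > 0, tau_u > 0, tau_s > 0, delta_v >= 0))
  invisible(params)
}

#' Default symmetric truncation bounds for the spike-threshold distribution
#'
#' Threshold disorder is truncated so that (a) the smallest admissible spike
#' threshold stays above the resting potential and (b) the truncated
#' distribution remains symmetric about its center. The lower bound is
#' `vr + margin`; the upper bound mirrors it about the threshold center,
#' `2 * vtheta_bar - low`.
#'
#' @param params an [izh_params()] object (or compatible list).
#' @param margin safety margin above the resting potential (mV, default 0;
#'   sampling treats the bounds as an open interval, so `margin = 0` already
#'   guarantees thresholds strictly above `vr`).
#' @return numeric vector `c(low, high)` in mV.
#' @export
#' @examples
#' default_truncation(izh_params("rs")) # c(-60, -20)
default_truncation <- function(params, margin = 0) {
  validate_params(params)
  stopifnot(is.numeric(margin), length(margin) == 1, margin >= 0)
  if (params$vtheta_bar <= params$vr) {
    stop("threshold center must exceed the resting potential (vtheta_bar > vr)")
  }
  low <- params$vr + margin
  high <- 2 * params$vtheta_bar - low
  if (low >= high) stop("truncation margin too large: empty threshold interval")
  c(low = low, high = high)
}

#' Gaussian standard deviation matching a Lorentzian half-width
#'
#' Converts a Lorentzian half-width-at-half-maximum into the standard
#' deviation of the Gaussian with identical interquartile range. The
#' Lorentzian IQR equals `2 * delta`; the Gaussian IQR equals
#' `2 * qnorm(0.75) * sd`, so `sd = delta / qnorm(0.75)`.
#'
#' @param delta Lorentzian half-width-at-half-maximum (mV), `>= 0`.
#' @return Gaussian standard deviation (mV).
#' @export
#' @examples
#' gaussian_equivalent_width(1) # approximately 1.4826
gaussian_equivalent_width <- function(delta) {
  stopifnot(is.numeric(delta), all(delta >= 0))
  delta / stats::qnorm(0.75)
}
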