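# Quenched spike-threshold disorder: truncated Lorentzian / Gaussian sampling.

# Run `expr` under a temporary RNG state seeded with `seed`; restores the
# caller's RNG afterwards so package functions never disturb the global stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministically derive a sub-seed from a master seed, keeping the result
# inside the 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + 104729 * as.numeric(offset)) %% 2147483647)
}

#' Specify quenched spike-threshold disorder
#'
#' A disorder specification names the distribution family of the quenched
#' spike thresholds, its center and width, and the symmetric truncation
#' interval. For the Lorentzian family the width is the
#' half-width-at-half-maximum; for the Gaussian family it is the standard
#' deviation.
#'
#' @param family `"lorentzian"` or `"gaussian"`.
#' @param center distribution center (mV).
#' @param width Lorentzian HWHM or Gaussian SD (mV), `>= 0`.
#' @param truncation_low,truncation_high truncation bounds (mV); must bracket
#'   the center and be symmetric about it.
#' @param seed integer seed making threshold draws reproducible.
#' @return An object of class `disorder_spec`.
#' @seealso [disorder_for()] for building a spec from a cell-type preset,
#'   [sample_thresholds()].
#' @export
disorder_spec <- function(family = c("lorentzian", "gaussian"), center, width,
                          truncation_low, truncation_high, seed = 1L) {
  family <- match.arg(family)
  stopifnot(is.numeric(center), is.numeric(width), width >= 0,
            is.numeric(truncation_low), is.numeric(truncation_high))
  if (!(truncation_low < center && center < truncation_high)) {
    stop("truncation bounds must strictly bracket the center")
  }
  if (abs((truncation_high - center) - (center - truncation_low)) > 1e-9) {
    stop("truncation must be symmetric about the center")
  }
  structure(
    list(family = family, center = center, width = width,
         truncation_low = truncation_low, truncation_high = truncation_high,
         seed = as.integer(seed)),
    class = "disorder_spec"
  )
}

#' Disorder specification derived from a cell-type preset
#'
#' Convenience constructor: center at the preset's threshold center, default
#' width at the preset `delta_v` (converted via [gaussian_equivalent_width()]
#' for the Gaussian family when `match_iqr = TRUE`), truncation from
#' [default_truncation()].
#'
#' @param params an [izh_params()] object.
#' @param family distribution family.
#' @param width half-width (Lorentzian) in mV; defaults to `params$delta_v`.
#'   For the Gaussian family the width actually used is
#'   `gaussian_equivalent_width(width)` when `match_iqr = TRUE` (the default),
#'   so that both families share the same interquartile range.
#' @param margin truncation margin above the resting potential (mV).
#' @param seed integer seed.
#' @param match_iqr logical; match the Gaussian SD to the Lorentzian IQR.
#' @return A `disorder_spec`.
#' @export
disorder_for <- function(params, family = c("lorentzian", "gaussian"),
                         width = NULL, margin = 0, seed = 1L,
                         match_iqr = TRUE) {
  family <- match.arg(family)
  validate_params(params)
  if (is.null(width)) width <- params$delta_v
  if (family == "gaussian" && match_iqr) width <- gaussian_equivalent_width(width)
  tr <- default_truncation(params, margin)
  disorder_spec(family, params$vtheta_bar, width, tr[["low"]], tr[["high"]],
                seed = seed)
}

# Untruncated CDF of the two supported families.
disorder_cdf <- function(spec, x) {
  switch(spec$family,
    lorentzian = stats::pcauchy(x, location = spec$center, scale = spec$width),
    gaussian = stats::pnorm(x, mean = spec$center, sd = spec$width)
  )
}

# Untruncated quantile function.
disorder_quantile <- function(spec, p) {
  switch(spec$family,
    lorentzian = stats::qcauchy(p, location = spec$center, scale = spec$width),
    gaussian = stats::qnorm(p, mean = spec$center, sd = spec$width)
  )
}

#' Analytic CDF of the truncated disorder distribution
#'
#' @param spec a [disorder_spec()].
#' @param x evaluation points (mV).
#' @return CDF values in `[0, 1]`.
#' @export
truncated_cdf <- function(spec, x) {
  stopifnot(inherits(spec, "disorder_spec"))
  if (spec$width == 0) return(as.numeric(x >= spec$center))
  fa <- disorder_cdf(spec, spec$truncation_low)
  fb <- disorder_cdf(spec, spec$truncation_high)
  pmin(1, pmax(0, (disorder_cdf(spec, x) - fa) / (fb - fa)))
}

#' Sample quenched spike thresholds
#'
#' Draws `n` i.i.d. values from the truncated distribution by inverse-CDF
#' sampling restricted to the quantile interval
#' `(F(truncation_low), F(truncation_high))`: uniforms are drawn on the open
#' interval, so every sample lies strictly inside the truncation bounds and
#' the cost is deterministic (no rejection loop). A zero-width spec returns
#' `n` copies of the center. Identical `(spec, n)` always yields the identical
#' vector.
#'
#' @param spec a [disorder_spec()].
#' @param n number of neurons, `>= 1`.
#' @return numeric vector of `n` thresholds (mV).
#' @export
#' @examples
#' spec <- disorder_for(izh_params("rs"), seed = 7)
#' v_theta <- sample_thresholds(spec, 100)
sample_thresholds <- function(spec, n) {
  stopifnot(inherits(spec, "disorder_spec"), is.numeric(n), length(n) == 1,
            n >= 1)
  n <- as.integer(n)
  if (spec$width == 0) return(rep(spec$center, n))
  fa <- disorder_cdf(spec, spec$truncation_low)
  fb <- disorder_cdf(spec, spec$truncation_high)
  if (!(fb > fa)) stop("invalid truncation bounds: zero probability mass")
  with_seed(spec$seed, {
    u <- stats::runif(n)
    # keep the quantile strictly inside (fa, fb): open-interval sampling
    q <- fa + (fb - fa) * u
    x <- disorder_quantile(spec, q)
    pmin(pmax(x, spec$truncation_low + 1e-12), spec$truncation_high - 1e-12)
  })
}
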