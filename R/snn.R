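# Spiking-network simulation: Euler integration of Izhikevich populations
# with quenched spike thresholds.

#' Integrator configuration for spiking-network runs
#'
#' The spike cutoff `vp` and reset `v0` default to large values placed
#' symmetrically about the vertex of the membrane quadratic,
#' `vp = vtheta_bar + 240` and `v0 = (vr + vtheta_bar) - vp`, approximating
#' the infinite cutoff/reset limit assumed by the mean-field reduction.
#'
#' @param params an [izh_params()] object supplying the defaults.
#' @param dt Euler step (ms, default 0.01).
#' @param vp spike cutoff (mV); a spike is recorded when `v >= vp`.
#' @param v0 reset potential (mV).
#' @param u_mode `"global"` (one shared recovery variable per population,
#'   driven by the population-mean voltage and rate) or `"per_neuron"`.
#' @return An object of class `integrator_config`.
#' @export
integrator_config <- function(params, dt = 0.01, vp = NULL, v0 = NULL,
                              u_mode = c("global", "per_neuron")) {
  u_mode <- match.arg(u_mode)
  validate_params(params)
  stopifnot(dt > 0)
  if (is.null(vp)) vp <- params$vtheta_bar + 240
  if (is.null(v0)) v0 <- (params$vr + params$vtheta_bar) - vp
  stopifnot(vp > params$vtheta_bar, v0 < params$vr)
  structure(list(dt = dt, vp = vp, v0 = v0, u_mode = u_mode),
            class = "integrator_config")
}

# Assemble the C++ population descriptor.
snn_pop_descriptor <- function(params, thresholds, stim, integ, times, init) {
  n <- length(thresholds)
  res <- resolve_stimulus(stim, n, times)
  if (is.null(init)) {
    init <- list(v = rep(params$vr, n),
                 u = if (integ$u_mode == "per_neuron") rep(0, n) else 0,
                 s = NULL)
  }
  list(n = n, C = params$C, k = params$k, vr = params$vr,
       kappa = params$kappa, b = params$b, tau_u = params$tau_u,
       vp = integ$vp, v0 = integ$v0,
       u_per_neuron = integ$u_mode == "per_neuron",
       vtheta = as.numeric(thresholds),
       I_common = res$common, I_extra = res$extra, masks = res$masks,
       v_init = as.numeric(init$v), u_init = as.numeric(init$u))
}

snn_syn_descriptor <- function(pre, post, params, J, coupling, tau_s, g, E,
                               n_post, s_init = NULL) {
  shared <- is.null(coupling) || coupling$topology == "all_to_all"
  s_len <- if (shared) 1L else n_post
  if (is.null(s_init)) s_init <- rep(0, s_len)
  out <- list(pre = pre - 1L, post = post - 1L,
              tau_s = if (is.null(tau_s)) params$tau_s else tau_s,
              g = if (is.null(g)) params$g else g,
              E = if (is.null(E)) params$E else E,
              shared = shared, J = J, s_init = as.numeric(s_init))
  if (!shared) {
    out$src_ptr <- coupling$src_ptr
    out$tgt <- coupling$tgt
    out$w <- coupling$w
  }
  out
}

#' Simulate a single population of Izhikevich neurons
#'
#' Explicit Euler integration of the membrane equations with quenched
#' thresholds, a shared (or per-neuron) recovery variable, and synaptic
#' low-pass filtering. For `all_to_all` coupling (or `coupling = NULL`) one
#' shared synaptic activation is driven by the population rate; for sparse
#' coupling each neuron carries its own activation, kicked by presynaptic
#' spikes through the weights of the [build_connectivity()] matrix.
#'
#' @param params an [izh_params()] object.
#' @param thresholds per-neuron spike thresholds (mV), e.g. from
#'   [sample_thresholds()]; the vector length sets `N`.
#' @param coupling a [build_connectivity()] result, or `NULL` for an
#'   uncoupled / mean-drive run with total coupling `params$J`.
#' @param stim a [stim_protocol()] (a single number is promoted to a constant
#'   baseline).
#' @param duration simulated time (ms).
#' @param integ an [integrator_config()]; defaults derived from `params`.
#' @param record_dt resolution of the recorded population traces (ms).
#' @param init optional list with initial `v` (length `N`), `u`, `s`.
#' @param record_raster keep individual spike times (default `TRUE`).
#' @return An object of class `snn_result`: `raster` (data.frame with columns
#'   `neuron`, `time`), `rate` (data.frame `time`, `r` in spikes/ms, `r_hz`),
#'   `vbar`, `u`, `s_mean`, `state_final`, and the run configuration.
#' @export
#' @examples
#' rs <- izh_params("rs")
#' th <- sample_thresholds(disorder_for(rs, seed = 1), 50)
#' cm <- build_connectivity(connectivity_spec(50, "random_sparse", 0.2, seed = 1),
#'                          J = rs$J)
#' out <- run_snn(rs, th, cm, stim = 60, duration = 200)
run_snn <- function(params, thresholds, coupling = NULL, stim = 0,
                    duration = 1000, integ = integrator_config(params),
                    record_dt = 1, init = NULL, record_raster = TRUE) {
  validate_params(params)
  if (is.numeric(stim)) stim <- stim_protocol(stim)
  n <- length(thresholds)
  if (!is.null(coupling)) stopifnot(coupling$n_neurons == n)
  J <- if (is.null(coupling)) params$J else coupling$J
  pops <- list(list(params = params, thresholds = thresholds, stim = stim,
                    init = init))
  syn <- list(list(pre = 1L, post = 1L, J = J, coupling = coupling,
                   tau_s = NULL, g = NULL, E = NULL))
  out <- run_snn_network(pops, syn, duration = duration, integ = integ,
                         record_dt = record_dt, record_raster = record_raster)
  res <- out$populations[[1]]
  res$s_mean <- out$synapses[[1]]$s_mean
  res$state_final$s <- out$synapses[[1]]$s_final
  res$params <- params
  res$integ <- integ
  class(res) <- "snn_result"
  res
}

#' Simulate several coupled Izhikevich populations
#'
#' General multi-population front end: each population carries its own
#' parameters, thresholds, and stimulation; each synapse group links a
#' presynaptic to a postsynaptic population with its own total coupling `J`,
#' conductance `g`, reversal potential `E`, and filter time constant `tau_s`
#' (the latter three default to the presynaptic cell type's values, treating
#' the synapse as a property of the transmitter of the source population).
#'
#' @param populations list of lists with fields `params`, `thresholds`,
#'   `stim`, optional `integ` and `init`.
#' @param synapses list of lists with fields `pre`, `post` (1-based population
#'   indices), `J`, optional `coupling` (a [build_connectivity()] or
#'   [cross_coupling()] object; `NULL` means all-to-all mean drive), `tau_s`,
#'   `g`, `E`.
#' @param duration simulated time (ms).
#' @param integ default [integrator_config()] applied to populations without
#'   their own (built from each population's `params` if `NULL`).
#' @param record_dt trace resolution (ms).
#' @param record_raster keep spike times.
#' @return list with `populations` (per population: raster, rate trace, vbar,
#'   u, final state) and `synapses` (mean activation traces), plus `time`.
#' @export
run_snn_network <- function(populations, synapses, duration = 1000,
                            integ = NULL, record_dt = 1,
                            record_raster = TRUE) {
  dt <- if (is.null(integ)) 0.01 else integ$dt
  n_steps <- round(duration / dt)
  record_every <- max(1L, round(record_dt / dt))
  times <- (seq_len(n_steps) - 1) * dt

  pop_desc <- lapply(populations, function(pp) {
    ig <- if (!is.null(pp$integ)) {
      pp$integ
    } else if (!is.null(integ)) {
      integrator_config(pp$params, dt = dt, vp = integ$vp, v0 = integ$v0,
                        u_mode = integ$u_mode)
    } else {
      integrator_config(pp$params, dt = dt)
    }
    stim <- pp$stim
    if (is.numeric(stim)) stim <- stim_protocol(stim)
    snn_pop_descriptor(pp$params, pp$thresholds, stim, ig, times,
                       pp$init)
  })
  syn_desc <- lapply(synapses, function(sy) {
    pre_params <- populations[[sy$pre]]$params
    snn_syn_descriptor(sy$pre, sy$post, pre_params, sy$J, sy$coupling,
                       sy$tau_s, sy$g, sy$E,
                       n_post = length(populations[[sy$post]]$thresholds),
                       s_init = sy$s_init)
  })

  raw <- snn_sim_cpp(pop_desc, syn_desc, dt, n_steps, record_every,
                     record_raster)

  pops_out <- lapply(seq_along(populations), function(p) {
    rast <- as.data.frame(raw$rasters[[p]])
    n <- pop_desc[[p]]$n
    list(
      raster = structure(rast, n_neurons = n, duration = duration),
      rate = data.frame(time = raw$time, r = raw$r[, p],
                        r_hz = 1000 * raw$r[, p]),
      vbar = raw$vbar[, p], u = raw$u[, p],
      n_neurons = n, duration = duration, dt = dt, record_dt = record_dt,
      state_final = list(v = raw$v_final[[p]], u = raw$u_final[[p]])
    )
  })
  syns_out <- lapply(seq_along(synapses), function(m) {
    list(s_mean = raw$s[, m], s_final = raw$s_final[[m]])
  })
  list(time = raw$time, populations = pops_out, synapses = syns_out)
}

#' Sparse coupling between two populations
#'
#' Each of the `n_post` target neurons receives `floor(p * n_pre)` synapses
#' from uniformly sampled source neurons, each of weight `J / (p * n_pre)`.
#'
#' @param n_post,n_pre population sizes.
#' @param coupling_prob coupling probability `p`.
#' @param J total coupling strength.
#' @param seed integer seed.
#' @return A `coupling_matrix`-compatible object for [run_snn_network()].
#' @export
cross_coupling <- function(n_post, n_pre, coupling_prob, J, seed = 1L) {
  stopifnot(coupling_prob > 0, coupling_prob <= 1)
  k_in <- floor(coupling_prob * n_pre)
  stopifnot(k_in >= 1)
  pre <- with_seed(seed, lapply(seq_len(n_post), function(i) {
    sample.int(n_pre, k_in)
  }))
  src <- unlist(pre, use.names = FALSE)
  tgt <- rep(seq_len(n_post), each = k_in)
  ord <- order(src)
  src_ptr <- c(0L, cumsum(tabulate(src[ord], nbins = n_pre)))
  structure(
    list(n_neurons = n_post, n_pre = n_pre, src_ptr = src_ptr,
         tgt = tgt[ord] - 1L,
         w = rep(J / (coupling_prob * n_pre), length(src)),
         in_degree = rep(k_in, n_post), topology = "random_sparse",
         coupling_prob = coupling_prob, J = J, seed = seed),
    class = "coupling_matrix"
  )
}

#' Population firing rate from a spike raster
#'
#' Bins spike counts and divides by `N * bin`, yielding the average rate in
#' spikes/ms per neuron together with a Hz-scaled copy.
#'
#' @param raster data.frame with columns `neuron` and `time` (ms), e.g. the
#'   `raster` field of an [run_snn()] result.
#' @param bin bin width (ms).
#' @param duration total duration (ms); taken from the raster attribute when
#'   missing.
#' @param n_neurons network size; taken from the raster attribute when
#'   missing.
#' @return data.frame with columns `time` (bin centers, ms), `r` (spikes/ms
#'   per neuron), and `r_hz`.
#' @export
population_rate <- function(raster, bin = 10, duration = NULL,
                            n_neurons = NULL) {
  stopifnot(bin > 0)
  if (is.null(duration)) duration <- attr(raster, "duration")
  if (is.null(n_neurons)) n_neurons <- attr(raster, "n_neurons")
  stopifnot(!is.null(duration), !is.null(n_neurons))
  breaks <- seq(0, duration, by = bin)
  if (breaks[length(breaks)] < duration) breaks <- c(breaks, duration)
  counts <- if (nrow(raster) == 0) {
    rep(0, length(breaks) - 1)
  } else {
    as.numeric(table(cut(raster$time, breaks, right = TRUE,
                         include.lowest = TRUE)))
  }
  widths <- diff(breaks)
  r <- counts / (n_neurons * widths)
  data.frame(time = (breaks[-length(breaks)] + breaks[-1]) / 2, r = r,
             r_hz = 1000 * r)
}

#' Gaussian-smoothed single-neuron firing rates
#'
#' Resamples each neuron's spike train onto a grid of `fs` samples per ms and
#' convolves it with a unit-area Gaussian kernel of standard deviation `sigma`
#' samples. One isolated spike therefore produces the kernel itself (unit
#' discrete integral); the result is in spikes per sample (multiply by `fs`
#' for spikes/ms).
#'
#' @param raster spike data.frame (`neuron`, `time`).
#' @param n_neurons network size (rows of the output).
#' @param fs sampling rate (samples per ms).
#' @param sigma kernel SD in samples.
#' @param t_start,t_end window (ms) covered by the output grid.
#' @return `n_neurons x T` matrix, `T = floor((t_end - t_start) * fs)`.
#' @export
smooth_rates <- function(raster, n_neurons, fs = 10, sigma = 200,
                         t_start = 0, t_end = NULL) {
  stopifnot(fs > 0, sigma > 0)
  if (is.null(t_end)) t_end <- attr(raster, "duration")
  if (is.null(n_neurons)) n_neurons <- attr(raster, "n_neurons")
  n_samp <- round((t_end - t_start) * fs)
  out <- matrix(0, n_neurons, n_samp)
  if (nrow(raster) == 0) return(out)
  half <- ceiling(6 * sigma)
  keep <- raster$time >= t_start - (half + 1) / fs &
    raster$time <= t_end + (half + 1) / fs
  rr <- raster[keep, , drop = FALSE]
  for (i in seq_len(nrow(rr))) {
    ps <- (rr$time[i] - t_start) * fs  # continuous sample position
    j0 <- max(0L, floor(ps - half))
    j1 <- min(n_samp - 1L, ceiling(ps + half))
    if (j0 > j1) next
    j <- j0:j1
    out[rr$neuron[i], j + 1L] <- out[rr$neuron[i], j + 1L] +
      stats::dnorm(j - ps, sd = sigma)
  }
  out
}

# Exact time-average of the Gaussian-smoothed rate over [t1, t2], per neuron,
# in spikes per sample: each spike contributes the kernel mass falling inside
# the window. Equivalent to averaging smooth_rates() columns but without
# materializing the N x T matrix.
window_mean_rates <- function(raster, n_neurons, t1, t2, fs = 10,
                              sigma = 200) {
  out <- numeric(n_neurons)
  if (nrow(raster) == 0) return(out)
  sig_ms <- sigma / fs
  keep <- raster$time >= t1 - 8 * sig_ms & raster$time <= t2 + 8 * sig_ms
  rr <- raster[keep, , drop = FALSE]
  if (nrow(rr) == 0) return(out)
  mass <- stats::pnorm(t2, mean = rr$time, sd = sig_ms) -
    stats::pnorm(t1, mean = rr$time, sd = sig_ms)
  acc <- tapply(mass, rr$neuron, sum)
  out[as.integer(names(acc))] <- as.numeric(acc)
  out / ((t2 - t1) * fs)
}
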