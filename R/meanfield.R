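# Mean-field equations for Izhikevich populations with Lorentzian
# spike-threshold disorder: derivatives, Euler integration, fixed points.

#' Mean-field derivative of one population
#'
#' Right-hand side of the four-dimensional mean-field system in state
#' `(r, v, u, s)` (rate in spikes/ms, mean voltage in mV, recovery in pA,
#' synaptic activation dimensionless):
#' \deqn{C \dot r = \Delta_v k^2 \sigma_v (v - v_r) / (\pi C)
#'       + r [ k (2 v - v_r - \bar v_\theta) - g s ]}
#' \deqn{C \dot v = k v (v - v_r - \bar v_\theta)
#'       - \pi C r (\Delta_v \sigma_v + \pi C r / k)
#'       + k v_r \bar v_\theta - u + I + g s (E - v) + \sum_m I_m}
#' \deqn{\tau_u \dot u = b (v - v_r) - u + \tau_u \kappa r}
#' \deqn{\tau_s \dot s = -s + \tau_s J r}
#' with \eqn{\sigma_v = \mathrm{sign}(v - v_r)}. Extra conductance-based
#' currents from afferent populations are supplied as
#' `list(list(g_s = g * s_m, E = E_m), ...)`; each contributes
#' `g_s * (E - v)` to the voltage equation and `-r * g_s` inside the bracket
#' of the rate equation (the population average of its `-g s v` part).
#'
#' @param state numeric vector `c(r, v, u, s)`.
#' @param params an [izh_params()] object.
#' @param delta_v heterogeneity half-width (mV); defaults to
#'   `params$delta_v`.
#' @param I input current (pA).
#' @param extra_currents list of afferent conductance currents (see above).
#' @return named numeric vector `c(r, v, u, s)` of time derivatives.
#' @export
#' @examples
#' rs <- izh_params("rs")
#' mf_derivative(c(0, rs$vr, 0, 0), rs, I = 0) # exactly zero
mf_derivative <- function(state, params, delta_v = NULL, I = 0,
                          extra_currents = list()) {
  validate_params(params)
  if (is.null(delta_v)) delta_v <- params$delta_v
  r <- state[[1]]; v <- state[[2]]; u <- state[[3]]; s <- state[[4]]
  Gs <- params$g * s
  GsE <- params$g * s * params$E
  for (ec in extra_currents) {
    Gs <- Gs + ec$g_s
    GsE <- GsE + ec$g_s * ec$E
  }
  sv <- sign(v - params$vr)
  C <- params$C; k <- params$k; vr <- params$vr; vth <- params$vtheta_bar
  dr <- (delta_v * k^2 * sv * (v - vr) / (pi * C) +
           r * (k * (2 * v - vr - vth) - Gs)) / C
  dv <- (k * v * (v - vr - vth) -
           pi * C * r * (delta_v * sv + pi * C * r / k) +
           k * vr * vth - u + I + GsE - Gs * v) / C
  du <- (params$b * (v - vr) - u) / params$tau_u + params$kappa * r
  ds <- -s / params$tau_s + params$J * r
  c(r = dr, v = dv, u = du, s = ds)
}

#' Define a coupled multi-population mean-field model
#'
#' @param populations list of lists with fields `params` (an [izh_params()]),
#'   optional `delta_v` (defaults to `params$delta_v`) and `stim` (a
#'   [stim_protocol()] or constant current, default 0).
#' @param synapses data.frame (or list of lists) with columns `pre`, `post`
#'   (1-based population indices), `J`, and optional `g`, `E`, `tau_s`
#'   defaulting to the presynaptic cell type's values. When `NULL`, each
#'   population gets its own recurrent synapse with its preset `J`.
#' @return An object of class `population_graph`.
#' @export
#' @examples
#' g <- population_graph(list(list(params = izh_params("rs"), stim = 60)))
population_graph <- function(populations, synapses = NULL) {
  stopifnot(length(populations) >= 1)
  pops <- lapply(populations, function(pp) {
    validate_params(pp$params)
    list(params = pp$params,
         delta_v = if (is.null(pp$delta_v)) pp$params$delta_v else pp$delta_v,
         stim = if (is.null(pp$stim)) stim_protocol(0)
                else if (is.numeric(pp$stim)) stim_protocol(pp$stim)
                else pp$stim)
  })
  if (is.null(synapses)) {
    synapses <- lapply(seq_along(pops), function(i) {
      list(pre = i, post = i, J = pops[[i]]$params$J)
    })
  }
  if (is.data.frame(synapses)) {
    synapses <- lapply(seq_len(nrow(synapses)), function(i) {
      as.list(synapses[i, , drop = FALSE])
    })
  }
  syns <- lapply(synapses, function(sy) {
    stopifnot(sy$pre >= 1, sy$pre <= length(pops),
              sy$post >= 1, sy$post <= length(pops))
    pp <- pops[[sy$pre]]$params
    list(pre = as.integer(sy$pre), post = as.integer(sy$post), J = sy$J,
         g = if (is.null(sy$g) || is.na(sy$g)) pp$g else sy$g,
         E = if (is.null(sy$E) || is.na(sy$E)) pp$E else sy$E,
         tau_s = if (is.null(sy$tau_s) || is.na(sy$tau_s)) pp$tau_s
                 else sy$tau_s)
  })
  structure(list(populations = pops, synapses = syns),
            class = "population_graph")
}

#' Integrate a mean-field population graph
#'
#' Explicit Euler integration of the coupled mean-field equations: each
#' population evolves its `(r, v, u)` triple; each synapse group carries one
#' activation `s` low-pass filtering the presynaptic rate with its own time
#' constant and coupling, and injects a conductance current `g s (E - v)`
#' into its target.
#'
#' @param graph a [population_graph()].
#' @param duration simulated time (ms).
#' @param dt Euler step (ms, default 0.01).
#' @param init optional list with matrices/vectors `r`, `v`, `u` (one entry
#'   per population) and `s` (one per synapse); defaults to the quiescent
#'   state `(0, vr, 0, 0)`.
#' @param record_dt trace resolution (ms).
#' @return list of class `mf_trajectory`: `time`, matrices `r`, `v`, `u`
#'   (columns = populations), `s` (columns = synapses), final state, and a
#'   tidy data.frame accessor via [as.data.frame()].
#' @export
run_meanfield_graph <- function(graph, duration, dt = 0.01, init = NULL,
                                record_dt = 0.1) {
  stopifnot(inherits(graph, "population_graph"), duration > 0, dt > 0)
  n_steps <- round(duration / dt)
  record_every <- max(1L, round(record_dt / dt))
  times <- (seq_len(n_steps) - 1) * dt
  P <- length(graph$populations)
  M <- length(graph$synapses)
  if (is.null(init)) {
    init <- list(r = rep(0, P),
                 v = vapply(graph$populations, function(p) p$params$vr, 1.0),
                 u = rep(0, P), s = rep(0, M))
  }
  pops <- lapply(seq_len(P), function(p) {
    pp <- graph$populations[[p]]
    list(C = pp$params$C, k = pp$params$k, vr = pp$params$vr,
         vtheta = pp$params$vtheta_bar, kappa = pp$params$kappa,
         b = pp$params$b, tau_u = pp$params$tau_u, delta = pp$delta_v,
         I = stim_current(pp$stim, times),
         r0 = init$r[p], v0 = init$v[p], u0 = init$u[p])
  })
  syns <- lapply(seq_len(M), function(m) {
    sy <- graph$synapses[[m]]
    list(pre = sy$pre - 1L, post = sy$post - 1L, J = sy$J, g = sy$g,
         E = sy$E, tau_s = sy$tau_s, s0 = init$s[m])
  })
  raw <- mf_sim_cpp(pops, syns, dt, n_steps, record_every)
  structure(
    list(time = raw$time, r = raw$r, v = raw$v, u = raw$u, s = raw$s,
         state_final = list(r = raw$r_final, v = raw$v_final,
                            u = raw$u_final, s = raw$s_final),
         duration = duration, dt = dt, record_dt = record_dt, graph = graph),
    class = "mf_trajectory"
  )
}

#' @export
as.data.frame.mf_trajectory <- function(x, ...) {
  P <- ncol(x$r)
  do.call(rbind, lapply(seq_len(P), function(p) {
    data.frame(time = x$time, population = p, r = x$r[, p],
               r_hz = 1000 * x$r[, p], v = x$v[, p], u = x$u[, p])
  }))
}

#' Integrate a single mean-field population
#'
#' Convenience wrapper around [run_meanfield_graph()] for one population with
#' its own recurrent synapse.
#'
#' @param params an [izh_params()] object.
#' @param delta_v heterogeneity half-width (mV); default `params$delta_v`.
#' @param stim a [stim_protocol()] or a constant current (pA).
#' @param duration simulated time (ms).
#' @param dt Euler step (ms).
#' @param init optional `c(r, v, u, s)` initial state.
#' @param record_dt trace resolution (ms).
#' @return An `mf_trajectory` whose `r`, `v`, `u`, `s` matrices have one
#'   column.
#' @export
#' @examples
#' tr <- run_meanfield(izh_params("rs"), stim = 60, duration = 500)
run_meanfield <- function(params, delta_v = NULL, stim = 0, duration = 1000,
                          dt = 0.01, init = NULL, record_dt = 0.1) {
  graph <- population_graph(list(list(params = params, delta_v = delta_v,
                                      stim = stim)))
  if (!is.null(init)) {
    stopifnot(length(init) == 4)
    init <- list(r = init[[1]], v = init[[2]], u = init[[3]], s = init[[4]])
  }
  run_meanfield_graph(graph, duration, dt, init, record_dt)
}

# Scales used to adimensionalize the residual norm of the fixed-point solver:
# 0.01 spikes/ms (10 Hz), 10 mV, 10 pA, 0.1 activation.
mf_state_scale <- c(r = 0.01, v = 10, u = 10, s = 0.1)

#' Locate a mean-field fixed point by damped Newton iteration
#'
#' Solves for a stationary state of the single-population mean-field
#' equations, starting from `guess`, and reports local stability through the
#' eigenvalues of the numerically evaluated Jacobian.
#'
#' @param params an [izh_params()] object.
#' @param delta_v heterogeneity half-width (mV).
#' @param I constant input current (pA).
#' @param guess numeric `c(r, v, u, s)` starting point.
#' @param tol convergence tolerance on the scaled derivative norm
#'   (default 1e-10; the residual is divided component-wise by
#'   10 Hz / 10 mV / 10 pA / 0.1 to make it dimensionless).
#' @param max_iter maximum Newton iterations.
#' @return list with `state` (named vector), `eigenvalues`, `stable`
#'   (all real parts negative), `residual`, `iterations`.
#' @export
#' @examples
#' fp <- find_fixed_point(izh_params("rs"), I = 0, guess = c(0, -60, 0, 0))
find_fixed_point <- function(params, delta_v = NULL, I = 0,
                             guess = c(0, params$vr, 0, 0), tol = 1e-10,
                             max_iter = 100) {
  validate_params(params)
  if (is.null(delta_v)) delta_v <- params$delta_v
  f <- function(x) unname(mf_derivative(x, params, delta_v, I))
  fs <- function(x) f(x) / mf_state_scale
  x <- as.numeric(guess)
  res <- sqrt(sum(fs(x)^2))
  it <- 0
  while (res > tol && it < max_iter) {
    Jm <- pracma::jacobian(fs, x)
    step <- tryCatch(solve(Jm, -fs(x)), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) {
      stop("fixed-point search failed: singular Jacobian at iteration ", it)
    }
    lambda <- 1
    repeat {
      x_new <- x + lambda * step
      res_new <- sqrt(sum(fs(x_new)^2))
      if (is.finite(res_new) && res_new < res) break
      lambda <- lambda / 2
      if (lambda < 1e-10) {
        stop("fixed-point search did not converge: damped step stalled ",
             "(residual ", signif(res, 3), ")")
      }
    }
    x <- x_new
    res <- res_new
    it <- it + 1
  }
  if (res > tol) {
    stop("fixed-point search did not converge in ", max_iter,
         " iterations (residual ", signif(res, 3), ")")
  }
  Jm <- pracma::jacobian(f, x)
  ev <- eigen(Jm, only.values = TRUE)$values
  list(state = c(r = x[1], v = x[2], u = x[3], s = x[4]),
       eigenvalues = ev, stable = all(Re(ev) < 0), residual = res,
       iterations = it)
}

# Steady-state-consistent excited initial condition used when probing for a
# high-activity attractor: quasi-stationary u and s at the requested rate.
excited_init <- function(params, r = 0.05, v = NULL) {
  if (is.null(v)) v <- params$vtheta_bar
  c(r = r, v = v,
    u = params$b * (v - params$vr) + params$tau_u * params$kappa * r,
    s = params$tau_s * params$J * r)
}
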