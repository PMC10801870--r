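# Network connectivity: all-to-all, random sparse, and ring networks with a
# power-law distance kernel.

#' Specify network connectivity
#'
#' @param n_neurons number of neurons `N >= 2`.
#' @param topology `"all_to_all"`, `"random_sparse"`, or `"ring_power_law"`.
#' @param coupling_prob coupling probability `p` in `(0, 1]`; every neuron
#'   receives exactly `floor(p * N)` synapses for the sparse topologies.
#'   Forced to 1 for `all_to_all`.
#' @param ring_exponent distance exponent `d >= 0` of the ring kernel
#'   `rho(x, y) = c * |x - y|^-d` (circular distance); only used by
#'   `ring_power_law`.
#' @param allow_self allow self-connections (all-to-all only; the spatial
#'   kernel is undefined at zero distance).
#' @param seed integer seed for the random wiring.
#' @return An object of class `connectivity_spec`.
#' @export
connectivity_spec <- function(n_neurons,
                              topology = c("random_sparse", "all_to_all",
                                           "ring_power_law"),
                              coupling_prob = 0.2, ring_exponent = 0,
                              allow_self = FALSE, seed = 1L) {
  topology <- match.arg(topology)
  stopifnot(is.numeric(n_neurons), n_neurons >= 2,
            is.numeric(coupling_prob), coupling_prob > 0, coupling_prob <= 1,
            is.numeric(ring_exponent), ring_exponent >= 0)
  if (topology == "all_to_all") coupling_prob <- 1
  structure(
    list(n_neurons = as.integer(n_neurons), topology = topology,
         coupling_prob = coupling_prob, ring_exponent = ring_exponent,
         allow_self = isTRUE(allow_self), seed = as.integer(seed)),
    class = "connectivity_spec"
  )
}

# Circular distances from target x (1-based) to all neurons on a ring of size N.
ring_distance <- function(x, N) {
  d <- abs(seq_len(N) - x)
  pmin(d, N - d)
}

# Sampling probabilities for presynaptic partners of target x under the
# power-law ring kernel (self excluded).
ring_probs <- function(x, N, d) {
  dist <- ring_distance(x, N)
  w <- ifelse(dist == 0, 0, dist^(-d))
  w / sum(w)
}

#' Build a coupling matrix
#'
#' Every neuron receives `floor(p * N)` presynaptic partners drawn without
#' replacement (uniformly for `random_sparse`; with probability proportional
#' to circular distance to the power `-d` for `ring_power_law`), each with
#' weight `J / (p * N)` so that the total recurrent drive matches the
#' mean-field coupling `J`. `all_to_all` yields the uniform weight `J / N`.
#'
#' @param spec a [connectivity_spec()].
#' @param J total recurrent coupling strength (dimensionless).
#' @return An object of class `coupling_matrix` holding a source-major edge
#'   list (`src_ptr`, `tgt`, `w`), the per-neuron in-degree, and the build
#'   parameters. Use [as.matrix()] to materialize the dense `N x N` weight
#'   matrix (rows = targets, columns = sources).
#' @export
#' @examples
#' cm <- build_connectivity(connectivity_spec(10, "random_sparse", 0.5), J = 15)
#' cm$in_degree
build_connectivity <- function(spec, J) {
  stopifnot(inherits(spec, "connectivity_spec"), is.numeric(J), length(J) == 1)
  N <- spec$n_neurons
  k_in <- if (spec$topology == "all_to_all") {
    if (spec$allow_self) N else N - 1
  } else {
    floor(spec$coupling_prob * N)
  }
  if (floor(spec$coupling_prob * N) < 1) {
    stop("coupling_prob * N < 1: every neuron needs at least one input")
  }
  w_per_edge <- J / (spec$coupling_prob * N)

  # pre[[i]] = presynaptic partners of target i
  pre <- with_seed(spec$seed, {
    switch(spec$topology,
      all_to_all = lapply(seq_len(N), function(i) {
        if (spec$allow_self) seq_len(N) else setdiff(seq_len(N), i)
      }),
      random_sparse = lapply(seq_len(N), function(i) {
        cand <- if (spec$allow_self) seq_len(N) else setdiff(seq_len(N), i)
        sample(cand, k_in)
      }),
      # with replacement: sequential weighted draws without replacement would
      # exhaust the local pool (k_in is a fifth of the ring) and flatten the
      # distance kernel by an order of magnitude; repeated draws simply stack
      # as multi-edges of equal strength, preserving the kernel exactly
      ring_power_law = lapply(seq_len(N), function(i) {
        p <- ring_probs(i, N, spec$ring_exponent)
        sample.int(N, k_in, prob = p, replace = TRUE)
      })
    )
  })

  # convert to source-major compressed form for the simulator
  src_of_edge <- unlist(pre, use.names = FALSE)
  tgt_of_edge <- rep(seq_len(N), vapply(pre, length, 1L))
  ord <- order(src_of_edge)
  src_sorted <- src_of_edge[ord]
  tgt_sorted <- tgt_of_edge[ord]
  src_ptr <- c(0L, cumsum(tabulate(src_sorted, nbins = N)))

  structure(
    list(n_neurons = N, src_ptr = src_ptr, tgt = tgt_sorted - 1L,
         w = rep(w_per_edge, length(tgt_sorted)),
         in_degree = vapply(pre, length, 1L),
         topology = spec$topology, coupling_prob = spec$coupling_prob,
         ring_exponent = spec$ring_exponent, J = J, seed = spec$seed),
    class = "coupling_matrix"
  )
}

#' @export
as.matrix.coupling_matrix <- function(x, ...) {
  N <- x$n_neurons
  W <- matrix(0, N, N)
  for (j in seq_len(N)) {
    idx <- if (x$src_ptr[j] < x$src_ptr[j + 1]) {
      (x$src_ptr[j] + 1):x$src_ptr[j + 1]
    } else {
      integer(0)
    }
    W[x$tgt[idx] + 1L, j] <- x$w[idx]
  }
  W
}

#' @export
print.coupling_matrix <- function(x, ...) {
  cat(sprintf("coupling_matrix: N=%d, topology=%s, p=%.3g, in-degree=%d, weight=%.4g\n",
              x$n_neurons, x$topology, x$coupling_prob, x$in_degree[1],
              if (length(x$w)) x$w[1] else NA_real_))
  invisible(x)
}
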