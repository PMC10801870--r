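# Shared miniature fixtures for fast tests.

rs_params <- izh_params("rs")
fs_params <- izh_params("fs")
lts_params <- izh_params("lts")

# small sparse RS network (N = 50) reused across SNN tests
tiny_net <- function(n = 50, delta_v = 0.5, seed = 1, topology = "random_sparse",
                     params = rs_params, ring_exponent = 0) {
  spec <- disorder_for(params, width = delta_v, seed = seed)
  list(
    thresholds = sample_thresholds(spec, n),
    coupling = build_connectivity(
      connectivity_spec(n, topology, 0.2, ring_exponent, seed = seed + 1),
      J = params$J)
  )
}

# deterministic toy response matrices for readout tests
toy_X <- function(n, t, seed = 1) {
  with_seed <- getFromNamespace("with_seed", "hetspike")
  with_seed(seed, matrix(stats::rnorm(n * t), n, t))
}
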