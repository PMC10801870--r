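# Configuration files, fixtures, experiment runner, and the command-line
# entry point.

config_schemas <- list(
  snn = c("type", "cell_type", "kappa", "delta_v", "family", "n_neurons",
          "topology", "coupling_prob", "ring_exponent", "duration",
          "baseline", "stim_on", "stim_off", "stim_amplitude", "seed"),
  meanfield = c("type", "cell_type", "kappa", "delta_v", "duration",
                "baseline", "stim_on", "stim_off", "stim_amplitude", "seed"),
  regime_map = c("type", "cell_type", "kappa", "input_grid", "delta_grid",
                 "settle_time", "measure_time", "seed"),
  bump = c("type", "cell_type", "kappa", "delta_grid", "p_in_grid",
           "n_neurons", "duration", "stim_on", "stim_off", "I_base",
           "I_stim", "ring_exponent", "coupling_prob", "test_window",
           "seeds", "seed"),
  reservoir = c("type", "cell_type", "kappa", "delta_grid", "regime_inputs",
                "n_neurons", "n_onsets", "n_train", "n_test", "burn_in",
                "post_onset", "ring_exponent", "coupling_prob", "seeds",
                "seed"),
  entrain = c("type", "cell_type", "kappa", "delta_grid", "omega_grid",
              "alpha", "I0", "duration", "discard", "seed")
)

config_defaults <- list(
  cell_type = "rs", kappa = NULL, delta_v = 0.5, family = "lorentzian",
  seed = 1L
)

#' Load and validate an experiment configuration
#'
#' Reads a YAML (or JSON) experiment description, rejects unknown keys,
#' applies defaults, and range-checks the common fields. The mandatory `type`
#' field selects the experiment: `snn`, `meanfield`, `regime_map`, `bump`,
#' `reservoir`, or `entrain`.
#'
#' @param path path to a YAML or JSON file.
#' @return validated configuration list (class `hetspike_config`).
#' @export
load_config <- function(path) {
  stopifnot(file.exists(path))
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  validate_config(cfg)
}

#' @rdname load_config
#' @param cfg a configuration list.
#' @export
validate_config <- function(cfg) {
  if (is.null(cfg$type) || !cfg$type %in% names(config_schemas)) {
    stop("config must carry a 'type' field, one of: ",
         paste(names(config_schemas), collapse = ", "))
  }
  allowed <- config_schemas[[cfg$type]]
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown)) {
    stop("unknown config keys for type '", cfg$type, "': ",
         paste(unknown, collapse = ", "))
  }
  for (key in setdiff(names(config_defaults), names(cfg))) {
    if (key %in% allowed) cfg[[key]] <- config_defaults[[key]]
  }
  if (!is.null(cfg$cell_type) &&
      !cfg$cell_type %in% c("rs", "fs", "lts")) {
    stop("invalid cell_type: ", cfg$cell_type)
  }
  for (key in c("coupling_prob", "p_in_grid")) {
    if (!is.null(cfg[[key]]) &&
        (any(cfg[[key]] <= 0) || any(cfg[[key]] > 1))) {
      stop(key, " must lie in (0, 1]")
    }
  }
  if (!is.null(cfg$delta_v) && any(cfg$delta_v < 0)) {
    stop("delta_v must be non-negative")
  }
  structure(cfg, class = c("hetspike_config", "list"))
}

#' Save a configuration to YAML
#'
#' @param cfg configuration list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Ready-to-run miniature experiment configurations
#'
#' Small configurations (N <= 200, duration <= 1000 ms) exercising each
#' pipeline quickly: `tiny_rs` (single sparse regular-spiking network with a
#' step input), `tiny_ring` (bump protocol on a small ring), `tiny_two_pop`
#' (coupled regular-spiking / fast-spiking mean-field model),
#' `tiny_regime_map`, `tiny_reservoir`, `tiny_entrain`.
#'
#' @param kind fixture name.
#' @param seed integer seed.
#' @return a validated configuration list.
#' @export
make_fixture <- function(kind = c("tiny_rs", "tiny_ring", "tiny_two_pop",
                                  "tiny_regime_map", "tiny_reservoir",
                                  "tiny_entrain"),
                         seed = 1L) {
  kind <- match.arg(kind)
  cfg <- switch(kind,
    tiny_rs = list(type = "snn", cell_type = "rs", delta_v = 0.5,
                   n_neurons = 100L, topology = "random_sparse",
                   coupling_prob = 0.2, duration = 500,
                   baseline = 30, stim_on = 100, stim_off = 300,
                   stim_amplitude = 30, seed = seed),
    tiny_ring = list(type = "bump", cell_type = "rs", delta_grid = 0.5,
                     p_in_grid = 0.25, n_neurons = 200L, duration = 800,
                     stim_on = 100, stim_off = 300, I_base = 30, I_stim = 60,
                     ring_exponent = 1.5, coupling_prob = 0.2,
                     test_window = 100, seeds = 1L, seed = seed),
    tiny_two_pop = list(type = "meanfield", cell_type = "rs", delta_v = 0.5,
                        duration = 1000, baseline = 30, stim_on = 300,
                        stim_off = 600, stim_amplitude = 30, seed = seed),
    tiny_regime_map = list(type = "regime_map", cell_type = "rs",
                           input_grid = c(30, 60), delta_grid = c(0.2, 1.5),
                           settle_time = 300, measure_time = 300,
                           seed = seed),
    tiny_reservoir = list(type = "reservoir", cell_type = "rs", kappa = 100,
                          delta_grid = 0.5, regime_inputs = 45,
                          n_neurons = 150L, n_onsets = 5L, n_train = 4L,
                          n_test = 1L, burn_in = 300, post_onset = 150,
                          ring_exponent = 0.75, coupling_prob = 0.2,
                          seeds = 1L, seed = seed),
    tiny_entrain = list(type = "entrain", cell_type = "rs", kappa = 100,
                        delta_grid = 0.5, omega_grid = c(4, 8), alpha = 4,
                        I0 = 55, duration = 1200, discard = 400, seed = seed)
  )
  validate_config(cfg)
}

config_params <- function(cfg) {
  izh_params(cfg$cell_type,
             kappa = if (is.null(cfg$kappa)) NULL else cfg$kappa)
}

config_stim <- function(cfg) {
  segs <- list()
  if (!is.null(cfg$stim_on)) {
    segs <- list(stim_segment(cfg$stim_on, cfg$stim_off, cfg$stim_amplitude))
  }
  stim_protocol(cfg$baseline %||% 0, segs)
}

#' Run an experiment configuration
#'
#' Dispatches on `cfg$type`, writes the experiment's CSV outputs into
#' `out_dir`, and emits a `manifest.json` recording the configuration, seeds,
#' package version, wall time, and an MD5 inventory of all written files.
#'
#' @param cfg a configuration list (validated with [validate_config()]).
#' @param out_dir output directory (created if absent).
#' @param seed overrides `cfg$seed` when non-`NULL`.
#' @return (invisibly) the manifest list.
#' @export
run_config <- function(cfg, out_dir, seed = NULL) {
  cfg <- validate_config(cfg)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  params <- config_params(cfg)
  files <- character(0)
  put <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
  }

  if (cfg$type == "snn") {
    spec <- disorder_for(params, family = cfg$family, width = cfg$delta_v,
                         seed = derive_seed(cfg$seed, 1))
    thr <- sample_thresholds(spec, cfg$n_neurons)
    cm <- build_connectivity(
      connectivity_spec(cfg$n_neurons, cfg$topology, cfg$coupling_prob,
                        cfg$ring_exponent %||% 0,
                        seed = derive_seed(cfg$seed, 2)),
      J = params$J)
    out <- run_snn(params, thr, cm, config_stim(cfg), cfg$duration)
    put(out$raster, "raster.csv")
    put(out$rate, "rate.csv")
  } else if (cfg$type == "meanfield") {
    tr <- run_meanfield(params, cfg$delta_v, config_stim(cfg), cfg$duration)
    put(as.data.frame(tr), "trajectory.csv")
  } else if (cfg$type == "regime_map") {
    config <- bif_detect_config(settle_time = cfg$settle_time %||% 1000,
                                measure_time = cfg$measure_time %||% 1000)
    map <- map_regimes(params, cfg$input_grid, cfg$delta_grid, config)
    put(map$cells, "regime_map.csv")
    put(map$boundaries, "boundaries.csv")
  } else if (cfg$type == "bump") {
    proto <- bump_protocol(n_neurons = cfg$n_neurons,
                           coupling_prob = cfg$coupling_prob %||% 0.2,
                           ring_exponent = cfg$ring_exponent %||% 1.5,
                           I_base = cfg$I_base %||% 30,
                           I_stim = cfg$I_stim %||% 60,
                           stim_on = cfg$stim_on, stim_off = cfg$stim_off,
                           duration = cfg$duration,
                           test_window = cfg$test_window %||% 200)
    sweep <- bump_sweep(params, proto, cfg$p_in_grid, cfg$delta_grid,
                        seeds = cfg$seeds %||% 1L)
    put(sweep, "bump_sweep.csv")
  } else if (cfg$type == "reservoir") {
    proto <- onset_protocol(n_onsets = cfg$n_onsets, n_train = cfg$n_train,
                            n_test = cfg$n_test, burn_in = cfg$burn_in,
                            post_onset = cfg$post_onset,
                            n_neurons = cfg$n_neurons,
                            coupling_prob = cfg$coupling_prob %||% 0.2,
                            ring_exponent = cfg$ring_exponent %||% 0.75)
    sweep <- function_generation_sweep(params, cfg$regime_inputs,
                                       cfg$delta_grid, proto,
                                       seeds = cfg$seeds %||% 1L)
    put(sweep, "reservoir_sweep.csv")
  } else if (cfg$type == "entrain") {
    map <- entrainment_map(params, cfg$omega_grid, delta_grid = cfg$delta_grid,
                           alpha = cfg$alpha %||% 4, I0 = cfg$I0 %||% 55,
                           duration = cfg$duration %||% 4000,
                           discard = cfg$discard %||% 1000)
    put(map, "entrainment_map.csv")
  }

  manifest <- list(
    config = unclass(cfg), seed = cfg$seed,
    package_version = as.character(utils::packageVersion("hetspike")),
    elapsed_s = proc.time()[["elapsed"]] - t0,
    files = lapply(files, function(f) {
      list(name = basename(f), md5 = unname(tools::md5sum(f)))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Command-line entry point
#'
#' Thin dispatcher used by the `inst/cli/hetspike.R` script:
#' `hetspike.R <subcommand> --config <file> [--seed <int>] --out-dir <dir>`
#' with subcommands `simulate-snn`, `simulate-mf`, `regime-map`, `bump`,
#' `reservoir`, `entrain` (each requiring a config of the matching type), or
#' `fixture <kind>` to write a ready-made miniature config.
#'
#' @param args character vector of command-line arguments.
#' @return exit status (0 on success), invisibly.
#' @export
hetspike_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: hetspike.R <simulate-snn|simulate-mf|regime-map|bump|reservoir|",
    "entrain> --config <file> [--seed <int>] --out-dir <dir>\n",
    "       hetspike.R fixture <kind> --out-dir <dir>")
  if (!length(args)) {
    message(usage)
    return(invisible(1L))
  }
  sub <- args[1]
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) && i < length(args)) args[i + 1] else default
  }
  out_dir <- opt("--out-dir", ".")
  if (sub == "fixture") {
    cfg <- make_fixture(args[2], seed = as.integer(opt("--seed", "1")))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    save_config(cfg, file.path(out_dir, paste0(args[2], ".yaml")))
    return(invisible(0L))
  }
  type_of <- c("simulate-snn" = "snn", "simulate-mf" = "meanfield",
               "regime-map" = "regime_map", "bump" = "bump",
               "reservoir" = "reservoir", "entrain" = "entrain")
  if (!sub %in% names(type_of)) {
    message("unknown subcommand: ", sub, "\n", usage)
    return(invisible(1L))
  }
  cfg <- load_config(opt("--config"))
  if (cfg$type != type_of[[sub]]) {
    stop("config type '", cfg$type, "' does not match subcommand '", sub, "'")
  }
  seed <- opt("--seed")
  run_config(cfg, out_dir, seed = if (is.null(seed)) NULL
                                  else as.integer(seed))
  invisible(0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
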