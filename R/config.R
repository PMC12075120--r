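#' Default run configuration
#'
#' A run configuration is a nested list controlling every knob of a
#' simulation; it round-trips losslessly through YAML ([load_config()],
#' [save_config()]). Defaults mirror the published model: 5,000 neurons,
#' global coupling `G = 5`, dt = 0.05 ms, receptor conductances 1 nS, the
#' 30 pA / 50% layer-4 feedforward stimulus convention, and the published
#' STDP constants. All four seed streams (wiring, background, stimulus
#' subset, plasticity/shuffle) are explicit so controls can vary one factor
#' at a time.
#'
#' @param n_total,G,dt,duration convenience overrides of the most common
#'   fields.
#' @param seed master seed: the four seed streams default to `seed`,
#'   `seed + 1`, `seed + 2`, `seed + 3`.
#' @return A nested configuration list of class `col_config`.
#' @export
default_config <- function(n_total = 5000, G = 5, dt = 0.05, duration = 1500,
                           seed = 1) {
  structure(list(
    network = list(
      n_total = n_total, G = G,
      matrices = "synthetic", style = "inhibition_dominated",
      path_P = NULL, path_S = NULL),
    dynamics = list(
      dt = dt, duration = duration,
      g_AMPA = 1, g_NMDA = 1, g_GABA = 1, Mg = 1,
      gaba_reversal = "postsynaptic"),
    stimulus = list(epochs = NULL),
    plasticity = list(
      enabled = FALSE, inh_enabled = FALSE,
      A_plus = 0.02, A_minus = 0.021, tau_plus = 20, tau_minus = 20,
      w_min = 0, w_max = 0.2,
      B_plus = 0.04, B_minus = 0.02, inh_tau_plus = 10, inh_tau_minus = 20),
    analysis = list(rate_window = 200, psd_rate_window = 5,
                    psd_segment_ms = 2000, band = c(5, 100)),
    seeds = list(wiring = seed, background = seed + 1, stimulus = seed + 2,
                 plasticity = seed + 3),
    output = list(record_V_every = 1)
  ), class = "col_config")
}

config_stdp <- function(config) {
  p <- config$plasticity
  stdp_config(A_plus = p$A_plus, A_minus = p$A_minus, tau_plus = p$tau_plus,
              tau_minus = p$tau_minus, w_min = p$w_min, w_max = p$w_max)
}

config_inh_stdp <- function(config) {
  p <- config$plasticity
  inh_stdp_config(B_plus = p$B_plus, B_minus = p$B_minus,
                  tau_plus = p$inh_tau_plus, tau_minus = p$inh_tau_minus,
                  w_min = p$w_min, w_max = p$w_max)
}

config_protocol <- function(config) {
  ep <- config$stimulus$epochs
  if (is.null(ep) || (is.data.frame(ep) && nrow(ep) == 0)) return(NULL)
  if (!is.data.frame(ep)) ep <- do.call(rbind, lapply(ep, as.data.frame))
  stimulus_protocol(ep, seed = config$seeds$stimulus)
}

#' Read or write a run configuration
#'
#' `load_config()` reads a YAML file, validates it and fills every missing
#' field with the [default_config()] value, so an empty file yields the full
#' default configuration and `save(load(x))` is a fixed point.
#'
#' @param path YAML file path.
#' @param config a configuration list.
#' @return `load_config()` returns the resolved `col_config`.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  cfg <- modify_defaults(unclass(default_config()), raw)
  class(cfg) <- "col_config"
  validate_config(cfg)
  cfg
}

#' @rdname load_config
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

modify_defaults <- function(defaults, values) {
  for (nm in names(values)) {
    if (is.null(values[[nm]])) next   # explicit nulls keep the default
    if (is.list(defaults[[nm]]) && is.list(values[[nm]]) &&
        !is.null(names(defaults[[nm]]))) {
      defaults[[nm]] <- modify_defaults(defaults[[nm]], values[[nm]])
    } else {
      defaults[[nm]] <- values[[nm]]
    }
  }
  defaults
}

validate_config <- function(cfg) {
  fail <- function(path, msg) {
    stop("config field '", path, "': ", msg, call. = FALSE)
  }
  if (!is.numeric(cfg$network$n_total) || cfg$network$n_total < 17) {
    fail("network.n_total", "must be numeric >= 17")
  }
  if (!is.numeric(cfg$network$G) || cfg$network$G < 0) {
    fail("network.G", "must be numeric >= 0")
  }
  if (!cfg$network$matrices %in% c("synthetic", "files")) {
    fail("network.matrices", "must be 'synthetic' or 'files'")
  }
  if (cfg$network$matrices == "files" &&
      (is.null(cfg$network$path_P) || is.null(cfg$network$path_S))) {
    fail("network.path_P/path_S", "required when matrices = 'files'")
  }
  if (!is.numeric(cfg$dynamics$dt) || cfg$dynamics$dt <= 0) {
    fail("dynamics.dt", "must be a positive number")
  }
  if (cfg$dynamics$dt > 0.1) {
    fail("dynamics.dt", "exceeds the 0.1 ms stability guard")
  }
  if (!cfg$dynamics$gaba_reversal %in% c("postsynaptic", "presynaptic")) {
    fail("dynamics.gaba_reversal", "must be 'postsynaptic' or 'presynaptic'")
  }
  for (s in c("wiring", "background", "stimulus", "plasticity")) {
    if (!is.numeric(cfg$seeds[[s]])) fail(paste0("seeds.", s), "must be numeric")
  }
  invisible(cfg)
}

#' Write a run manifest
#'
#' Records everything needed to re-run an experiment bit-identically: the
#' resolved configuration (embedded and hashed), the seed streams, the package
#' version, and MD5 checksums of the run's output files.
#'
#' @param result a `col_experiment`.
#' @param dir output directory (created if missing); the experiment's spike
#'   record and final synapse table are written there as CSV alongside
#'   `manifest.yaml`.
#' @return The manifest path, invisibly.
#' @export
write_run_manifest <- function(result, dir) {
  stopifnot(inherits(result, "col_experiment"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  spikes_path <- file.path(dir, "spikes.csv")
  syn_path <- file.path(dir, "synapses.csv")
  data.table::fwrite(result$sim$spikes, spikes_path)
  write_synapse_table(result$sim$synapses, syn_path)
  cfg_tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(cfg_tmp))
  save_config(result$config, cfg_tmp)
  manifest <- list(
    type = result$type,
    package_version = as.character(utils::packageVersion("colrhythm")),
    config = unclass(result$config),
    config_md5 = unname(tools::md5sum(cfg_tmp)),
    seeds = result$config$seeds,
    files = list(
      spikes = list(path = basename(spikes_path),
                    md5 = unname(tools::md5sum(spikes_path))),
      synapses = list(path = basename(syn_path),
                      md5 = unname(tools::md5sum(syn_path))))
  )
  manifest_path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, manifest_path)
  invisible(manifest_path)
}

#' Verify a run directory against its manifest
#'
#' @param dir a directory written by [write_run_manifest()].
#' @return `TRUE` if all checksums match; otherwise an error naming the
#'   mismatched file.
#' @export
verify_run_manifest <- function(dir) {
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  for (f in manifest$files) {
    actual <- unname(tools::md5sum(file.path(dir, f$path)))
    if (!identical(actual, f$md5)) {
      stop("checksum mismatch for ", f$path, call. = FALSE)
    }
  }
  TRUE
}
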