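#' Packaged parameter tables for the V1 column
#'
#' The model's published constants are shipped as plain-text fixtures and
#' exposed through these loaders:
#' \describe{
#'   \item{`default_layer_fractions()`}{fraction of `n_total` in each layer.
#'     Note: the L6 fraction is 0.2972, back-derived from the published cell
#'     census at n_total = 5,000 (1,486 L6 neurons); the independently printed
#'     per-layer fraction for L6 is inconsistent with that census by one
#'     neuron and the census was taken as authoritative.}
#'   \item{`default_inh_fractions()`}{per full layer, the fraction of the
#'     layer's inhibitory pool (15% of the layer) belonging to PV, SST, VIP.}
#'   \item{`default_membrane_params()`}{per group: capacitance `C_m` (pF),
#'     leak conductance `g_L` (nS), refractory period `tau_ref` (ms), resting
#'     potential `V_rest` (mV) and spike threshold `V_th` (mV).}
#'   \item{`default_background_rates()`}{per group: rate (Hz) of the
#'     independent background Poisson generator each neuron receives.}
#' }
#'
#' @return A data.frame (see Details).
#' @name default_parameters
NULL

read_fixture <- function(name) {
  path <- system.file("extdata", name, package = "colrhythm", mustWork = TRUE)
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' @rdname default_parameters
#' @export
default_layer_fractions <- function() read_fixture("layer_fractions.csv")

#' @rdname default_parameters
#' @export
default_inh_fractions <- function() read_fixture("inh_fractions.csv")

#' @rdname default_parameters
#' @export
default_membrane_params <- function() {
  mp <- read_fixture("membrane_params.csv")
  validate_membrane_params(mp)
  mp
}

#' @rdname default_parameters
#' @export
default_background_rates <- function() read_fixture("background_rates.csv")

validate_membrane_params <- function(mp) {
  stopifnot(setequal(mp$group, group_labels()))
  if (any(mp$C_m <= 0) || any(mp$g_L <= 0) || any(mp$tau_ref < 0)) {
    stop("membrane parameters out of range: C_m, g_L must be > 0, tau_ref >= 0",
         call. = FALSE)
  }
  if (any(mp$V_th <= mp$V_rest)) {
    stop("spike threshold must exceed resting potential for every group",
         call. = FALSE)
  }
  invisible(mp)
}

#' Receptor kinetics and coupling constants
#'
#' Fixed synaptic constants: AMPA and GABA-A gating decay times (2 and 5 ms),
#' NMDA decay/rise times (80 and 2 ms), the NMDA saturation rate `alpha`
#' (0.5 per ms), extracellular magnesium concentration (1 mM), excitatory
#' reversal potential (0 mV), the external-synapse weight `w_ext` (1), and the
#' receptor conductances. The receptor conductances are not published; they
#' default to 1 nS each and are exposed for configuration (their scale is
#' absorbed into the connectivity strengths).
#'
#' @param g_AMPA,g_NMDA,g_GABA receptor conductances (nS).
#' @param Mg extracellular magnesium concentration (mM).
#' @return A named list of synaptic constants.
#' @export
synapse_constants <- function(g_AMPA = 1, g_NMDA = 1, g_GABA = 1, Mg = 1) {
  stopifnot(g_AMPA >= 0, g_NMDA >= 0, g_GABA >= 0, Mg >= 0)
  list(
    tau_AMPA = 2, tau_GABA = 5,
    tau_NMDA_decay = 80, tau_NMDA_rise = 2,
    alpha = 0.5, Mg = Mg,
    V_E = 0,
    g_AMPA = g_AMPA, g_NMDA = g_NMDA, g_GABA = g_GABA,
    w_ext = 1
  )
}
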