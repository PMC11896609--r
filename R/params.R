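#' Membrane and action-potential parameters for an antennal-lobe cell class
#'
#' Single-compartment leaky integrate-and-fire parameters. Defaults for the
#' three antennal-lobe classes come from published electrophysiology: ORNs,
#' LNs and PNs differ in resting potential, threshold, action-potential
#' envelope and passive membrane properties.
#'
#' Units: potentials in mV, durations in ms, capacitance in pF, resistance in
#' GOhm. With these units the membrane time constant R*C is in ms and
#' current in pA enters the voltage update without conversion factors.
#'
#' @param V_0 resting potential (mV).
#' @param V_thr spike threshold (mV); must exceed `V_0`.
#' @param ap_min action-potential minimum, the post-spike reset voltage (mV).
#' @param ap_max action-potential peak (mV).
#' @param ap_duration action-potential template duration (ms).
#' @param C membrane capacitance (pF).
#' @param R membrane resistance (GOhm).
#' @return A `cell_class_params` list.
#' @export
cell_class_params <- function(V_0, V_thr, ap_min, ap_max, ap_duration, C, R) {
  stopifnot(ap_min <= V_0, V_0 < V_thr, V_thr < ap_max, C > 0, R > 0,
            ap_duration > 0)
  structure(
    list(V_0 = V_0, V_thr = V_thr, ap_min = ap_min, ap_max = ap_max,
         ap_duration = ap_duration, C = C, R = R),
    class = "cell_class_params"
  )
}

#' Default electrophysiology parameters for ORNs, LNs and PNs
#'
#' Typical values measured in the three antennal-lobe cell types:
#' resting potential -70/-50/-55 mV, threshold -50/-40/-40 mV, spike
#' minimum -70/-60/-55 mV, spike peak 0/0/-30 mV, spike duration 2/4/2 ms,
#' capacitance 73/64/73 pF and input resistance 1.8/1/0.3 GOhm for
#' ORN/LN/PN respectively.
#'
#' @return Named list with elements `ORN`, `LN`, `PN`, each a
#'   [cell_class_params()] object. Both uniglomerular and multiglomerular
#'   PNs use the `PN` entry.
#' @export
default_cell_params <- function() {
  list(
    ORN = cell_class_params(V_0 = -70, V_thr = -50, ap_min = -70, ap_max = 0,
                            ap_duration = 2, C = 73, R = 1.8),
    LN  = cell_class_params(V_0 = -50, V_thr = -40, ap_min = -60, ap_max = 0,
                            ap_duration = 4, C = 64, R = 1),
    PN  = cell_class_params(V_0 = -55, V_thr = -40, ap_min = -55, ap_max = -30,
                            ap_duration = 2, C = 73, R = 0.3)
  )
}

#' Class-specific synaptic sensitivity multipliers
#'
#' Each postsynaptic neuron scales its incoming synaptic current by a single
#' hand-tuned, class-specific sensitivity (current per upstream action
#' potential). These four numbers are the model's only free parameters; the
#' defaults are the tuned configuration under which the simulated antennal
#' lobe reproduces the canonical computations (see the package vignette).
#'
#' @param a_ORN,a_eLN,a_iLN,a_PN strictly positive multipliers applied to the
#'   columns of the connectivity matrix for ORN, excitatory-LN,
#'   inhibitory-LN and PN postsynaptic targets.
#' @return A `sensitivity_config` list.
#' @export
sensitivity_config <- function(a_ORN = 0.1, a_eLN = 0.04, a_iLN = 0.02,
                               a_PN = 0.4) {
  vals <- c(a_ORN = a_ORN, a_eLN = a_eLN, a_iLN = a_iLN, a_PN = a_PN)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("all sensitivity multipliers must be strictly positive")
  }
  structure(as.list(vals), class = "sensitivity_config")
}

#' ORN odor-drive parameters
#'
#' Parameters of the odor-evoked ORN firing-rate model
#' `FR = FR_max * D * (f_a + (1 - f_a) * exp(-t / t_a))`, the spontaneous
#' firing rate used off-odor, and the suprathreshold current kick used to
#' force scheduled ORN spikes.
#'
#' @param FR_max maximum ORN firing rate (Hz); default 400.
#' @param f_a adapted fraction of the initial rate, in (0, 1]; default 0.75,
#'   so the fully adapted maximal rate is 300 Hz.
#' @param t_a adaptation timescale (ms); default 110.
#' @param spontaneous_rate off-odor Poisson rate (Hz); default 10.
#' @param kick_current current injected for a single time step to force a
#'   scheduled ORN spike (pA); default 1e6.
#' @return A `drive_params` list.
#' @export
drive_params <- function(FR_max = 400, f_a = 0.75, t_a = 110,
                         spontaneous_rate = 10, kick_current = 1e6) {
  stopifnot(FR_max > 0, f_a > 0, f_a <= 1, t_a > 0, spontaneous_rate >= 0,
            kick_current > 0)
  structure(list(FR_max = FR_max, f_a = f_a, t_a = t_a,
                 spontaneous_rate = spontaneous_rate,
                 kick_current = kick_current),
            class = "drive_params")
}

#' Odor-panel stimulus protocol
#'
#' Odors are delivered back to back: each odor is on for `on_duration` ms
#' followed by an odor-free gap of `gap_duration` ms, after an odor-free
#' lead-in. Defaults mirror the tuning protocol (400 ms on, 300 ms gaps).
#'
#' @param odors character vector of odor labels, in delivery order.
#' @param on_duration odor-on duration (ms).
#' @param gap_duration odor-free gap between odors (ms).
#' @param lead_in odor-free lead-in before the first odor (ms).
#' @return A `stimulus_protocol` list with a precomputed tibble of odor
#'   windows (`onset`, `offset`, ms from simulation start).
#' @export
stimulus_protocol <- function(odors, on_duration = 400, gap_duration = 300,
                              lead_in = 200) {
  stopifnot(length(odors) >= 1, on_duration > 0, gap_duration >= 0,
            lead_in >= 0)
  odors <- as.character(odors)
  onset <- lead_in + (seq_along(odors) - 1) * (on_duration + gap_duration)
  windows <- tibble::tibble(odor = odors, onset = onset,
                            offset = onset + on_duration)
  structure(list(odors = odors, on_duration = on_duration,
                 gap_duration = gap_duration, lead_in = lead_in,
                 windows = windows,
                 total_duration = max(windows$offset) + gap_duration),
            class = "stimulus_protocol")
}

#' Read a shared configuration file
#'
#' Reads a YAML (or JSON) configuration holding the keys used across the
#' package: `excluded_glomeruli`, `sensitivities`, `drive`, `protocol`.
#' Missing keys fall back to package defaults.
#'
#' @param path path to a YAML or JSON file.
#' @return A named list with elements `excluded_glomeruli`,
#'   `sensitivities` ([sensitivity_config()]), `drive` ([drive_params()])
#'   and `protocol` (list of protocol fields, or `NULL`).
#' @export
read_al_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  sens <- do.call(sensitivity_config, as.list(cfg$sensitivities %||% list()))
  drv <- do.call(drive_params, as.list(cfg$drive %||% list()))
  proto <- if (!is.null(cfg$protocol)) do.call(stimulus_protocol,
                                               as.list(cfg$protocol))
  list(
    excluded_glomeruli = cfg$excluded_glomeruli %||% default_excluded_glomeruli(),
    sensitivities = sens, drive = drv, protocol = proto
  )
}

#' Non-olfactory glomeruli excluded from the model
#'
#' Hygro- and thermosensory glomeruli whose ORNs and PNs are removed when a
#' roster is loaded, leaving the olfactory glomeruli only.
#'
#' @return Character vector of glomerulus labels.
#' @export
default_excluded_glomeruli <- function() {
  c("VP1d", "VP1l", "VP1m", "VP2", "VP3", "VP4", "VP5")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
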