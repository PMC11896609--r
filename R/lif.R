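#' Simulate the antennal-lobe network
#'
#' Forward-Euler integration (default dt = 0.1 ms) of single-compartment
#' leaky integrate-and-fire dynamics for every neuron. Scheduled ORN spikes
#' are forced by injecting the kick current for a single time step. When a
#' neuron crosses threshold, a templated action potential is written into
#' its voltage trace (integration suspended, acting as a refractory
#' period), and a unit-amplitude exponential postsynaptic current is
#' delivered to downstream neurons, scaled by the signed effective weight,
#' beginning the following time step.
#'
#' @param weights an `al_weights` from [build_weight_matrix()].
#' @param schedules named list of numeric vectors: scheduled spike times
#'   (ms) per neuron id (typically ORNs). Ids absent from the list receive
#'   no scheduled spikes.
#' @param duration simulated duration (ms).
#' @param dt time step (ms); must divide the action-potential durations.
#' @param cell_params list with `ORN`, `LN`, `PN` entries
#'   ([default_cell_params()]).
#' @param tau_syn postsynaptic-current decay timescale (ms); default 4, the tuned value.
#' @param kick_current current (pA) injected for one step per scheduled
#'   spike.
#' @param constant_current optional named vector of constant injected
#'   current (pA) per neuron id; unnamed scalar applies to all neurons.
#' @param store_voltage keep the full voltage traces (time x neuron)?
#'   Spike times are always kept.
#' @param protocol optional [stimulus_protocol()] stored as metadata.
#' @return An `al_simulation`: list with `spikes` (named list of spike-time
#'   vectors, ms), `dt`, `duration`, `roster`, optional `voltage`, and
#'   `protocol`.
#' @export
simulate_circuit <- function(weights, schedules = list(), duration,
                             dt = 0.1, cell_params = default_cell_params(),
                             tau_syn = 4, kick_current = 1e6,
                             constant_current = 0, store_voltage = FALSE,
                             protocol = NULL) {
  stopifnot(inherits(weights, "al_weights"))
  roster <- weights$roster
  n <- nrow(roster)
  cls <- ifelse(roster$cell_class %in% c("uPN", "mPN"), "PN",
                ifelse(roster$cell_class == "LN", "LN", "ORN"))
  par_of <- function(field) vapply(cls, function(k) cell_params[[k]][[field]],
                                   numeric(1))
  ap_dur <- par_of("ap_duration")
  ap_steps <- round(ap_dur / dt)
  if (any(abs(ap_steps * dt - ap_dur) > 1e-9) || any(ap_steps < 1)) {
    abort("dt must divide every action-potential duration")
  }
  n_steps <- as.integer(round(duration / dt))

  if (length(constant_current) == 1 && is.null(names(constant_current))) {
    const_i <- rep(as.numeric(constant_current), n)
  } else {
    const_i <- rep(0, n)
    idx <- match(names(constant_current), roster$id)
    if (anyNA(idx)) abort("constant_current names must be roster ids")
    const_i[idx] <- as.numeric(constant_current)
  }

  sched <- schedules[names(schedules) %in% roster$id]
  if (length(schedules) && length(sched) < length(schedules)) {
    abort("schedule names must be roster ids")
  }
  if (length(sched)) {
    neuron <- rep(match(names(sched), roster$id) - 1L,
                  lengths(sched))
    step <- as.integer(round(unlist(sched, use.names = FALSE) / dt))
    if (any(step < 0) || any(step >= n_steps)) {
      abort("scheduled spike times must lie within the simulated duration")
    }
    o <- order(step)
    step <- step[o]; neuron <- neuron[o]
  } else {
    step <- integer(0); neuron <- integer(0)
  }

  res <- lif_simulate_cpp(
    Wt = t(weights$effective),
    V0 = par_of("V_0"), Vthr = par_of("V_thr"),
    ap_min = par_of("ap_min"), ap_max = par_of("ap_max"),
    ap_steps = as.integer(ap_steps),
    Cm = par_of("C"), Rm = par_of("R"),
    sched_step = step, sched_neuron = neuron,
    constant_current = const_i,
    n_steps = n_steps, dt = dt, tau_syn = tau_syn,
    kick_current = kick_current, store_voltage = store_voltage)

  spikes <- setNames(res$spikes, roster$id)
  out <- list(spikes = spikes, dt = dt, duration = duration,
              roster = roster, protocol = protocol)
  if (store_voltage) {
    out$voltage <- res$voltage
    colnames(out$voltage) <- roster$id
  }
  structure(out, class = "al_simulation")
}

#' @export
print.al_simulation <- function(x, ...) {
  cat("<al_simulation> ", length(x$spikes), " neurons, ",
      sum(lengths(x$spikes)), " spikes over ", x$duration, " ms (dt = ",
      x$dt, " ms)\n", sep = "")
  invisible(x)
}

#' Firing rates over a time window
#'
#' Counts spikes in the half-open window `\[start, end)` and divides by the
#' window length.
#'
#' @param sim an `al_simulation`.
#' @param window numeric length-2, window start and end (ms).
#' @return Named numeric vector of rates (Hz) per neuron.
#' @export
compute_firing_rates <- function(sim, window) {
  stopifnot(length(window) == 2)
  len <- window[2] - window[1]
  if (len <= 0) abort("window must have positive length")
  if (window[1] < 0 || window[2] > sim$duration + 1e-9) {
    abort("window must lie within the simulated duration")
  }
  counts <- vapply(sim$spikes,
                   function(s) sum(s >= window[1] & s < window[2]),
                   numeric(1))
  counts / len * 1000  # ms -> Hz
}

#' Simulate an odor panel and reduce to glomerulus-by-odor responses
#'
#' Runs one continuous simulation across the whole panel: ORN spike
#' schedules are drawn from the adapting evoked rate (or the spontaneous
#' rate off-odor and for unresponsive glomeruli), the network is
#' integrated, and mean firing rates are computed over each odor-on
#' window. The glomerular PN response is the mean rate over the
#' glomerulus's uPNs; the glomerular ORN response is the mean over its
#' ORNs.
#'
#' @param weights an `al_weights`.
#' @param door complete glomerulus-by-odor response matrix in \[0, 1\].
#' @param protocol a [stimulus_protocol()]; all protocol odors must be
#'   columns of `door`.
#' @param drive a [drive_params()].
#' @param seed integer seed governing ORN spike sampling.
#' @param dt time step (ms).
#' @param cell_params per-class electrophysiology
#'   ([default_cell_params()]).
#' @param tau_syn postsynaptic-current decay (ms).
#' @param subtract_baseline subtract each neuron's lead-in rate from its
#'   odor-window rates before glomerular averaging? Off by default (raw
#'   response vectors).
#' @return An `al_response`: list with `pn` and `orn` (glomeruli x odors
#'   rate matrices, Hz), `neuron_rates` (neurons x odors),
#'   `baseline_rates` (per neuron, lead-in window), `protocol`, `roster`.
#' @export
run_odor_panel <- function(weights, door, protocol, drive = drive_params(),
                           seed = 1, dt = 0.1,
                           cell_params = default_cell_params(),
                           tau_syn = 4, subtract_baseline = FALSE) {
  door <- as_response_matrix(door)
  if (anyNA(door)) abort("response matrix must be complete; impute first")
  roster <- weights$roster
  orn_rows <- which(roster$cell_class == "ORN")
  prof <- orn_rate_profiles(roster$glomerulus[orn_rows], door, protocol,
                            drive, dt)
  schedules <- withr::with_seed(seed, {
    seeds <- sample.int(.Machine$integer.max, length(orn_rows))
    lapply(seq_along(orn_rows), function(k) {
      sample_orn_spike_times(prof[, k], protocol$total_duration, dt,
                             seed = seeds[k])
    })
  })
  names(schedules) <- roster$id[orn_rows]

  sim <- simulate_circuit(weights, schedules, protocol$total_duration,
                          dt = dt, cell_params = cell_params,
                          tau_syn = tau_syn,
                          kick_current = drive$kick_current,
                          protocol = protocol)

  rates <- sapply(seq_len(nrow(protocol$windows)), function(w) {
    compute_firing_rates(sim, c(protocol$windows$onset[w],
                                protocol$windows$offset[w]))
  })
  colnames(rates) <- protocol$windows$odor
  baseline <- if (protocol$lead_in > 0) {
    compute_firing_rates(sim, c(0, protocol$lead_in))
  } else {
    setNames(rep(NA_real_, nrow(roster)), roster$id)
  }
  if (subtract_baseline) rates <- rates - baseline

  gloms <- sort(unique(stats::na.omit(roster$glomerulus)))
  glom_mean <- function(class_keep) {
    t(sapply(gloms, function(g) {
      rows <- which(roster$glomerulus %in% g &
                    roster$cell_class %in% class_keep)
      if (!length(rows)) return(rep(NA_real_, ncol(rates)))
      colMeans(rates[rows, , drop = FALSE])
    }))
  }
  pn <- glom_mean("uPN")
  orn <- glom_mean("ORN")
  colnames(pn) <- colnames(orn) <- protocol$windows$odor

  structure(list(pn = pn, orn = orn, neuron_rates = rates,
                 baseline_rates = baseline, protocol = protocol,
                 roster = roster, seed = seed),
            class = "al_response")
}

#' @export
print.al_response <- function(x, ...) {
  cat("<al_response> ", nrow(x$pn), " glomeruli x ", ncol(x$pn),
      " odors; mean PN rate ",
      round(mean(x$pn, na.rm = TRUE), 1), " Hz\n", sep = "")
  invisible(x)
}

#' Serialize a simulation result to plain-text files
#'
#' Spike times go to a CSV (`neuron_id, time_ms`, one row per spike);
#' metadata (dt, duration, protocol odors/windows) to a JSON sidecar.
#'
#' @param sim an `al_simulation`.
#' @param spikes_path CSV output path.
#' @param meta_path JSON output path.
#' @return Invisibly, `sim`.
#' @export
write_simulation <- function(sim, spikes_path, meta_path) {
  df <- tibble::tibble(
    neuron_id = rep(names(sim$spikes), lengths(sim$spikes)),
    time_ms = unlist(sim$spikes, use.names = FALSE))
  readr::write_csv(df, spikes_path)
  meta <- list(dt = sim$dt, duration = sim$duration,
               neuron_ids = names(sim$spikes))
  if (!is.null(sim$protocol)) {
    meta$protocol <- list(odors = sim$protocol$odors,
                          on_duration = sim$protocol$on_duration,
                          gap_duration = sim$protocol$gap_duration,
                          lead_in = sim$protocol$lead_in)
  }
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA)
  invisible(sim)
}

#' @rdname write_simulation
#' @param spikes_path,meta_path paths written by [write_simulation()].
#' @export
read_simulation <- function(spikes_path, meta_path) {
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  df <- readr::read_csv(spikes_path, col_types = readr::cols(
    neuron_id = readr::col_character(), time_ms = readr::col_double()))
  spikes <- setNames(vector("list", length(meta$neuron_ids)),
                     meta$neuron_ids)
  spl <- split(df$time_ms, df$neuron_id)
  spikes[names(spl)] <- spl
  spikes[vapply(spikes, is.null, logical(1))] <- list(numeric(0))
  proto <- if (!is.null(meta$protocol)) {
    do.call(stimulus_protocol, meta$protocol)
  }
  structure(list(spikes = spikes, dt = meta$dt, duration = meta$duration,
                 roster = NULL, protocol = proto),
            class = "al_simulation")
}
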