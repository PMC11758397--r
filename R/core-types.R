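#' Step-current protocol description
#'
#' Describes the family of 1-s square current pulses used to probe passive
#' and firing properties: a series of steps starting with hyperpolarising
#' amplitudes and increasing into the suprathreshold range.
#'
#' @param step_amplitudes_pa Numeric vector of injected currents (pA),
#'   strictly increasing.
#' @param step_onset_ms Time of step onset within each sweep (ms), >= 0.
#' @param step_duration_ms Step duration (ms), nominally 1000.
#' @param inter_sweep_interval_s Interval between successive sweeps (s).
#' @return An object of class `step_protocol`.
#' @export
step_protocol <- function(step_amplitudes_pa,
                          step_onset_ms = 200,
                          step_duration_ms = 1000,
                          inter_sweep_interval_s = 5) {
  step_amplitudes_pa <- as.numeric(step_amplitudes_pa)
  if (length(step_amplitudes_pa) < 1L || anyNA(step_amplitudes_pa)) {
    stop("step_amplitudes_pa must be a nonempty numeric vector", call. = FALSE)
  }
  if (any(diff(step_amplitudes_pa) <= 0)) {
    stop("step amplitudes must be strictly increasing", call. = FALSE)
  }
  if (step_duration_ms <= 0) stop("step_duration_ms must be > 0", call. = FALSE)
  if (step_onset_ms < 0) stop("step_onset_ms must be >= 0", call. = FALSE)
  structure(
    list(
      step_amplitudes_pa = step_amplitudes_pa,
      step_onset_ms = as.numeric(step_onset_ms),
      step_duration_ms = as.numeric(step_duration_ms),
      inter_sweep_interval_s = as.numeric(inter_sweep_interval_s)
    ),
    class = "step_protocol"
  )
}

#' Single current-clamp sweep
#'
#' A uniformly sampled membrane-potential trace with the corresponding
#' injected-current trace. Internal units are fixed: mV, pA, ms.
#'
#' @param time_ms Uniform time grid (ms).
#' @param voltage_mv Membrane potential samples (mV).
#' @param current_pa Injected current samples (pA); may be a scalar step
#'   amplitude, in which case the trace is reconstructed from the protocol
#'   at read time.
#' @param sweep_id Identifier of the sweep within its set.
#' @param neuron_id Identifier of the recorded neuron.
#' @return An object of class `sweep_recording`.
#' @export
sweep_recording <- function(time_ms, voltage_mv, current_pa,
                            sweep_id = 1L, neuron_id = "n1") {
  time_ms <- as.numeric(time_ms)
  voltage_mv <- as.numeric(voltage_mv)
  current_pa <- as.numeric(current_pa)
  n <- length(time_ms)
  if (n < 2L) stop("sweep needs at least 2 samples", call. = FALSE)
  if (length(voltage_mv) != n) {
    stop(sprintf("sweep '%s': time (%d) and voltage (%d) lengths differ",
                 sweep_id, n, length(voltage_mv)), call. = FALSE)
  }
  if (!length(current_pa) %in% c(1L, n)) {
    stop(sprintf("sweep '%s': current length must be 1 or %d", sweep_id, n),
         call. = FALSE)
  }
  dt <- diff(time_ms)
  if (any(abs(dt - dt[1]) > 1e-6 * max(dt[1], 1e-12)) || dt[1] <= 0) {
    stop(sprintf("sweep '%s': time grid is not uniform", sweep_id),
         call. = FALSE)
  }
  structure(
    list(
      time_ms = time_ms,
      voltage_mv = voltage_mv,
      current_pa = current_pa,
      dt_ms = dt[1],
      sweep_id = sweep_id,
      neuron_id = neuron_id
    ),
    class = "sweep_recording"
  )
}

#' Sampling interval of a sweep (ms)
#' @param sweep A `sweep_recording`.
#' @return Sampling interval in ms.
#' @export
sweep_dt <- function(sweep) sweep$dt_ms

#' Set of sweeps recorded under one step protocol
#'
#' @param protocol A [step_protocol()].
#' @param sweeps List of [sweep_recording()] objects, one per step amplitude,
#'   in protocol order.
#' @return An object of class `sweep_set`.
#' @export
sweep_set <- function(protocol, sweeps) {
  stopifnot(inherits(protocol, "step_protocol"))
  if (length(sweeps) != length(protocol$step_amplitudes_pa)) {
    stop(sprintf("sweep count (%d) does not match protocol amplitude count (%d)",
                 length(sweeps), length(protocol$step_amplitudes_pa)),
         call. = FALSE)
  }
  if (!all(vapply(sweeps, inherits, logical(1), "sweep_recording"))) {
    stop("all elements of 'sweeps' must be sweep_recording objects",
         call. = FALSE)
  }
  ns <- vapply(sweeps, function(s) length(s$time_ms), integer(1))
  if (length(unique(ns)) != 1L) {
    bad <- sweeps[[which(ns != ns[1])[1]]]$sweep_id
    stop(sprintf("sweep '%s' has a different sample count than the others", bad),
         call. = FALSE)
  }
  structure(list(protocol = protocol, sweeps = sweeps), class = "sweep_set")
}

#' @export
print.sweep_set <- function(x, ...) {
  cat(sprintf("<sweep_set> %d sweeps, steps %g..%g pA, dt %g ms\n",
              length(x$sweeps),
              min(x$protocol$step_amplitudes_pa),
              max(x$protocol$step_amplitudes_pa),
              x$sweeps[[1]]$dt_ms))
  invisible(x)
}

#' Long drug-application trace
#'
#' A continuous current-clamp voltage recording spanning a pre-application
#' baseline (nominally >= 3 min), the bath-application window, and washout.
#'
#' @param voltage_mv Voltage samples (mV).
#' @param dt_ms Sampling interval (ms).
#' @param application_onset_ms,application_offset_ms Application window (ms).
#' @param drug_label Free-text drug label (e.g. "ACh 30 uM").
#' @param ttx_present Logical; whether TTX blocked action potentials.
#' @param baseline_window_ms Optional explicit baseline window
#'   `c(start, end)` in ms; defaults to the 180 s preceding onset.
#' @return An object of class `drug_trace`.
#' @export
drug_trace <- function(voltage_mv, dt_ms, application_onset_ms,
                       application_offset_ms, drug_label = "drug",
                       ttx_present = FALSE, baseline_window_ms = NULL) {
  voltage_mv <- as.numeric(voltage_mv)
  if (dt_ms <= 0) stop("dt_ms must be > 0", call. = FALSE)
  if (application_onset_ms >= application_offset_ms) {
    stop("application onset must precede offset", call. = FALSE)
  }
  if (is.null(baseline_window_ms)) {
    if (application_onset_ms < 180e3) {
      stop(paste("less than 180 s of baseline precedes application onset;",
                 "supply baseline_window_ms explicitly"), call. = FALSE)
    }
    baseline_window_ms <- c(application_onset_ms - 180e3, application_onset_ms)
  }
  structure(
    list(
      voltage_mv = voltage_mv,
      dt_ms = as.numeric(dt_ms),
      application_onset_ms = as.numeric(application_onset_ms),
      application_offset_ms = as.numeric(application_offset_ms),
      drug_label = drug_label,
      ttx_present = isTRUE(ttx_present),
      baseline_window_ms = as.numeric(baseline_window_ms)
    ),
    class = "drug_trace"
  )
}

#' Paired-recording sweep set
#'
#' Presynaptic action-potential peak times and the postsynaptic voltage
#' trace for each sweep of a paired recording, with the 10 Hz train
#' protocol metadata and an experimental-phase label per sweep.
#'
#' @param sweeps List of sweeps; each element a list with fields
#'   `presyn_ap_peak_ms` (numeric, >= 2 peaks), `voltage_mv`, `dt_ms`.
#' @param stimulation_hz Presynaptic stimulation frequency (Hz), nominally 10.
#' @param n_aps_per_train Number of presynaptic APs per train (2, 3 or 10).
#' @param phase Character vector, one of `baseline`, `drug`, `washout`
#'   per sweep (recycled if scalar).
#' @return An object of class `paired_sweep_set`.
#' @export
paired_sweep_set <- function(sweeps, stimulation_hz = 10,
                             n_aps_per_train = 10, phase = "baseline") {
  if (length(sweeps) < 1L) stop("need at least one sweep", call. = FALSE)
  phase <- rep_len(as.character(phase), length(sweeps))
  if (!all(phase %in% c("baseline", "drug", "washout"))) {
    stop("phase labels must be baseline/drug/washout", call. = FALSE)
  }
  ipi_ms <- 1000 / stimulation_hz
  for (i in seq_along(sweeps)) {
    sw <- sweeps[[i]]
    if (length(sw$presyn_ap_peak_ms) < 2L) {
      stop(sprintf("sweep %d: need >= 2 presynaptic AP peaks", i), call. = FALSE)
    }
    gaps <- diff(sw$presyn_ap_peak_ms)
    if (any(abs(gaps - ipi_ms) > sw$dt_ms + 1e-9)) {
      stop(sprintf(
        "sweep %d: inter-AP spacing inconsistent with %g Hz (within 1 sample)",
        i, stimulation_hz), call. = FALSE)
    }
  }
  structure(
    list(
      sweeps = sweeps,
      stimulation_hz = as.numeric(stimulation_hz),
      n_aps_per_train = as.integer(n_aps_per_train),
      phase = phase
    ),
    class = "paired_sweep_set"
  )
}

#' Recording quality-control policy
#'
#' Recordings with a series resistance above `max_series_resistance_mohm`
#' or an initial membrane potential depolarised above `max_initial_vm_mv`
#' are excluded from analysis.
#'
#' @param max_series_resistance_mohm Series-resistance ceiling (MOhm).
#' @param max_initial_vm_mv Most depolarised acceptable initial Vm (mV).
#' @return An object of class `qc_policy`.
#' @export
qc_policy <- function(max_series_resistance_mohm = 40,
                      max_initial_vm_mv = -55) {
  structure(
    list(
      max_series_resistance_mohm = as.numeric(max_series_resistance_mohm),
      max_initial_vm_mv = as.numeric(max_initial_vm_mv)
    ),
    class = "qc_policy"
  )
}

#' Apply recording quality control
#'
#' Pure function of the metadata and the policy: a neuron fails if its
#' series resistance exceeds the ceiling or its initial membrane potential
#' is depolarised above the ceiling (strict inequalities).
#'
#' @param neuron_metadata List or one-row data frame with fields
#'   `series_resistance_mohm` and `initial_vm_mv`.
#' @param policy A [qc_policy()].
#' @return List with `pass` (logical) and `reason` (character; `""` on pass).
#' @export
apply_qc <- function(neuron_metadata, policy = qc_policy()) {
  rs <- neuron_metadata[["series_resistance_mohm"]]
  vm <- neuron_metadata[["initial_vm_mv"]]
  if (is.null(rs) || is.na(rs)) {
    stop("neuron metadata lacks series_resistance_mohm", call. = FALSE)
  }
  if (is.null(vm) || is.na(vm)) {
    stop("neuron metadata lacks initial_vm_mv", call. = FALSE)
  }
  reasons <- character(0)
  if (rs > policy$max_series_resistance_mohm) {
    reasons <- c(reasons, sprintf(
      "series resistance %g MOhm exceeds %g MOhm",
      rs, policy$max_series_resistance_mohm))
  }
  if (vm > policy$max_initial_vm_mv) {
    reasons <- c(reasons, sprintf(
      "depolarised membrane potential %g mV exceeds %g mV",
      vm, policy$max_initial_vm_mv))
  }
  list(pass = length(reasons) == 0L, reason = paste(reasons, collapse = "; "))
}
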