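#' Align sweeps to the first presynaptic AP peak and average
#'
#' Every sweep is time-shifted so its first presynaptic AP peak sits at
#' t = 0, then the sweeps are averaged arithmetically (release failures,
#' if any, included — the mean is a potency-weighted amplitude). The
#' baseline is the mean over the [-10, -1] ms pre-AP window; the
#' baseline noise SD of the mean trace is stored for the noise floor.
#'
#' @param paired A [paired_sweep_set()].
#' @param phase Phase to average (`"baseline"`, `"drug"`, `"washout"`).
#' @return An object of class `mean_uepsp`: list with `time_ms` (zero at
#'   the presynaptic AP peak), `voltage_mv`, `dt_ms`, `n_sweeps`,
#'   `baseline_vm_mv`, `baseline_noise_sd_mv`, `pulse_times_ms`,
#'   `stimulation_hz`, `n_aps`.
#' @export
align_and_average <- function(paired, phase = "baseline") {
  stopifnot(inherits(paired, "paired_sweep_set"))
  sel <- which(paired$phase == phase)
  if (length(sel) == 0L) stop("no sweeps in phase '", phase, "'", call. = FALSE)
  sweeps <- paired$sweeps[sel]
  dt <- sweeps[[1]]$dt_ms
  # aligned time of each sweep: t - first presyn peak
  starts <- vapply(sweeps, function(sw) {
    tm <- sw$time_ms %||% ((seq_along(sw$voltage_mv) - 1) * sw$dt_ms)
    tm[1] - sw$presyn_ap_peak_ms[1]
  }, numeric(1))
  ends <- vapply(seq_along(sweeps), function(i) {
    starts[i] + (length(sweeps[[i]]$voltage_mv) - 1) * sweeps[[i]]$dt_ms
  }, numeric(1))
  lo <- max(starts); hi <- min(ends)
  if (lo > -50) stop("sweeps must include >= 50 ms pre-AP baseline",
                     call. = FALSE)
  grid <- seq(ceiling(lo / dt) * dt, floor(hi / dt) * dt, by = dt)
  acc <- numeric(length(grid))
  for (i in seq_along(sweeps)) {
    sw <- sweeps[[i]]
    tm <- (sw$time_ms %||% ((seq_along(sw$voltage_mv) - 1) * sw$dt_ms)) -
      sw$presyn_ap_peak_ms[1]
    acc <- acc + stats::approx(tm, sw$voltage_mv, xout = grid,
                               rule = 2)$y
  }
  mean_v <- acc / length(sweeps)
  bwin <- grid >= -10 & grid <= -1
  structure(list(
    time_ms = grid, voltage_mv = mean_v, dt_ms = dt,
    n_sweeps = length(sweeps),
    baseline_vm_mv = mean(mean_v[bwin]),
    baseline_noise_sd_mv = stats::sd(mean_v[grid >= lo & grid < -1]),
    pulse_times_ms = sweeps[[1]]$presyn_ap_peak_ms -
      sweeps[[1]]$presyn_ap_peak_ms[1],
    stimulation_hz = paired$stimulation_hz,
    n_aps = paired$n_aps_per_train
  ), class = "mean_uepsp")
}

#' EPSP amplitude of pulse k on the mean trace
#'
#' The amplitude is the maximum of the mean trace in the window
#' `(t_k + 1 ms, t_k + min(interpulse, 90 ms))` minus the pulse-local
#' baseline: the [-10, -1] ms pre-train baseline for pulse 1, and the
#' mean over the 2 ms immediately preceding `t_k` for later pulses
#' (raw amplitudes on the summating train, no decay subtraction).
#'
#' @param mean_uepsp A [align_and_average()] result.
#' @param pulse_index k (1-based).
#' @return Amplitude (mV).
#' @export
epsp_amplitude <- function(mean_uepsp, pulse_index = 1) {
  m <- mean_uepsp
  k <- pulse_index
  if (k < 1 || k > length(m$pulse_times_ms)) {
    stop("pulse ", k, " does not exist", call. = FALSE)
  }
  tk <- m$pulse_times_ms[k]
  ipi <- 1000 / m$stimulation_hz
  win <- m$time_ms > tk + 1 & m$time_ms <= tk + min(ipi, 90)
  if (!any(win)) stop("empty search window for pulse ", k, call. = FALSE)
  base <- if (k == 1) m$baseline_vm_mv else {
    pre <- m$time_ms >= tk - 2 & m$time_ms < tk
    mean(m$voltage_mv[pre])
  }
  max(m$voltage_mv[win]) - base
}

#' All per-pulse amplitudes of the mean uEPSP
#' @param mean_uepsp A [align_and_average()] result.
#' @return Numeric vector A_1..A_k.
#' @export
per_pulse_amplitudes <- function(mean_uepsp) {
  vapply(seq_along(mean_uepsp$pulse_times_ms),
         function(k) epsp_amplitude(mean_uepsp, k), numeric(1))
}

#' Paired-pulse ratio on the mean trace
#'
#' PPR = A_2 / A_1, computed on the mean trace (per-sweep ratios are
#' unstable when A_1 is near zero). The ratio is flagged undefined when
#' A_1 falls below the noise floor (3x the baseline SD of the mean
#' trace).
#'
#' @param mean_uepsp A [align_and_average()] result.
#' @return List with `ppr` (`NA` when flagged), `a1_mv`, `a2_mv`,
#'   `below_noise_floor` (logical).
#' @export
paired_pulse_ratio <- function(mean_uepsp) {
  a1 <- epsp_amplitude(mean_uepsp, 1)
  a2 <- epsp_amplitude(mean_uepsp, 2)
  floor3 <- 3 * mean_uepsp$baseline_noise_sd_mv
  below <- is.na(a1) || a1 <= floor3
  list(ppr = if (below) NA_real_ else a2 / a1,
       a1_mv = a1, a2_mv = a2, below_noise_floor = below)
}

#' Summarise one phase of a connection
#'
#' @param paired A [paired_sweep_set()].
#' @param phase Phase label.
#' @param pre_cell_class,post_cell_class Optional cell-class labels.
#' @return List (`connection_summary`): `epsp1_amplitude_mv`, `ppr`,
#'   `phase`, `n_sweeps`, `below_noise_floor`, class labels.
#' @export
connection_summary <- function(paired, phase = "baseline",
                               pre_cell_class = NA_character_,
                               post_cell_class = NA_character_) {
  m <- align_and_average(paired, phase)
  pr <- paired_pulse_ratio(m)
  structure(list(
    epsp1_amplitude_mv = pr$a1_mv, ppr = pr$ppr, phase = phase,
    n_sweeps = m$n_sweeps, below_noise_floor = pr$below_noise_floor,
    pre_cell_class = pre_cell_class, post_cell_class = post_cell_class
  ), class = "connection_summary")
}

#' Neuromodulator effect on a connection
#'
#' Computes independent mean uEPSPs for the baseline and drug phases and
#' reports the per-phase amplitude and PPR plus their drug/baseline
#' ratios.
#'
#' @param paired A [paired_sweep_set()] containing both phases.
#' @return List with `baseline`, `drug` (each a [connection_summary()]),
#'   `amplitude_ratio`, `ppr_ratio`.
#' @export
drug_modulation <- function(paired) {
  for (ph in c("baseline", "drug")) {
    if (!ph %in% paired$phase) stop("missing phase '", ph, "'", call. = FALSE)
  }
  b <- connection_summary(paired, "baseline")
  d <- connection_summary(paired, "drug")
  list(baseline = b, drug = d,
       amplitude_ratio = d$epsp1_amplitude_mv / b$epsp1_amplitude_mv,
       ppr_ratio = d$ppr / b$ppr)
}
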