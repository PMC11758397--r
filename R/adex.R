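#' AdEx model parameters
#'
#' Parameter record for the adaptive exponential integrate-and-fire
#' neuron used as the ground-truthed spiking-trace generator. With
#' `a = b = 0` and no noise the model reduces to the exponential
#' integrate-and-fire neuron, whose rheobase has the closed form
#' `I_rh = gL * (VT - EL - DeltaT)` — the analytic oracle the test suite
#' leans on.
#'
#' @param C_pf Membrane capacitance (pF).
#' @param gL_ns Leak conductance (nS).
#' @param EL_mv Leak reversal / resting potential (mV).
#' @param VT_mv Exponential threshold (mV).
#' @param DeltaT_mv Spike slope factor (mV).
#' @param a_ns Subthreshold adaptation conductance (nS).
#' @param b_pa Spike-triggered adaptation increment (pA).
#' @param tauw_ms Adaptation time constant (ms).
#' @param Vr_mv Post-spike reset potential (mV).
#' @param Vpeak_mv Spike cutoff / drawn peak (mV).
#' @param noise_sigma_pa Stationary SD of the Ornstein-Uhlenbeck noise
#'   current (pA); 0 disables noise.
#' @param noise_tau_ms Correlation time of the noise current (ms).
#' @return An object of class `adex_params`.
#' @export
adex_params <- function(C_pf, gL_ns, EL_mv, VT_mv, DeltaT_mv = 2,
                        a_ns = 0, b_pa = 0, tauw_ms = 200,
                        Vr_mv = -60, Vpeak_mv = 30,
                        noise_sigma_pa = 0, noise_tau_ms = 5) {
  if (C_pf <= 0 || gL_ns <= 0 || tauw_ms <= 0 || DeltaT_mv <= 0) {
    stop("C, gL, tauw and DeltaT must all be > 0", call. = FALSE)
  }
  if (Vr_mv >= Vpeak_mv) stop("Vr must lie below Vpeak", call. = FALSE)
  structure(list(
    C_pf = C_pf, gL_ns = gL_ns, EL_mv = EL_mv, VT_mv = VT_mv,
    DeltaT_mv = DeltaT_mv, a_ns = a_ns, b_pa = b_pa, tauw_ms = tauw_ms,
    Vr_mv = Vr_mv, Vpeak_mv = Vpeak_mv,
    noise_sigma_pa = noise_sigma_pa, noise_tau_ms = noise_tau_ms
  ), class = "adex_params")
}

#' Closed-form rheobase of the non-adapting exponential IF neuron
#'
#' Valid for `a = 0` (no subthreshold adaptation): the saddle-node current
#' above which no stable subthreshold fixed point exists.
#'
#' @param params An [adex_params()] with `a_ns = 0`.
#' @return Rheobase current (pA).
#' @export
eif_rheobase <- function(params) {
  if (params$a_ns != 0) {
    stop("closed-form rheobase requires a_ns = 0", call. = FALSE)
  }
  params$gL_ns * (params$VT_mv - params$EL_mv - params$DeltaT_mv)
}

#' Firing-phenotype presets
#'
#' Calibrated AdEx parameter sets emulating the four layer-6 excitatory
#' firing phenotypes: corticothalamic (CT) cells in upper (`ct_l6a`) and
#' deep (`ct_l6b`) layer 6 fire a single AP at rheobase and irregular
#' trains at higher steps (irregularity produced by OU current noise);
#' corticocortical (CC) cells fire an initial burst/doublet followed by a
#' regular, rapidly (`cc_burst_rapid`) or slowly (`cc_multipolar_slow`)
#' adapting train. Passive parameters (gL, C, EL) are set so input
#' resistance, membrane time constant and resting potential sit at the
#' respective group means; adaptation and reset parameters were calibrated
#' once against the qualitative signature and frozen.
#'
#' @param name One of `"ct_l6a"`, `"ct_l6b"`, `"cc_burst_rapid"`,
#'   `"cc_multipolar_slow"`.
#' @return List with fields `name`, `adex` ([adex_params()]) and
#'   `signature` (list: `single_ap_at_rheobase`, `initial_burst`,
#'   `isi_regularity` in `{"irregular","regular"}`).
#' @export
phenotype_preset <- function(name = c("ct_l6a", "ct_l6b",
                                      "cc_burst_rapid",
                                      "cc_multipolar_slow")) {
  name <- match.arg(name)
  p <- switch(name,
    ct_l6a = list(
      adex = adex_params(C_pf = 89, gL_ns = 5.56, EL_mv = -70.6,
                         VT_mv = -43.2, DeltaT_mv = 2,
                         a_ns = 2, b_pa = 90, tauw_ms = 250,
                         Vr_mv = -58, Vpeak_mv = 30,
                         noise_sigma_pa = 22, noise_tau_ms = 5),
      signature = list(single_ap_at_rheobase = TRUE, initial_burst = FALSE,
                       isi_regularity = "irregular")),
    ct_l6b = list(
      adex = adex_params(C_pf = 92.8, gL_ns = 4.5, EL_mv = -68.3,
                         VT_mv = -45.5, DeltaT_mv = 2,
                         a_ns = 2, b_pa = 80, tauw_ms = 250,
                         Vr_mv = -56, Vpeak_mv = 30,
                         noise_sigma_pa = 14, noise_tau_ms = 5),
      signature = list(single_ap_at_rheobase = TRUE, initial_burst = FALSE,
                       isi_regularity = "irregular")),
    cc_burst_rapid = list(
      adex = adex_params(C_pf = 131, gL_ns = 6.69, EL_mv = -71.1,
                         VT_mv = -50.0, DeltaT_mv = 2,
                         a_ns = 0, b_pa = 60, tauw_ms = 150,
                         Vr_mv = -44, Vpeak_mv = 30,
                         noise_sigma_pa = 0, noise_tau_ms = 5),
      signature = list(single_ap_at_rheobase = FALSE, initial_burst = TRUE,
                       isi_regularity = "regular")),
    cc_multipolar_slow = list(
      adex = adex_params(C_pf = 110, gL_ns = 4.63, EL_mv = -66.6,
                         VT_mv = -46.6, DeltaT_mv = 2,
                         a_ns = 0, b_pa = 25, tauw_ms = 400,
                         Vr_mv = -43.5, Vpeak_mv = 30,
                         noise_sigma_pa = 4, noise_tau_ms = 5),
      signature = list(single_ap_at_rheobase = FALSE, initial_burst = TRUE,
                       isi_regularity = "regular"))
  )
  c(list(name = name), p)
}

#' Simulate an AdEx neuron under a step protocol
#'
#' Integrates the AdEx equations (Euler-Maruyama, fixed step) for each
#' step amplitude of the protocol and returns the sweeps plus a ground
#' truth record. Identical `(params, protocol, seed)` reproduce the
#' output bit-exactly.
#'
#' @param params An [adex_params()] or a preset name accepted by
#'   [phenotype_preset()].
#' @param protocol A [step_protocol()].
#' @param seed RNG seed (integer).
#' @param dt_ms Integration / sampling step (ms); must be <= 0.05.
#' @param tail_ms Recording continued after step offset (ms).
#' @param neuron_id Identifier stored in the sweeps.
#' @return List with `sweepset` ([sweep_set()]) and `ground_truth`
#'   (list: `spike_times_ms` per sweep, `spike_counts`,
#'   `rheobase_bracket_pa` — the analytic closed form when `a = b = 0`,
#'   otherwise the bracketing step amplitudes from the simulated counts).
#' @export
simulate_adex <- function(params, protocol, seed = 1L, dt_ms = 0.025,
                          tail_ms = 100, neuron_id = "syn1") {
  if (is.character(params)) params <- phenotype_preset(params)$adex
  stopifnot(inherits(params, "adex_params"), inherits(protocol, "step_protocol"))
  if (dt_ms > 0.05) stop("integration step must be <= 0.05 ms", call. = FALSE)
  total_ms <- protocol$step_onset_ms + protocol$step_duration_ms + tail_ms
  n <- floor(total_ms / dt_ms) + 1L
  time_ms <- (seq_len(n) - 1L) * dt_ms
  on_step <- time_ms >= protocol$step_onset_ms &
    time_ms < protocol$step_onset_ms + protocol$step_duration_ms

  set.seed(seed)
  sweeps <- vector("list", length(protocol$step_amplitudes_pa))
  spike_times <- vector("list", length(sweeps))
  for (i in seq_along(sweeps)) {
    amp <- protocol$step_amplitudes_pa[i]
    cur <- numeric(n)
    cur[on_step] <- amp
    sim <- adex_integrate_cpp(cur, dt_ms,
                              params$C_pf, params$gL_ns, params$EL_mv,
                              params$VT_mv, params$DeltaT_mv, params$a_ns,
                              params$b_pa, params$tauw_ms, params$Vr_mv,
                              params$Vpeak_mv, params$noise_sigma_pa,
                              params$noise_tau_ms,
                              V0 = params$EL_mv, w0 = 0)
    sweeps[[i]] <- sweep_recording(time_ms, sim$voltage_mv, cur,
                                   sweep_id = i, neuron_id = neuron_id)
    spike_times[[i]] <- time_ms[sim$spike_idx]
  }
  counts <- lengths(spike_times)
  gt <- list(spike_times_ms = spike_times, spike_counts = counts)
  if (params$a_ns == 0 && params$b_pa == 0) {
    gt$rheobase_bracket_pa <- c(eif_rheobase(params), Inf)
  } else if (any(counts > 0)) {
    first <- which(counts > 0)[1]
    gt$rheobase_bracket_pa <- c(
      if (first > 1) protocol$step_amplitudes_pa[first - 1] else -Inf,
      protocol$step_amplitudes_pa[first])
  }
  list(sweepset = sweep_set(protocol, sweeps), ground_truth = gt)
}
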