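#' Tsodyks-Markram short-term plasticity parameters
#'
#' Mean-field release model used to generate facilitating and depressing
#' unitary EPSP trains. Release fraction `u` facilitates toward 1 with
#' increment `U` and decays with `tau_fac`; resources `R` deplete by the
#' released fraction and recover with `tau_rec`. The mean amplitude of
#' pulse k is `n_sites * quantal_amplitude_mv * u_k * R_k`.
#'
#' The optional `u1` overrides the release fraction of the *first* pulse
#' only (subsequent facilitation increments still use `U`). The textbook
#' single-`U` recursion bounds the paired-pulse ratio below 2 at 10 Hz;
#' decoupling the first-pulse utilization from the facilitation increment
#' lets the analytic recursion reach the strong facilitation (PPR > 2.5)
#' shown by corticothalamic connections.
#'
#' @param U Facilitation increment / baseline release fraction, in (0, 1].
#' @param tau_fac_ms Facilitation decay time constant (ms).
#' @param tau_rec_ms Resource recovery time constant (ms); `Inf` allowed.
#' @param u1 Optional first-pulse release fraction override (0, 1].
#' @param n_sites Number of release sites (scales amplitude only).
#' @param quantal_amplitude_mv Quantal EPSP amplitude (mV).
#' @param epsp_rise_ms,epsp_decay_ms Double-exponential EPSP kernel time
#'   constants (ms).
#' @param noise_sd_mv Additive voltage noise SD (mV).
#' @param noise_tau_ms Correlation time of the additive noise (ms);
#'   membrane-filtered background noise rather than white noise.
#' @return An object of class `tm_params`.
#' @export
tm_params <- function(U, tau_fac_ms, tau_rec_ms, u1 = NULL,
                      n_sites = 1, quantal_amplitude_mv = 0.5,
                      epsp_rise_ms = 2, epsp_decay_ms = 20,
                      noise_sd_mv = 0.1, noise_tau_ms = 15) {
  if (U <= 0 || U > 1) stop("U must be in (0, 1]", call. = FALSE)
  if (!is.null(u1) && (u1 <= 0 || u1 > 1)) {
    stop("u1 must be in (0, 1]", call. = FALSE)
  }
  if (tau_fac_ms <= 0 || tau_rec_ms <= 0) {
    stop("time constants must be > 0", call. = FALSE)
  }
  structure(list(
    U = U, tau_fac_ms = tau_fac_ms, tau_rec_ms = tau_rec_ms,
    u1 = u1 %||% U, n_sites = n_sites,
    quantal_amplitude_mv = quantal_amplitude_mv,
    epsp_rise_ms = epsp_rise_ms, epsp_decay_ms = epsp_decay_ms,
    noise_sd_mv = noise_sd_mv, noise_tau_ms = noise_tau_ms
  ), class = "tm_params")
}

#' Analytic mean per-pulse EPSP amplitudes of the TM model
#'
#' Evaluates the deterministic facilitation-depression recursion at the
#' stated stimulation frequency: between pulses separated by `dt`,
#' `u_{k+1} = U + u_k (1 - U) exp(-dt/tau_fac)` and
#' `R_{k+1} = 1 - (1 - R_k (1 - u_k)) exp(-dt/tau_rec)`, with
#' `u_1 = u1`, `R_1 = 1`.
#'
#' @param params A [tm_params()].
#' @param n_aps Number of pulses.
#' @param frequency_hz Stimulation frequency (Hz).
#' @return List with `amplitudes_mv` (vector A_1..A_k), `u`, `R`, and
#'   `ppr` (= A_2/A_1).
#' @export
tm_mean_amplitudes <- function(params, n_aps = 10, frequency_hz = 10) {
  stopifnot(inherits(params, "tm_params"), n_aps >= 1)
  dt <- 1000 / frequency_hz
  f <- exp(-dt / params$tau_fac_ms)
  r <- exp(-dt / params$tau_rec_ms)
  u <- numeric(n_aps); R <- numeric(n_aps)
  u[1] <- params$u1; R[1] <- 1
  if (n_aps > 1) {
    for (k in 2:n_aps) {
      u[k] <- params$U + u[k - 1] * (1 - params$U) * f
      R[k] <- 1 - (1 - R[k - 1] * (1 - u[k - 1])) * r
    }
  }
  amp <- params$n_sites * params$quantal_amplitude_mv * u * R
  list(amplitudes_mv = amp, u = u, R = R,
       ppr = if (n_aps >= 2) amp[2] / amp[1] else NA_real_)
}

#' Calibrate TM parameters to a target first-pulse amplitude and PPR
#'
#' Solves the analytic recursion for parameters whose mean first-pulse
#' amplitude and paired-pulse ratio equal the targets at the given
#' frequency. Depressing / weakly facilitating targets are met with the
#' single-`U` model (root of a monotone function); strongly facilitating
#' targets beyond the single-`U` bound `1 + exp(-dt/tau_fac)` use the
#' first-pulse utilization override with `u1 = u1_base`.
#'
#' @param target_a1_mv Target analytic first-pulse amplitude (mV).
#' @param target_ppr Target analytic A2/A1.
#' @param tau_fac_ms,tau_rec_ms Time constants held fixed during
#'   calibration.
#' @param frequency_hz Stimulation frequency (Hz).
#' @param u1_base First-pulse release fraction used when the override
#'   route is needed.
#' @param ... Passed on to [tm_params()] (kernel and noise settings).
#' @return A calibrated [tm_params()].
#' @export
tm_calibrate <- function(target_a1_mv, target_ppr,
                         tau_fac_ms = 600, tau_rec_ms = 50,
                         frequency_hz = 10, u1_base = 0.1, ...) {
  dt <- 1000 / frequency_hz
  f <- exp(-dt / tau_fac_ms)
  r <- exp(-dt / tau_rec_ms)
  single_u_ppr <- function(U) (1 + f * (1 - U)) * (1 - U * r)
  if (target_ppr < single_u_ppr(1e-9)) {
    U <- stats::uniroot(function(U) single_u_ppr(U) - target_ppr,
                        c(1e-9, 1 - 1e-9), tol = 1e-12)$root
    u1 <- U
  } else {
    u1 <- u1_base
    R2 <- 1 - u1 * r
    u2 <- target_ppr * u1 / R2
    U <- (u2 - u1 * f) / (1 - u1 * f)
    if (U <= 0 || U > 1) {
      stop(sprintf("target PPR %.3g not reachable with u1_base = %.3g",
                   target_ppr, u1_base), call. = FALSE)
    }
  }
  p <- tm_params(U = U, tau_fac_ms = tau_fac_ms, tau_rec_ms = tau_rec_ms,
                 u1 = u1, n_sites = 1,
                 quantal_amplitude_mv = target_a1_mv / u1, ...)
  p
}

#' Calibrated connection presets
#'
#' TM parameter sets whose analytic first-pulse amplitude and paired-pulse
#' ratio equal the group means reported for layer-6 connections:
#' weak, strongly facilitating connections made by FOXP2+ CT cells
#' (`foxp2_pos`: 0.22 mV, PPR 2.57) split by sublayer
#' (`ct_l6a`: 0.13 mV, 2.78; `ct_l6b`: 0.33 mV, 2.30), and stronger,
#' depressing connections made by FOXP2- CC cells
#' (`foxp2_neg`: 0.51 mV, PPR 0.88).
#'
#' @param name One of `"foxp2_pos"`, `"foxp2_neg"`, `"ct_l6a"`, `"ct_l6b"`.
#' @return A calibrated [tm_params()].
#' @export
tm_preset <- function(name = c("foxp2_pos", "foxp2_neg", "ct_l6a", "ct_l6b")) {
  name <- match.arg(name)
  switch(name,
    foxp2_pos = tm_calibrate(0.22, 2.57, tau_fac_ms = 600, tau_rec_ms = 50),
    ct_l6a    = tm_calibrate(0.13, 2.78, tau_fac_ms = 600, tau_rec_ms = 50),
    ct_l6b    = tm_calibrate(0.33, 2.30, tau_fac_ms = 600, tau_rec_ms = 50),
    foxp2_neg = tm_calibrate(0.51, 0.88, tau_fac_ms = 20, tau_rec_ms = 300)
  )
}

#' Simulate a paired recording with TM synaptic dynamics
#'
#' Each sweep is the superposition of double-exponential EPSP kernels with
#' the analytic per-pulse mean amplitudes, plus correlated Gaussian
#' voltage noise. Ground truth carries the analytic amplitudes and PPR.
#'
#' @param params A [tm_params()].
#' @param n_aps Presynaptic APs per train (>= 2).
#' @param frequency_hz Stimulation frequency (Hz).
#' @param n_sweeps Number of sweeps.
#' @param seed RNG seed.
#' @param phase Phase label applied to all sweeps.
#' @param baseline_vm_mv Resting potential of the postsynaptic trace (mV).
#' @param dt_ms Sampling interval (ms); 0.1 ms = 10 kHz.
#' @param pre_ms Baseline before the first presynaptic AP peak (ms).
#' @param tail_ms Recording after the last pulse (ms).
#' @param onset_jitter_samples Maximum uniform integer-sample jitter added
#'   to each sweep's absolute timing (annotations shifted consistently).
#' @return List with `paired` ([paired_sweep_set()]) and `ground_truth`
#'   (analytic `amplitudes_mv`, `ppr`, `u`, `R`).
#' @export
simulate_connection <- function(params, n_aps = 10, frequency_hz = 10,
                                n_sweeps = 40, seed = 1L,
                                phase = "baseline", baseline_vm_mv = -70,
                                dt_ms = 0.1, pre_ms = 100, tail_ms = 150,
                                onset_jitter_samples = 0) {
  stopifnot(inherits(params, "tm_params"), n_aps >= 2)
  ipi <- 1000 / frequency_hz
  if (params$epsp_decay_ms >= 5 * ipi) {
    warning("EPSP decay >= 5x inter-pulse interval; per-pulse amplitudes ",
            "are ill-defined", call. = FALSE)
  }
  gt <- tm_mean_amplitudes(params, n_aps, frequency_hz)
  total_ms <- pre_ms + (n_aps - 1) * ipi + tail_ms
  n <- floor(total_ms / dt_ms) + 1L
  time_ms <- (seq_len(n) - 1L) * dt_ms
  pulse_t <- pre_ms + (seq_len(n_aps) - 1) * ipi

  # unit-peak double-exponential kernel
  tr <- params$epsp_rise_ms; td <- params$epsp_decay_ms
  tp <- (td * tr / (td - tr)) * log(td / tr)
  knorm <- exp(-tp / td) - exp(-tp / tr)
  kernel <- function(t) {
    out <- numeric(length(t))
    pos <- t > 0
    out[pos] <- (exp(-t[pos] / td) - exp(-t[pos] / tr)) / knorm
    out
  }
  clean <- rep(baseline_vm_mv, n)
  for (k in seq_len(n_aps)) {
    clean <- clean + gt$amplitudes_mv[k] * kernel(time_ms - pulse_t[k])
  }

  set.seed(seed)
  edt <- exp(-dt_ms / params$noise_tau_ms)
  sde <- sqrt(1 - edt^2)
  sweeps <- vector("list", n_sweeps)
  for (s in seq_len(n_sweeps)) {
    jit <- if (onset_jitter_samples > 0) {
      sample.int(onset_jitter_samples + 1L, 1L) - 1L
    } else 0L
    v <- clean
    if (params$noise_sd_mv > 0) {
      eps <- stats::rnorm(n)
      ou <- as.numeric(stats::filter(params$noise_sd_mv * sde * eps,
                                     edt, method = "recursive"))
      v <- v + ou
    }
    sweeps[[s]] <- list(
      presyn_ap_peak_ms = pulse_t + jit * dt_ms,
      voltage_mv = v,
      dt_ms = dt_ms,
      time_ms = time_ms + jit * dt_ms
    )
  }
  list(
    paired = paired_sweep_set(sweeps, stimulation_hz = frequency_hz,
                              n_aps_per_train = n_aps, phase = phase),
    ground_truth = gt
  )
}
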