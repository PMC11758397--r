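#' Drug-application response parameters
#'
#' Generative model for a bath-application experiment: a stable baseline,
#' an exponential-saturating membrane-potential excursion of signed
#' amplitude `delta_vm_mv` during application, exponential relaxation
#' after washout begins, and slow correlated voltage noise.
#'
#' @param baseline_vm_mv Resting potential (mV).
#' @param delta_vm_mv Signed plateau excursion (mV).
#' @param onset_tau_s,offset_tau_s Response onset / relaxation time
#'   constants (s).
#' @param noise_sd_mv Stationary SD of the OU voltage noise (mV).
#' @param noise_tau_s Correlation time of the noise (s); fast synaptic
#'   background fluctuations dominate in vitro, so the default is well
#'   below the 1-s analysis filter.
#' @param spiking_enabled If `TRUE`, action potentials are superimposed
#'   whenever the noise-free response depolarises past `spike_threshold_mv`
#'   (emulating recordings without TTX).
#' @param spike_threshold_mv Depolarisation threshold for superimposed
#'   firing (mV).
#' @return An object of class `drug_response_params`.
#' @export
drug_response_params <- function(baseline_vm_mv = -70, delta_vm_mv = 0,
                                 onset_tau_s = 15, offset_tau_s = 60,
                                 noise_sd_mv = 0.3, noise_tau_s = 0.02,
                                 spiking_enabled = FALSE,
                                 spike_threshold_mv = -45) {
  if (noise_sd_mv < 0) stop("noise_sd_mv must be >= 0", call. = FALSE)
  structure(list(
    baseline_vm_mv = baseline_vm_mv, delta_vm_mv = delta_vm_mv,
    onset_tau_s = onset_tau_s, offset_tau_s = offset_tau_s,
    noise_sd_mv = noise_sd_mv, noise_tau_s = noise_tau_s,
    spiking_enabled = isTRUE(spiking_enabled),
    spike_threshold_mv = spike_threshold_mv
  ), class = "drug_response_params")
}

#' Simulate a drug-application trace
#'
#' @param params A [drug_response_params()].
#' @param duration_s Total recording length (s); must cover >= 180 s of
#'   baseline plus the application window.
#' @param seed RNG seed.
#' @param onset_s,offset_s Application window (s).
#' @param fs_hz Sampling rate (Hz). Bath-application responses evolve over
#'   tens of seconds, so traces are generated at a reduced rate.
#' @param ttx_present Stored on the trace; when `params$spiking_enabled`
#'   is `TRUE` this is forced to `FALSE`.
#' @param drug_label Label stored on the trace.
#' @return List with `trace` ([drug_trace()]) and `ground_truth`
#'   (list: `delta_vm_mv`, `spike_times_ms`).
#' @export
simulate_drug_application <- function(params, duration_s = 480, seed = 1L,
                                      onset_s = 240, offset_s = onset_s + 120,
                                      fs_hz = 50, ttx_present = TRUE,
                                      drug_label = "ACh 30 uM") {
  stopifnot(inherits(params, "drug_response_params"))
  if (onset_s < 180) stop("need >= 180 s of baseline before onset", call. = FALSE)
  if (duration_s < offset_s) stop("duration must cover the application window",
                                  call. = FALSE)
  dt_s <- 1 / fs_hz
  n <- floor(duration_s * fs_hz) + 1L
  t_s <- (seq_len(n) - 1L) * dt_s

  resp <- numeric(n)
  during <- t_s >= onset_s & t_s < offset_s
  after <- t_s >= offset_s
  resp[during] <- params$delta_vm_mv *
    (1 - exp(-(t_s[during] - onset_s) / params$onset_tau_s))
  d_off <- params$delta_vm_mv * (1 - exp(-(offset_s - onset_s) / params$onset_tau_s))
  resp[after] <- d_off * exp(-(t_s[after] - offset_s) / params$offset_tau_s)
  clean <- params$baseline_vm_mv + resp

  set.seed(seed)
  v <- clean
  if (params$noise_sd_mv > 0) {
    edt <- exp(-dt_s / params$noise_tau_s)
    sde <- sqrt(1 - edt^2)
    eps <- stats::rnorm(n)
    v <- v + as.numeric(stats::filter(params$noise_sd_mv * sde * eps,
                                      edt, method = "recursive"))
  }
  spike_times_ms <- numeric(0)
  if (params$spiking_enabled) {
    ttx_present <- FALSE
    hot <- which(clean > params$spike_threshold_mv)
    if (length(hot) > 0) {
      # Poisson firing at 5 Hz while depolarised past threshold
      p_spk <- 5 * dt_s
      spk <- hot[stats::runif(length(hot)) < p_spk]
      v[spk] <- 20  # drawn AP peak
      spike_times_ms <- t_s[spk] * 1000
    }
  }
  trace <- drug_trace(v, dt_ms = dt_s * 1000,
                      application_onset_ms = onset_s * 1000,
                      application_offset_ms = offset_s * 1000,
                      drug_label = drug_label, ttx_present = ttx_present)
  list(trace = trace,
       ground_truth = list(delta_vm_mv = params$delta_vm_mv,
                           spike_times_ms = spike_times_ms))
}
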