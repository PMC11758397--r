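# centered running mean with shrinking windows at the edges
running_mean <- function(v, k) {
  n <- length(v)
  h <- k %/% 2L
  cs <- cumsum(c(0, v))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# running-median filter with a kernel given in seconds
median_filter <- function(v, dt_ms, kernel_s) {
  k <- round(kernel_s * 1000 / dt_ms)
  k <- max(3L, as.integer(k))
  if (k %% 2L == 0L) k <- k + 1L
  if (k >= length(v)) k <- if (length(v) %% 2L == 0L) length(v) - 1L else length(v)
  as.numeric(stats::runmed(v, k, endrule = "median"))
}

#' Baseline stability of a drug-application trace
#'
#' The pre-application baseline qualifies as stable when the fluctuation
#' (max minus min) of the 1-s-median-filtered baseline stays below
#' `max_fluct_mv` (nominally 1 mV over the 3 min preceding application).
#'
#' @param trace A [drug_trace()].
#' @param window_s Baseline window length (s) ending at application onset.
#' @param max_fluct_mv Fluctuation ceiling (mV).
#' @param filter_kernel_s Median-filter kernel (s).
#' @return List with `stable` (logical) and `fluctuation_mv`.
#' @export
baseline_stability <- function(trace, window_s = 180, max_fluct_mv = 1.0,
                               filter_kernel_s = 1) {
  stopifnot(inherits(trace, "drug_trace"))
  t_ms <- (seq_along(trace$voltage_mv) - 1) * trace$dt_ms
  w0 <- trace$application_onset_ms - window_s * 1000
  if (w0 < t_ms[1] - 1e-9) {
    stop("insufficient pre-application baseline for a ", window_s,
         " s window", call. = FALSE)
  }
  # filter the full trace first: shrinking windows at the ends of runmed
  # leave near-raw samples, so filtering the extracted window alone would
  # contaminate the fluctuation estimate at the window edges
  f_all <- median_filter(trace$voltage_mv, trace$dt_ms, filter_kernel_s)
  f <- f_all[t_ms >= w0 & t_ms < trace$application_onset_ms]
  fluct <- max(f) - min(f)
  list(stable = fluct < max_fluct_mv, fluctuation_mv = fluct)
}

#' Drug-induced membrane-potential change
#'
#' The baseline potential is the mean over the last 60 s before
#' application onset. The response is the peak excursion (positive or
#' negative, whichever lies farther from baseline) of the
#' median-filtered trace between onset and `post_offset_s` past the
#' application offset; median filtering suppresses APs and synaptic
#' events before the extremum search. Because the raw extremum of a
#' noisy plateau overestimates the plateau by the expected maximum of
#' the filtered noise over the near-peak stretch, the default estimator
#' subtracts a Monte-Carlo estimate of that inflation, built from the
#' trace's own pre-application baseline noise laid over the smoothed
#' response shape; set `bias_correct = FALSE` for the raw extremum.
#'
#' @param trace A [drug_trace()].
#' @param class_threshold_mv Smallest |delta Vm| classified as a
#'   response (mV); reuses the 1 mV baseline-fluctuation criterion.
#' @param filter_kernel_s Median-filter kernel (s).
#' @param post_offset_s Search extension past application offset (s),
#'   to catch slow responses.
#' @param bias_correct Subtract the baseline-referenced extremum of the
#'   filtered noise (default `TRUE`).
#' @param override_stability Proceed despite an unstable baseline.
#' @param dvdt_spike_threshold_mv Voltage criterion above which samples
#'   count as AP firing during application (used when TTX is absent).
#' @return List (`drug_response_result`): `delta_vm_mv`, `baseline_vm_mv`,
#'   `baseline_stable`, `response_class`, `n_aps_during_application`,
#'   `time_to_peak_s`.
#' @export
delta_vm <- function(trace, class_threshold_mv = 1.0, filter_kernel_s = 1,
                     post_offset_s = 60, bias_correct = TRUE,
                     override_stability = FALSE,
                     dvdt_spike_threshold_mv = 0) {
  stopifnot(inherits(trace, "drug_trace"))
  stab <- baseline_stability(trace, filter_kernel_s = filter_kernel_s)
  if (!stab$stable && !override_stability) {
    stop(sprintf("baseline unstable (fluctuation %.2f mV >= 1 mV); %s",
                 stab$fluctuation_mv,
                 "pass override_stability = TRUE to proceed"), call. = FALSE)
  }
  v <- trace$voltage_mv
  t_ms <- (seq_along(v) - 1) * trace$dt_ms
  onset <- trace$application_onset_ms
  offset <- trace$application_offset_ms

  base_sel <- t_ms >= onset - 60e3 & t_ms < onset
  baseline_vm <- mean(v[base_sel])

  # spike count during application (raw trace, before filtering)
  n_aps <- 0L
  if (!trace$ttx_present) {
    app <- v[t_ms >= onset & t_ms < offset]
    up <- app[-1] >= dvdt_spike_threshold_mv & app[-length(app)] <
      dvdt_spike_threshold_mv
    n_aps <- sum(up)
  }

  f <- median_filter(v, trace$dt_ms, filter_kernel_s)
  win <- which(t_ms >= onset & t_ms <= offset + post_offset_s * 1000)
  fw <- f[win]
  i_max <- which.max(fw); i_min <- which.min(fw)
  exc_pos <- fw[i_max] - baseline_vm
  exc_neg <- fw[i_min] - baseline_vm
  if (abs(exc_pos) >= abs(exc_neg)) {
    d <- exc_pos; peak_i <- win[i_max]
  } else {
    d <- exc_neg; peak_i <- win[i_min]
  }

  if (bias_correct) {
    # The extremum of the filtered noisy trace overshoots the response
    # peak by the expected maximum of the filtered noise over the
    # near-peak stretch. Estimate that inflation by Monte Carlo: smooth
    # the windowed trace heavily (45 s running mean) to get the response
    # shape with the residual noise averaged out, add circularly shifted
    # filtered-baseline noise segments, and average how far the extremum
    # moves beyond the shape's own extremum. Subtract that inflation.
    bstart <- max(t_ms[1], onset - 180e3)
    fb <- f[t_ms >= bstart & t_ms < onset]
    eta <- fb - mean(fb)
    ksm <- max(3L, as.integer(round(20e3 / trace$dt_ms)))
    shape <- running_mean(fw, ksm)
    nb <- length(eta)
    nw <- length(fw)
    m_rep <- 32L
    offs <- floor((seq_len(m_rep) - 1) * nb / m_rep)
    inflation <- function(noise_pool) {
      mean(vapply(offs, function(o) {
        idx <- ((o + seq_len(nw) - 1L) %% nb) + 1L
        if (d >= 0) max(shape + noise_pool[idx]) - max(shape)
        else min(shape) - min(shape + noise_pool[idx])
      }, numeric(1)))
    }
    # first-order term: filtered noise on top of the smoothed shape;
    # second-order term: the residual noise the shape itself retains
    # (the same statistic evaluated with the noise smoothed like the
    # shape), which the first term misses
    corr <- inflation(eta) + inflation(running_mean(eta, ksm))
    if (d >= 0) d <- max(d - corr, 0) else d <- min(d + corr, 0)
  }

  res <- list(
    delta_vm_mv = d,
    baseline_vm_mv = baseline_vm,
    baseline_stable = stab$stable,
    response_class = classify_response(d, n_aps, class_threshold_mv),
    n_aps_during_application = n_aps,
    time_to_peak_s = (t_ms[peak_i] - onset) / 1000
  )
  class(res) <- "drug_response_result"
  res
}

#' Classify a drug response
#'
#' Spiking takes precedence whenever APs occurred during application;
#' otherwise the response is depolarising or hyperpolarising by the sign
#' of delta Vm when its magnitude reaches the class threshold, and
#' `"none"` below it.
#'
#' @param delta_vm_mv Signed membrane-potential change (mV).
#' @param n_aps Number of APs during application.
#' @param class_threshold_mv Magnitude threshold (mV).
#' @return One of `"spiking"`, `"depolarizing"`, `"hyperpolarizing"`,
#'   `"none"`.
#' @export
classify_response <- function(delta_vm_mv, n_aps = 0,
                              class_threshold_mv = 1.0) {
  if (n_aps >= 1) return("spiking")
  if (abs(delta_vm_mv) < class_threshold_mv) return("none")
  if (delta_vm_mv > 0) "depolarizing" else "hyperpolarizing"
}

#' Fraction of neurons showing a given response class
#'
#' @param results List of [delta_vm()] results (or character vector of
#'   classes).
#' @param class_of_interest Response class to count.
#' @return List with `fraction`, `numerator`, `denominator`.
#' @export
responder_fraction <- function(results, class_of_interest) {
  if (length(results) == 0L) stop("empty result list", call. = FALSE)
  classes <- if (is.character(results)) results else {
    vapply(results, function(r) r$response_class, character(1))
  }
  k <- sum(classes == class_of_interest)
  list(fraction = k / length(classes), numerator = k,
       denominator = length(classes))
}
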