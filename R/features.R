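#' Detect action potentials in a sweep
#'
#' Threshold criterion: the AP threshold is the first sample at which the
#' centered-difference dV/dt crosses `dvdt_threshold` upward before the
#' AP peak. For each event, the fast-afterhyperpolarisation (fAHP) trough
#' is the voltage minimum between the AP peak and the next event's
#' threshold (or the step offset / trace end). Half-width is the time
#' between the two half-amplitude crossings, linearly interpolated
#' between samples, with half-amplitude measured between threshold and
#' peak voltage.
#'
#' @param sweep A [sweep_recording()].
#' @param dvdt_threshold dV/dt criterion (mV/ms).
#' @param min_amplitude_mv Minimum threshold-to-peak amplitude for a
#'   candidate event to count as an AP (rejects noise crossings).
#' @param search_end_ms Optional end of the trough-search window
#'   (typically the step offset).
#' @return Data frame of events, ordered in time, with columns
#'   `threshold_time_ms`, `threshold_vm_mv`, `peak_time_ms`, `peak_vm_mv`,
#'   `half_width_ms`, `fahp_trough_time_ms`, `fahp_trough_vm_mv`.
#'   Zero rows for subthreshold sweeps.
#' @export
detect_aps <- function(sweep, dvdt_threshold = 20, min_amplitude_mv = 20,
                       search_end_ms = NULL) {
  stopifnot(inherits(sweep, "sweep_recording"), dvdt_threshold > 0)
  v <- sweep$voltage_mv
  t <- sweep$time_ms
  n <- length(v)
  dt <- sweep$dt_ms
  dvdt <- c(NA, (v[3:n] - v[1:(n - 2)]) / (2 * dt), NA)
  up <- which(dvdt[-1] >= dvdt_threshold & dvdt[-n] < dvdt_threshold) + 1L

  empty <- data.frame(threshold_time_ms = numeric(0),
                      threshold_vm_mv = numeric(0),
                      peak_time_ms = numeric(0), peak_vm_mv = numeric(0),
                      half_width_ms = numeric(0),
                      fahp_trough_time_ms = numeric(0),
                      fahp_trough_vm_mv = numeric(0))
  if (length(up) == 0L) return(empty)

  events <- list()
  last_peak <- 0L
  for (i in up) {
    if (i <= last_peak) next
    # first local maximum at/after the crossing
    j <- i
    while (j < n && v[j + 1] > v[j]) j <- j + 1L
    if (j == i && v[i] <= v[max(i - 1L, 1L)]) next  # not rising
    if (v[j] - v[i] < min_amplitude_mv) next
    events[[length(events) + 1L]] <- c(th = i, pk = j)
    last_peak <- j
  }
  if (length(events) == 0L) return(empty)
  thr_idx <- vapply(events, `[`, numeric(1), "th")
  pk_idx <- vapply(events, `[`, numeric(1), "pk")

  end_idx <- if (is.null(search_end_ms)) n else {
    max(which(t <= search_end_ms))
  }
  k <- length(events)
  trough_idx <- integer(k)
  for (e in seq_len(k)) {
    lo <- pk_idx[e] + 1L
    hi <- if (e < k) thr_idx[e + 1] - 1L else end_idx
    if (hi <= lo) { trough_idx[e] <- NA_integer_; next }
    trough_idx[e] <- lo - 1L + which.min(v[lo:hi])
  }

  half_width <- vapply(seq_len(k), function(e) {
    i <- thr_idx[e]; j <- pk_idx[e]
    half <- (v[i] + v[j]) / 2
    # upward crossing between threshold and peak
    seg <- i:j
    a <- seg[which(v[seg] >= half)[1]]
    t_up <- if (a == i) t[i] else {
      t[a - 1] + (half - v[a - 1]) / (v[a] - v[a - 1]) * dt
    }
    # downward crossing after peak
    lim <- if (e < k) thr_idx[e + 1] else n
    b <- j
    while (b < lim && v[b] > half) b <- b + 1L
    if (v[b] > half) return(NA_real_)
    t_dn <- t[b - 1] + (v[b - 1] - half) / (v[b - 1] - v[b]) * dt
    t_dn - t_up
  }, numeric(1))

  data.frame(
    threshold_time_ms = t[thr_idx],
    threshold_vm_mv = v[thr_idx],
    peak_time_ms = t[pk_idx],
    peak_vm_mv = v[pk_idx],
    half_width_ms = half_width,
    fahp_trough_time_ms = ifelse(is.na(trough_idx), NA_real_, t[trough_idx]),
    fahp_trough_vm_mv = ifelse(is.na(trough_idx), NA_real_, v[trough_idx])
  )
}

ap_counts <- function(sweepset, dvdt_threshold = 20) {
  onset <- sweepset$protocol$step_onset_ms
  offset <- onset + sweepset$protocol$step_duration_ms
  vapply(sweepset$sweeps, function(sw) {
    ev <- detect_aps(sw, dvdt_threshold, search_end_ms = offset)
    sum(ev$peak_time_ms >= onset & ev$peak_time_ms <= offset)
  }, numeric(1))
}

#' Passive membrane properties from subthreshold sweeps
#'
#' Resting potential is the mean pre-stimulus voltage; input resistance
#' is the slope of the steady-state voltage deflection against injected
#' current over all subthreshold sweeps; the membrane time constant is a
#' single-exponential fit to the onset of the smallest hyperpolarising
#' response (fit window: onset to 3x an initial 63%-crossing guess); sag
#' is the trough-versus-steady-state fraction of the trough deflection on
#' the largest hyperpolarising sweep, with steady state taken as the mean
#' of the last 100 ms of the step.
#'
#' @param sweepset A [sweep_set()].
#' @param dvdt_threshold Passed to AP detection to identify subthreshold
#'   sweeps.
#' @return List with `v_rest_mv`, `r_in_mohm`, `tau_m_ms`, `sag_pct`,
#'   and `flags` (character vector; contains `"nonlinear_iv"` when the
#'   deflection-current correlation has |r| < 0.9).
#' @export
passive_properties <- function(sweepset, dvdt_threshold = 20) {
  stopifnot(inherits(sweepset, "sweep_set"))
  proto <- sweepset$protocol
  onset <- proto$step_onset_ms
  offset <- onset + proto$step_duration_ms
  amps <- proto$step_amplitudes_pa
  counts <- ap_counts(sweepset, dvdt_threshold)
  sub <- which(counts == 0)
  if (length(sub) < 2L) {
    stop("need >= 2 subthreshold sweeps for passive properties", call. = FALSE)
  }
  flags <- character(0)

  base_of <- function(sw) mean(sw$voltage_mv[sw$time_ms < onset])
  ss_of <- function(sw) {
    mean(sw$voltage_mv[sw$time_ms >= offset - 100 & sw$time_ms < offset])
  }
  v_rest <- mean(vapply(sweepset$sweeps, base_of, numeric(1)))

  dv <- vapply(sweepset$sweeps[sub], function(sw) ss_of(sw) - base_of(sw),
               numeric(1))
  ii <- amps[sub]
  fit <- stats::lm(dv ~ ii)
  r_in <- unname(stats::coef(fit)[2]) * 1000  # mV/pA -> MOhm
  if (abs(stats::cor(dv, ii)) < 0.9) flags <- c(flags, "nonlinear_iv")

  hyper <- sub[amps[sub] < 0]
  if (length(hyper) == 0L) {
    stop("no hyperpolarising subthreshold sweeps", call. = FALSE)
  }
  # tau from the smallest (least negative) hyperpolarising response
  sm <- hyper[which.max(amps[hyper])]
  sw <- sweepset$sweeps[[sm]]
  b0 <- base_of(sw); ssv <- ss_of(sw)
  sel <- sw$time_ms >= onset & sw$time_ms < offset
  tt <- sw$time_ms[sel] - onset
  vv <- sw$voltage_mv[sel]
  # initial guess from the 63% crossing
  target <- b0 + 0.632 * (ssv - b0)
  cross <- if (ssv < b0) which(vv <= target)[1] else which(vv >= target)[1]
  tau_guess <- if (is.na(cross)) 20 else max(tt[cross], 2 * sw$dt_ms)
  win <- tt <= max(3 * tau_guess, 30)
  tau_m <- tryCatch({
    fit2 <- stats::nls(vv[win] ~ vinf + (b0 - vinf) * exp(-tt[win] / tau),
                       start = list(vinf = ssv, tau = tau_guess),
                       control = stats::nls.control(warnOnly = TRUE))
    unname(stats::coef(fit2)["tau"])
  }, error = function(e) {
    # fall back to the 63%-crossing estimate on pathological traces
    flags <<- c(flags, "tau_fit_fallback")
    tau_guess
  })

  # sag on the largest hyperpolarising sweep
  lg <- hyper[which.min(amps[hyper])]
  sw <- sweepset$sweeps[[lg]]
  b0 <- base_of(sw); ssv <- ss_of(sw)
  sel <- sw$time_ms >= onset & sw$time_ms < offset
  trough <- min(sw$voltage_mv[sel])
  sag <- if (trough < ssv && trough < b0) {
    100 * (trough - ssv) / (trough - b0)
  } else 0
  sag <- min(max(sag, 0), 100)

  list(v_rest_mv = v_rest, r_in_mohm = r_in, tau_m_ms = tau_m,
       sag_pct = sag, flags = flags)
}

#' Rheobase: smallest step current eliciting at least one AP
#'
#' @param sweepset A [sweep_set()].
#' @param dvdt_threshold AP detection criterion (mV/ms).
#' @return List with `rheobase_pa`, `sweep_index`, and `sweep` (the
#'   rheobase sweep itself).
#' @export
rheobase <- function(sweepset, dvdt_threshold = 20) {
  counts <- ap_counts(sweepset, dvdt_threshold)
  idx <- which(counts > 0)
  if (length(idx) == 0L) stop("no suprathreshold sweep in set", call. = FALSE)
  i <- idx[1]
  list(rheobase_pa = sweepset$protocol$step_amplitudes_pa[i],
       sweep_index = i, sweep = sweepset$sweeps[[i]])
}

#' Single-AP features from the rheobase sweep
#'
#' All fields refer to the first AP of the sweep: latency is measured
#' from step onset to the AP threshold; amplitude is peak minus threshold
#' voltage; the fAHP amplitude is threshold minus trough voltage and the
#' fAHP latency runs from the threshold to the trough.
#'
#' @param rheobase_sweep The rheobase sweep ([sweep_recording()]).
#' @param step_onset_ms Step onset time (ms).
#' @param step_offset_ms Step offset time (ms); bounds the trough search.
#' @param dvdt_threshold AP detection criterion (mV/ms).
#' @return List with `ap_threshold_mv`, `ap_amplitude_mv`,
#'   `ap_half_width_ms`, `ap_latency_ms`, `fahp_amplitude_mv`,
#'   `fahp_latency_ms`, `flags`.
#' @export
single_ap_features <- function(rheobase_sweep, step_onset_ms,
                               step_offset_ms = NULL, dvdt_threshold = 20) {
  ev <- detect_aps(rheobase_sweep, dvdt_threshold,
                   search_end_ms = step_offset_ms)
  if (nrow(ev) == 0L) stop("no AP in rheobase sweep", call. = FALSE)
  e <- ev[1, ]
  flags <- character(0)
  fahp_amp <- e$threshold_vm_mv - e$fahp_trough_vm_mv
  fahp_lat <- e$fahp_trough_time_ms - e$threshold_time_ms
  if (is.na(e$fahp_trough_vm_mv)) {
    flags <- c(flags, "fahp_undetectable")
    fahp_amp <- NA_real_; fahp_lat <- NA_real_
  }
  list(
    ap_threshold_mv = e$threshold_vm_mv,
    ap_amplitude_mv = e$peak_vm_mv - e$threshold_vm_mv,
    ap_half_width_ms = e$half_width_ms,
    ap_latency_ms = e$threshold_time_ms - step_onset_ms,
    fahp_amplitude_mv = fahp_amp,
    fahp_latency_ms = fahp_lat,
    flags = flags
  )
}

#' Select the repetitive-firing analysis sweep
#'
#' The train sweep is the one whose AP count is closest to `target_n`
#' (nominally 10), ties broken toward the lower current. If every
#' suprathreshold sweep has fewer than 4 APs the maximum-count sweep is
#' returned with a flag.
#'
#' @param sweepset A [sweep_set()].
#' @param target_n Target AP count.
#' @param dvdt_threshold AP detection criterion (mV/ms).
#' @return List with `sweep`, `sweep_index`, `ap_count`, `flags`.
#' @export
select_train_sweep <- function(sweepset, target_n = 10, dvdt_threshold = 20) {
  counts <- ap_counts(sweepset, dvdt_threshold)
  supra <- which(counts > 0)
  if (length(supra) == 0L) stop("no suprathreshold sweep", call. = FALSE)
  flags <- character(0)
  if (all(counts[supra] < 4)) {
    i <- supra[which.max(counts[supra])]
    flags <- "all_counts_below_4"
  } else {
    d <- abs(counts[supra] - target_n)
    i <- supra[which(d == min(d))[1]]  # ties: first = lower current
  }
  list(sweep = sweepset$sweeps[[i]], sweep_index = i, ap_count = counts[i],
       flags = flags)
}

#' Repetitive-firing (train) features
#'
#' Initial bursts, doublets or triplets — a leading run of at most three
#' inter-spike intervals each shorter than `burst_isi_max_ms` — are
#' flagged and excluded from the adaptation-ratio and SD-of-ISIs
#' indexing: after re-indexing the remaining intervals, the adaptation
#' ratio is the last ISI over the 3rd and the SD of ISIs is the sample
#' standard deviation of ISI 3 through ISI 9 (or through the last
#' available ISI). `isi1..isi3` and the per-AP amplitude/half-width
#' fields are reported on the raw train including any burst. The AHP
#' change is the trough-voltage difference between the last and the
#' first AP (negative when the last trough is deeper). The maximum
#' firing frequency is the largest AP count across sweeps during the
#' step, expressed in Hz.
#'
#' @param train_sweep The selected train sweep.
#' @param sweepset The full [sweep_set()] (for max firing frequency and
#'   F-I slope).
#' @param burst_isi_max_ms Burst ISI criterion (ms).
#' @param dvdt_threshold AP detection criterion (mV/ms).
#' @return Named list of train features plus `burst_flags` and `flags`.
#' @export
train_features <- function(train_sweep, sweepset, burst_isi_max_ms = 15,
                           dvdt_threshold = 20) {
  proto <- sweepset$protocol
  onset <- proto$step_onset_ms
  offset <- onset + proto$step_duration_ms
  ev <- detect_aps(train_sweep, dvdt_threshold, search_end_ms = offset)
  ev <- ev[ev$peak_time_ms >= onset & ev$peak_time_ms <= offset, ]
  if (nrow(ev) < 4L) {
    stop("train sweep has < 4 APs; use a larger current step", call. = FALSE)
  }
  flags <- character(0)
  isis <- diff(ev$peak_time_ms)
  # leading run of <= 3 short ISIs marks an initial burst
  burst_flags <- rep(FALSE, length(isis))
  i <- 1L
  while (i <= min(3L, length(isis)) && isis[i] < burst_isi_max_ms) {
    burst_flags[i] <- TRUE
    i <- i + 1L
  }
  post <- isis[!seq_along(isis) %in% which(burst_flags)]

  adaptation_ratio <- if (length(post) >= 3) post[length(post)] / post[3] else {
    flags <- c(flags, "too_few_isis_for_adaptation")
    NA_real_
  }
  sd_isis <- if (length(post) >= 4) {
    stats::sd(post[3:min(9, length(post))])
  } else {
    flags <- c(flags, "too_few_isis_for_sd")
    NA_real_
  }

  counts <- ap_counts(sweepset, dvdt_threshold)
  max_ff <- max(counts) / (proto$step_duration_ms / 1000)

  fi <- fi_slope(sweepset, dvdt_threshold)
  pick <- function(x, i) if (length(x) >= i) x[i] else NA_real_
  amp <- ev$peak_vm_mv - ev$threshold_vm_mv
  fahp_amp <- ev$threshold_vm_mv - ev$fahp_trough_vm_mv
  nlast <- nrow(ev)
  out <- list(
    max_firing_freq_hz = max_ff,
    fi_slope_aps_per_100pa = fi$slope,
    adaptation_ratio = adaptation_ratio,
    sd_isis_ms = sd_isis,
    isi1_ms = pick(isis, 1), isi2_ms = pick(isis, 2), isi3_ms = pick(isis, 3),
    ap1_amplitude_mv = pick(amp, 1), ap2_amplitude_mv = pick(amp, 2),
    ap3_amplitude_mv = pick(amp, 3),
    ap1_half_width_ms = pick(ev$half_width_ms, 1),
    ap2_half_width_ms = pick(ev$half_width_ms, 2),
    ap3_half_width_ms = pick(ev$half_width_ms, 3),
    ap1_threshold_mv = pick(ev$threshold_vm_mv, 1),
    ap9_threshold_mv = pick(ev$threshold_vm_mv, 9),
    fahp1_amplitude_mv = pick(fahp_amp, 1),
    fahp9_amplitude_mv = pick(fahp_amp, 9),
    ahp_change_mv = ev$fahp_trough_vm_mv[nlast] - ev$fahp_trough_vm_mv[1],
    n_aps = nlast,
    burst_flags = burst_flags,
    flags = c(flags, fi$flags)
  )
  out
}

#' Slope of the frequency-current (F-I) curve
#'
#' Ordinary least-squares slope of AP count against injected current over
#' all suprathreshold steps, scaled to APs per 100 pA.
#'
#' @param sweepset A [sweep_set()].
#' @param dvdt_threshold AP detection criterion (mV/ms).
#' @return List with `slope` (APs/100 pA; `NA` with a flag when fewer
#'   than 3 suprathreshold sweeps exist) and `flags`.
#' @export
fi_slope <- function(sweepset, dvdt_threshold = 20) {
  counts <- ap_counts(sweepset, dvdt_threshold)
  supra <- which(counts > 0)
  if (length(supra) < 3L) {
    return(list(slope = NA_real_, flags = "fi_slope_too_few_points"))
  }
  x <- sweepset$protocol$step_amplitudes_pa[supra]
  y <- counts[supra]
  list(slope = unname(stats::coef(stats::lm(y ~ x))[2]) * 100,
       flags = character(0))
}

#' Extract the full per-neuron feature record
#'
#' Convenience wrapper running passive, rheobase/single-AP and train
#' feature extraction on one sweep set and returning a flat one-row data
#' frame (scalar fields only).
#'
#' @param sweepset A [sweep_set()].
#' @param dvdt_threshold AP detection criterion (mV/ms).
#' @param burst_isi_max_ms Burst ISI criterion (ms).
#' @return One-row data frame of features.
#' @export
extract_features <- function(sweepset, dvdt_threshold = 20,
                             burst_isi_max_ms = 15) {
  proto <- sweepset$protocol
  pp <- passive_properties(sweepset, dvdt_threshold)
  rh <- rheobase(sweepset, dvdt_threshold)
  sap <- single_ap_features(rh$sweep, proto$step_onset_ms,
                            proto$step_onset_ms + proto$step_duration_ms,
                            dvdt_threshold)
  ts <- select_train_sweep(sweepset, 10, dvdt_threshold)
  tf <- tryCatch(
    train_features(ts$sweep, sweepset, burst_isi_max_ms, dvdt_threshold),
    error = function(e) NULL)
  rec <- c(
    list(v_rest_mv = pp$v_rest_mv, r_in_mohm = pp$r_in_mohm,
         tau_m_ms = pp$tau_m_ms, sag_pct = pp$sag_pct,
         rheobase_pa = rh$rheobase_pa),
    sap[setdiff(names(sap), "flags")],
    if (!is.null(tf)) tf[setdiff(names(tf), c("burst_flags", "flags"))]
  )
  as.data.frame(rec[vapply(rec, function(x)
    is.numeric(x) && length(x) == 1L, logical(1))])
}
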