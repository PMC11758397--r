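test_that("AP detection matches simulator event logs on noise-free sweeps", {
  proto <- step_protocol(seq(-100, 400, by = 50))
  for (nm in c("ct_l6a", "ct_l6b", "cc_burst_rapid", "cc_multipolar_slow")) {
    p <- phenotype_preset(nm)$adex
    p$noise_sigma_pa <- 0
    sim <- simulate_adex(p, proto, seed = 1)
    off <- proto$step_onset_ms + proto$step_duration_ms
    for (i in seq_along(sim$sweepset$sweeps)) {
      ev <- detect_aps(sim$sweepset$sweeps[[i]], search_end_ms = off)
      expect_identical(nrow(ev), sim$ground_truth$spike_counts[[i]],
                       label = sprintf("%s sweep %d", nm, i))
    }
  }
})

test_that("flat traces and constructed waveforms localise the threshold", {
  flat <- sweep_recording(seq(0, 500, 0.1), rep(-70, 5001), 0)
  expect_identical(nrow(detect_aps(flat)), 0L)
  sw <- make_triangle_spike_sweep()
  ev <- detect_aps(sw)
  expect_identical(nrow(ev), 1L)
  # dV/dt crosses 20 mV/ms where the steep rise starts, at t = 100
  expect_lt(abs(ev$threshold_time_ms - 100), 2 * sweep_dt(sw))
  expect_equal(ev$peak_vm_mv, 50, tolerance = 0.1)
})

test_that("triangle geometry fixes amplitude, half-width and fAHP fields", {
  sw <- make_triangle_spike_sweep()
  feats <- single_ap_features(sw, step_onset_ms = 0)
  expect_equal(feats$ap_amplitude_mv, 90, tolerance = 0.2)
  # half-amplitude chord of a symmetric triangle is half its 2 ms base
  expect_equal(feats$ap_half_width_ms, 1.0, tolerance = 0.02)
  expect_equal(feats$fahp_amplitude_mv, -40 - (-52), tolerance = 0.2)
  expect_equal(feats$ap_latency_ms, 100, tolerance = 0.2)
  # fAHP latency = trough time - threshold time
  ev <- detect_aps(sw)
  expect_equal(feats$fahp_latency_ms,
               ev$fahp_trough_time_ms - ev$threshold_time_ms)
})

test_that("passive properties are recovered within 2% on analytic RC traces", {
  ss <- make_rc_sweepset(r_mohm = 200, tau_ms = 20, amps_pa = c(-50, -25, 25))
  pp <- passive_properties(ss)
  expect_equal(pp$v_rest_mv, -70, tolerance = 1e-6)
  expect_lt(abs(pp$r_in_mohm - 200) / 200, 0.02)
  expect_lt(abs(pp$tau_m_ms - 20) / 20, 0.02)
  expect_equal(pp$sag_pct, 0, tolerance = 0.5)
  expect_error(passive_properties(sweep_set(step_protocol(c(25)),
    list(make_rc_sweepset(amps_pa = c(25))$sweeps[[1]]))), "subthreshold")
})

test_that("sag follows the trough/steady-state definition on a built trace", {
  # trough -90, steady state -88, baseline -70 -> 10 %
  t <- seq(0, 1300, 0.1)
  v <- rep(-70, length(t))
  on <- t >= 200 & t < 1200
  v[on] <- -88 - 2 * exp(-(t[on] - 200) / 60) * (1 - exp(-(t[on] - 200) / 5)) * 4.1
  # shape the trace so its minimum is exactly -90 and late plateau -88
  v[on][v[on] < -90] <- -90
  proto <- step_protocol(c(-100, -50), 200, 1000)
  sw1 <- sweep_recording(t, v, -100)
  v2 <- rep(-70, length(t)); v2[on] <- -80
  sw2 <- sweep_recording(t, v2, -50)
  ss <- sweep_set(proto, list(sw1, sw2))
  pp <- passive_properties(ss)
  expect_equal(pp$sag_pct, 100 * (-90 + 88) / (-90 + 70), tolerance = 1)
})

test_that("rheobase is the smallest suprathreshold step", {
  p <- adex_params(C_pf = 200, gL_ns = 10, EL_mv = -70, VT_mv = -50,
                   DeltaT_mv = 2)  # analytic rheobase 180 pA
  proto <- step_protocol(seq(-100, 300, by = 10), 200, 1000)
  sim <- simulate_adex(p, proto, seed = 1)
  rh <- rheobase(sim$sweepset)
  expect_gte(rh$rheobase_pa, eif_rheobase(p))
  expect_lte(rh$rheobase_pa, eif_rheobase(p) + 10)
  sub <- simulate_adex(p, step_protocol(c(-50, 50, 100)), seed = 1)
  expect_error(rheobase(sub$sweepset), "no suprathreshold")
})

test_that("train sweep selection targets ~10 APs with lower-current ties", {
  sel_from_counts <- function(counts, amps) {
    proto <- step_protocol(amps, 10, 100)
    t <- seq(0, 150, 0.05)
    sweeps <- lapply(seq_along(amps), function(i) {
      v <- rep(-70, length(t))
      if (counts[i] > 0) {
        at <- 10 + seq_len(counts[i]) * 100 / (counts[i] + 1)
        for (a in at) {
          up <- t >= a & t < a + 0.5
          v[up] <- -45 + (t[up] - a) / 0.5 * 95
          dn <- t >= a + 0.5 & t < a + 1
          v[dn] <- 50 - (t[dn] - a - 0.5) / 0.5 * 100
        }
      }
      sweep_recording(t, v, amps[i])
    })
    select_train_sweep(sweep_set(proto, sweeps))
  }
  expect_identical(sel_from_counts(c(3, 9, 14), c(100, 150, 200))$sweep_index, 2L)
  # |8-10| = |12-10|: tie resolved toward the lower current
  expect_identical(sel_from_counts(c(8, 12), c(100, 150))$sweep_index, 1L)
  expect_identical(sel_from_counts(c(0, 7), c(50, 100))$sweep_index, 2L)
})

test_that("train features follow the stated ISI arithmetic", {
  # construct a train with ISIs 10,20,...,90 ms (peaks via sharp triangles)
  isis <- seq(10, 90, by = 10)
  peaks <- 250 + c(0, cumsum(isis))
  t <- seq(0, 1300, 0.05)
  v <- rep(-70, length(t))
  for (a in peaks) {
    up <- t >= a - 0.5 & t < a
    v[up] <- -45 + (t[up] - (a - 0.5)) / 0.5 * 95
    dn <- t >= a & t < a + 0.5
    v[dn] <- 50 - (t[dn] - a) / 0.5 * 102
  }
  proto <- step_protocol(c(200), 200, 1000)
  ss <- sweep_set(proto, list(sweep_recording(t, v, 200)))
  # burst criterion below ISI1 so the full 10..90 sequence is analysed raw
  tf <- train_features(ss$sweeps[[1]], ss, burst_isi_max_ms = 10)
  expect_equal(tf$adaptation_ratio, 90 / 30, tolerance = 1e-6)
  expect_equal(tf$sd_isis_ms, sd(seq(30, 90, 10)), tolerance = 1e-6)
  expect_equal(sd(seq(30, 90, 10)), sqrt(2800 / 6))  # frozen arithmetic
  expect_equal(tf$isi1_ms, 10, tolerance = 1e-6)
  expect_identical(tf$n_aps, 10L)
  expect_equal(tf$max_firing_freq_hz, 10)
  # troughs all equal here, so the AHP change is ~0
  expect_equal(tf$ahp_change_mv, 0, tolerance = 0.5)
})

test_that("burst ISIs are excluded from adaptation indexing", {
  # leading doublet (5 ms) then regular 50 ms ISIs
  isis <- c(5, rep(50, 8))
  peaks <- 250 + c(0, cumsum(isis))
  t <- seq(0, 1300, 0.05)
  v <- rep(-70, length(t))
  for (a in peaks) {
    up <- t >= a - 0.4 & t < a
    v[up] <- -45 + (t[up] - (a - 0.4)) / 0.4 * 95
    dn <- t >= a & t < a + 0.4
    v[dn] <- 50 - (t[dn] - a) / 0.4 * 102
  }
  proto <- step_protocol(c(200), 200, 1000)
  ss <- sweep_set(proto, list(sweep_recording(t, v, 200)))
  tf <- train_features(ss$sweeps[[1]], ss)
  expect_identical(tf$burst_flags[1], TRUE)
  expect_identical(sum(tf$burst_flags), 1L)
  expect_equal(tf$adaptation_ratio, 1, tolerance = 1e-6)  # 50/50 post-burst
  expect_equal(tf$isi1_ms, 5, tolerance = 1e-6)           # raw ISI kept
})

test_that("F-I slope is exact on collinear counts and flags short data", {
  mk <- function(counts, amps) {
    proto <- step_protocol(amps, 10, 1000)
    t <- seq(0, 1100, 0.05)
    sweeps <- lapply(seq_along(amps), function(i) {
      v <- rep(-70, length(t))
      if (counts[i] > 0) {
        at <- 10 + seq_len(counts[i]) * 1000 / (counts[i] + 1)
        for (a in at) {
          up <- t >= a & t < a + 0.4
          v[up] <- -45 + (t[up] - a) / 0.4 * 95
          dn <- t >= a + 0.4 & t < a + 0.8
          v[dn] <- 50 - (t[dn] - a - 0.4) / 0.4 * 100
        }
      }
      sweep_recording(t, v, amps[i])
    })
    sweep_set(proto, sweeps)
  }
  expect_equal(fi_slope(mk(c(2, 5, 8, 11), c(100, 150, 200, 250)))$slope, 6)
  expect_equal(fi_slope(mk(c(4, 4, 4), c(100, 150, 200)))$slope, 0)
  r <- fi_slope(mk(c(0, 3, 5), c(50, 100, 150)))
  expect_true(is.na(r$slope))
  expect_match(r$flags, "too_few")
})

test_that("features shift correctly under constant voltage offsets", {
  sw <- make_triangle_spike_sweep()
  f0 <- single_ap_features(sw, 0)
  sw2 <- sweep_recording(sw$time_ms, sw$voltage_mv + 7, sw$current_pa)
  f7 <- single_ap_features(sw2, 0)
  expect_equal(f7$ap_threshold_mv, f0$ap_threshold_mv + 7, tolerance = 1e-9)
  expect_equal(f7$ap_amplitude_mv, f0$ap_amplitude_mv, tolerance = 1e-9)
  expect_equal(f7$ap_half_width_ms, f0$ap_half_width_ms, tolerance = 1e-9)
  expect_equal(f7$fahp_amplitude_mv, f0$fahp_amplitude_mv, tolerance = 1e-9)
})

test_that("adaptation ratio is scale-invariant; SD of ISIs scales linearly", {
  isis <- c(12, 25, 31, 44, 58, 63, 71)
  post <- isis  # no burst
  ar <- function(x) x[length(x)] / x[3]
  sdi <- function(x) sd(x[3:min(9, length(x))])
  expect_equal(ar(isis * 3), ar(isis))
  expect_equal(sdi(isis * 3), 3 * sdi(isis))
})
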