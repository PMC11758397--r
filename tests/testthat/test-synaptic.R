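make_epsp_sweep <- function(peak_ms, amp = 0.5, base = -70, dt = 0.1,
                            total = 400, rise = 2, decay = 20,
                            epsp_lat = 1.5) {
  t <- seq(0, total, by = dt)
  tp <- (decay * rise / (decay - rise)) * log(decay / rise)
  knorm <- exp(-tp / decay) - exp(-tp / rise)
  v <- rep(base, length(t))
  tt <- t - peak_ms - epsp_lat
  pos <- tt > 0
  v[pos] <- v[pos] + amp * (exp(-tt[pos] / decay) - exp(-tt[pos] / rise)) / knorm
  list(presyn_ap_peak_ms = c(peak_ms, peak_ms + 100), voltage_mv = v,
       dt_ms = dt, time_ms = t)
}

test_that("aligned averaging preserves amplitude where naive averaging blurs", {
  s1 <- make_epsp_sweep(100)
  s2 <- make_epsp_sweep(103)
  ps <- paired_sweep_set(list(s1, s2), 10, 2)
  m <- align_and_average(ps)
  a_aligned <- epsp_amplitude(m, 1)
  # naive (unaligned) mean of the two traces has a lower peak
  naive <- (s1$voltage_mv + s2$voltage_mv) / 2
  a_naive <- max(naive) - (-70)
  expect_equal(a_aligned, 0.5, tolerance = 0.005)
  expect_lt(a_naive, a_aligned - 0.01)
  # two identical sweeps average to either sweep
  ps2 <- paired_sweep_set(list(s1, s1), 10, 2)
  m2 <- align_and_average(ps2)
  expect_equal(epsp_amplitude(m2, 1), a_aligned, tolerance = 1e-9)
})

test_that("mean amplitude over noisy sweeps sits within the CLT bound", {
  p <- tm_params(U = 0.5, tau_fac_ms = 100, tau_rec_ms = 200,
                 quantal_amplitude_mv = 0.66, noise_sd_mv = 0.1)
  sim <- simulate_connection(p, n_aps = 2, n_sweeps = 40, seed = 31)
  m <- align_and_average(sim$paired)
  expect_lt(abs(epsp_amplitude(m, 1) - sim$ground_truth$amplitudes_mv[1]),
            3 * 0.1 / sqrt(40))
})

test_that("zero-noise TM pulse recovers the kernel peak exactly", {
  p <- tm_params(U = 1, tau_fac_ms = 1, tau_rec_ms = 1e9,
                 quantal_amplitude_mv = 0.33, noise_sd_mv = 0)
  sim <- simulate_connection(p, n_aps = 2, n_sweeps = 1, seed = 1)
  m <- align_and_average(sim$paired)
  # exact up to the 0.1 ms sampling of the analytic kernel maximum
  expect_equal(epsp_amplitude(m, 1), 0.33, tolerance = 1e-4)
})

test_that("PPR arithmetic, noise floor and scale invariance hold", {
  p <- tm_params(U = 1, tau_fac_ms = 1, tau_rec_ms = 1e9, noise_sd_mv = 0,
                 quantal_amplitude_mv = 0.4)
  sim <- simulate_connection(p, n_aps = 2, n_sweeps = 3, seed = 1)
  m <- align_and_average(sim$paired)
  pr <- paired_pulse_ratio(m)
  # A2 ~ 0 up to the 2-ms pulse-local baseline on the decaying first EPSP
  expect_equal(pr$ppr, 0, tolerance = 1e-2)  # full depletion
  # flat zero-amplitude connection: amplitude 0, flagged
  pf <- tm_params(U = 0.5, tau_fac_ms = 100, tau_rec_ms = 100,
                  quantal_amplitude_mv = 0, noise_sd_mv = 0)
  simf <- simulate_connection(pf, n_aps = 2, n_sweeps = 4, seed = 8)
  mf <- align_and_average(simf$paired)
  prf <- paired_pulse_ratio(mf)
  expect_true(prf$below_noise_floor)
  expect_true(is.na(prf$ppr))
  expect_equal(prf$a1_mv, 0, tolerance = 1e-12)
  # multiplying voltages by c > 0 scales A1, leaves the PPR unchanged
  p2 <- tm_preset("foxp2_pos")
  p2$noise_sd_mv <- 0
  sim2 <- simulate_connection(p2, n_aps = 2, n_sweeps = 1, seed = 1)
  m2 <- align_and_average(sim2$paired)
  pr2 <- paired_pulse_ratio(m2)
  sw <- sim2$paired$sweeps[[1]]
  sw$voltage_mv <- (sw$voltage_mv + 70) * 3 - 70
  m3 <- align_and_average(paired_sweep_set(list(sw), 10, 2))
  pr3 <- paired_pulse_ratio(m3)
  expect_equal(pr3$a1_mv, 3 * pr2$a1_mv, tolerance = 1e-9)
  expect_equal(pr3$ppr, pr2$ppr, tolerance = 1e-9)
})

test_that("estimates are invariant to integer-sample acquisition jitter", {
  p <- tm_preset("foxp2_pos")
  p$noise_sd_mv <- 0
  a <- simulate_connection(p, n_sweeps = 8, seed = 4,
                           onset_jitter_samples = 0)
  b <- simulate_connection(p, n_sweeps = 8, seed = 4,
                           onset_jitter_samples = 40)
  ma <- align_and_average(a$paired)
  mb <- align_and_average(b$paired)
  expect_equal(epsp_amplitude(ma, 1), epsp_amplitude(mb, 1),
               tolerance = 1e-9)
  expect_equal(paired_pulse_ratio(ma)$ppr, paired_pulse_ratio(mb)$ppr,
               tolerance = 1e-9)
})

test_that("estimator RMSE shrinks roughly as 1/sqrt(n_sweeps)", {
  p <- tm_preset("foxp2_neg")
  errs <- sapply(c(10, 160), function(ns) {
    e <- sapply(1:6, function(s) {
      sim <- simulate_connection(p, n_sweeps = ns, seed = 100 + s)
      m <- align_and_average(sim$paired)
      epsp_amplitude(m, 1) - sim$ground_truth$amplitudes_mv[1]
    })
    sqrt(mean(e^2))
  })
  expect_lt(errs[2], errs[1])  # 16x sweeps must cut the RMSE clearly
})

test_that("a release-probability change moves amplitude and PPR oppositely", {
  base <- tm_preset("ct_l6b")
  up <- base; up$U <- min(1, base$U * 4); up$u1 <- min(1, base$u1 * 4)
  both <- c(simulate_connection(base, n_sweeps = 20, seed = 11,
                                phase = "baseline")$paired$sweeps,
            simulate_connection(up, n_sweeps = 20, seed = 12,
                                phase = "drug")$paired$sweeps)
  ps <- paired_sweep_set(both, 10, 10,
                         phase = rep(c("baseline", "drug"), each = 20))
  dm <- drug_modulation(ps)
  expect_gt(dm$amplitude_ratio, 1)  # A1 increases with release probability
  expect_lt(dm$ppr_ratio, 1)        # PPR decreases
  dn <- base; dn$u1 <- base$u1 * 0.5
  both2 <- c(simulate_connection(base, n_sweeps = 20, seed = 13)$paired$sweeps,
             simulate_connection(dn, n_sweeps = 20, seed = 14,
                                 phase = "drug")$paired$sweeps)
  ps2 <- paired_sweep_set(both2, 10, 10,
                          phase = rep(c("baseline", "drug"), each = 20))
  dm2 <- drug_modulation(ps2)
  expect_lt(dm2$amplitude_ratio, 1)
  expect_gt(dm2$ppr_ratio, 1)
  expect_error(drug_modulation(simulate_connection(base, n_sweeps = 2,
                                                   seed = 1)$paired),
               "missing phase")
})
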