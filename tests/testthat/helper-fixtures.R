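# Fixtures built in code: analytic RC sweeps, constructed spike
# waveforms, and small helpers shared across the suite.

# ideal RC membrane response to the step protocol: V = EL + I*R*(1 - e^(-t/tau))
make_rc_sweepset <- function(r_mohm = 200, tau_ms = 20, el_mv = -70,
                             amps_pa = c(-50, -25, 25),
                             onset_ms = 200, dur_ms = 1000, dt_ms = 0.1) {
  proto <- step_protocol(amps_pa, onset_ms, dur_ms)
  t <- seq(0, onset_ms + dur_ms + 100, by = dt_ms)
  sweeps <- lapply(seq_along(amps_pa), function(i) {
    amp <- amps_pa[i]
    dv <- amp * r_mohm / 1000  # pA * MOhm -> mV
    v <- rep(el_mv, length(t))
    on <- t >= onset_ms & t < onset_ms + dur_ms
    v[on] <- el_mv + dv * (1 - exp(-(t[on] - onset_ms) / tau_ms))
    off <- t >= onset_ms + dur_ms
    v_end <- el_mv + dv * (1 - exp(-dur_ms / tau_ms))
    v[off] <- el_mv + (v_end - el_mv) * exp(-(t[off] - onset_ms - dur_ms) / tau_ms)
    sweep_recording(t, v, amp, sweep_id = i)
  })
  sweep_set(proto, sweeps)
}

# piecewise-linear AP: gentle ramp to threshold at t = 100 ms, linear rise
# to the peak at 101, symmetric fall to a trough, then flat
make_triangle_spike_sweep <- function(dt_ms = 0.05, threshold_mv = -40,
                                      peak_mv = 50, trough_mv = -52) {
  t <- seq(0, 200, by = dt_ms)
  v <- rep(-70, length(t))
  ramp <- t >= 60 & t < 100
  v[ramp] <- -70 + (t[ramp] - 60) / 40 * (threshold_mv + 70)  # < 1 mV/ms
  up <- t >= 100 & t < 101
  v[up] <- threshold_mv + (t[up] - 100) * (peak_mv - threshold_mv)
  dn <- t >= 101 & t < 102
  v[dn] <- peak_mv - (t[dn] - 101) * (peak_mv - threshold_mv)
  post <- t >= 102
  v[post] <- pmax(threshold_mv - (t[post] - 102) / 1.4 * (threshold_mv - trough_mv),
                  trough_mv)
  sweep_recording(t, v, 0)
}

# brute-force Mann-Whitney U permutation p (two-sided, doubled tail)
brute_force_mwu_p <- function(x, y) {
  n1 <- length(x)
  rk <- rank(c(x, y))
  u_obs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(rk), n1)
  u_perm <- colSums(matrix(rk[combos], nrow = n1)) - n1 * (n1 + 1) / 2
  min(1, 2 * min(mean(u_perm <= u_obs + 1e-9), mean(u_perm >= u_obs - 1e-9)))
}

# brute-force signed-rank p over all sign patterns
brute_force_wsr_p <- function(pre, post) {
  d <- post - pre
  d <- d[d != 0]
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), length(d))))
  w <- as.numeric(signs %*% r)
  min(1, 2 * min(mean(w <= w_obs + 1e-9), mean(w >= w_obs - 1e-9)))
}

# fine-sampling voxelization oracle: subdivide every segment at `step` um
# and assign midpoints to voxels; returns env keyed "i j k" -> length
fine_voxel_oracle <- function(m, ctx, compartment_types, edge = 50,
                              step = 0.1) {
  segs <- segment_lengths(m)
  segs <- segs[segs$type %in% compartment_types & segs$length_um > 0, ]
  soma <- m[m$type == 1, ][1, ]
  sx <- ctx$barrel_center_x_um; sz <- soma$z
  h <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(segs))) {
    n <- max(2, ceiling(segs$length_um[i] / step))
    tt <- (seq_len(n) - 0.5) / n
    px <- segs$x0[i] + tt * (segs$x1[i] - segs$x0[i]) - sx
    py <- segs$y0[i] + tt * (segs$y1[i] - segs$y0[i])
    pz <- segs$z0[i] + tt * (segs$z1[i] - segs$z0[i]) - sz
    key <- paste(floor(px / edge), floor(py / edge), floor(pz / edge))
    tb <- tapply(rep(segs$length_um[i] / n, n), key, sum)
    for (k in names(tb)) {
      prev <- if (exists(k, envir = h, inherits = FALSE)) get(k, envir = h) else 0
      assign(k, prev + tb[[k]], envir = h)
    }
  }
  h
}

map_voxel_at <- function(map, key) {
  ijk <- as.integer(strsplit(key, " ")[[1]])
  idx <- ijk - as.integer(round(map$origin_um / map$voxel_edge_um)) + 1L
  d <- dim(map$values)
  if (any(idx < 1L) || any(idx > d)) return(0)
  map$values[idx[1], idx[2], idx[3]]
}
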