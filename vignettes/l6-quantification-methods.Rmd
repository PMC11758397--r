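---
title: "Quantifying layer-6 neuron physiology and morphology: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying layer-6 neuron physiology and morphology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(l6ephys)
```

## Scope

Deep cortical layer 6 contains two sharply distinct excitatory
populations: FOXP2-expressing corticothalamic (CT) pyramidal cells and
FOXP2-negative corticocortical (CC) neurons. The two classes differ in
firing pattern (a single AP at rheobase with irregular trains versus an
initial burst with regular trains), in synaptic output (weak,
facilitating versus stronger, depressing connections), in neuromodulator
sensitivity (strong cholinergic depolarization of CT cells), and in
morphology (upright pyramids versus inverted and multipolar cells).
`l6ephys` implements the quantification methods used to characterise
these classes — current-clamp feature extraction, paired-recording
synaptic analysis, bath-application response quantification,
SWC morphometry and voxelised length-density maps, and exact rank
statistics — together with a ground-truthed synthetic-data generator for
every stage. Raw recordings of this kind are rarely deposited; the
generator stands in for them, which makes every estimator testable
against a known truth.

## The synthetic-data generator

### Spiking traces: AdEx

Firing phenotypes are emulated with the adaptive exponential
integrate-and-fire model,

$$C\,\dot V = -g_L (V - E_L) + g_L \Delta_T e^{(V - V_T)/\Delta_T} - w + I(t) + \eta(t),
\qquad \tau_w \dot w = a (V - E_L) - w,$$

with reset $V \to V_r$, $w \to w + b$ at the spike cutoff, integrated by
Euler–Maruyama at a fixed 0.025 ms step (spike time = first sample at
the cutoff). $\eta$ is an Ornstein–Uhlenbeck current (SD
`noise_sigma_pa`, correlation `noise_tau_ms`). AdEx was chosen over
simpler phenomenological models because with $a = 0$ the rheobase has
the closed form $I_{rh} = g_L (V_T - E_L - \Delta_T)$, giving the test
suite an analytic oracle for spike/no-spike behaviour.

The four presets fix $g_L$, $C$ and $E_L$ at each group's mean input
resistance, membrane time constant and resting potential. CT presets
(`ct_l6a`, `ct_l6b`) use strong spike-triggered adaptation
($b \approx 80\!-\!90$ pA, $\tau_w = 250$ ms) so exactly one AP appears
at the smallest suprathreshold step, and OU noise ($\sigma = 14\!-\!22$
pA) to produce irregular inter-spike intervals; irregularity is thus a
controlled noise property, not intrinsic chaos. CC presets produce the
initial burst purely through reset dynamics ($V_r$ a few mV above
$V_T$), with low or zero noise for regular trains; the depolarising
afterpotential seen in real CC cells is not modelled. Preset
calibration was done once against the qualitative signatures (single AP
at rheobase; burst with first ISI < 15 ms) and frozen.

### Synaptic trains: Tsodyks–Markram

Mean per-pulse unitary EPSP amplitudes follow the facilitation–
depression recursion with utilisation $u$ and resources $R$:

$$u_{k+1} = U + u_k (1 - U) e^{-\Delta t/\tau_{fac}}, \qquad
R_{k+1} = 1 - \bigl(1 - R_k (1 - u_k)\bigr) e^{-\Delta t/\tau_{rec}},$$

with $A_k \propto u_k R_k$, $u_1 = u_1^{(0)}$, $R_1 = 1$. A structural
property of the single-$U$ recursion is that the paired-pulse ratio is
bounded: $A_2/A_1 = (1 + f(1-U))(1 - U r) < 2$ at any parameter values
(where $f, r$ are the two decay factors). Measured CT connections
facilitate more strongly than that (group-mean PPR 2.57), so the package
decouples the first-pulse utilisation $u_1^{(0)}$ from the facilitation
increment $U$: with $u_1^{(0)} < U$ the recursion reaches any PPR while
remaining the textbook model when $u_1^{(0)} = U$ (the default).
`tm_calibrate()` solves for parameters whose *analytic* $A_1$ and PPR
equal requested targets — a monotone root-find in $U$ for depressing
targets, the $u_1$ override for strongly facilitating ones — and
`tm_preset()` freezes the four study cohorts (0.22 mV / 2.57,
0.51 mV / 0.88, 0.13 mV / 2.78, 0.33 mV / 2.30 at 10 Hz with
$\tau_{fac} = 600$ ms, $\tau_{rec} = 50$ ms for facilitating and
$\tau_{fac} = 20$ ms, $\tau_{rec} = 300$ ms for depressing presets).

Sweeps superpose unit-peak double-exponential kernels (rise 2 ms, decay
20 ms) scaled by the analytic $A_k$, plus OU voltage noise with a 15 ms
correlation time — membrane-filtered background noise rather than white
noise, which matters because the amplitude estimator takes a windowed
maximum and white noise would bias it upward.

### Drug applications and morphologies

Bath-application traces hold a baseline for ≥ 3 min, rise to a plateau
$\Delta V_m (1 - e^{-t/\tau_{on}})$ during application (default
$\tau_{on} = 15$ s, 120 s application) and relax with $\tau_{off}$
afterwards, sampled at 50 Hz — adequate for responses that evolve over
tens of seconds. Noise is OU with a 20 ms correlation time (again the
membrane time-constant scale); slower noise of the same amplitude would
fail the study's own < 1 mV baseline-stability criterion, i.e. it would
not represent recordings that enter the analysis. With
`spiking_enabled`, APs are superimposed at 5 Hz while the noise-free
response is depolarised past threshold, emulating recordings without
TTX.

Morphology archetypes are random branched walks with directional
persistence: `upright_pc` sends an apical trunk with obliques and a
terminal tuft toward the pia, `inverted_pc` points it toward the white
matter, `multipolar` has no apical compartment; all carry basal
dendrites and a descending axon with lateral collaterals. The generator
bookkeeps exact per-compartment cable length from the node table, so
morphometrics and density maps can be tested to machine precision.
Generated cells emulate the geometry and totals of real reconstructions
only coarsely (no diameter taper, spines, or boutons) — passing tests
demonstrate correctness of the measurement code, not biological realism
of the cells.

## Measurement conventions

**Current-clamp features.** AP threshold is the first sample where the
centered-difference dV/dt crosses 20 mV/ms upward before a peak (the
criterion is configurable; published reports rarely state theirs).
Half-width interpolates the two half-amplitude crossings linearly
between samples, with half-amplitude midway between threshold and peak.
The fAHP trough is the minimum between peak and the next threshold or
the step offset; fAHP amplitude is threshold − trough, fAHP latency
threshold → trough. AP latency runs from step onset to *threshold* (not
peak). Passive properties: $R_{in}$ is the OLS slope of steady-state
deflection against current over subthreshold sweeps; $\tau_m$ a
single-exponential fit to the onset of the smallest hyperpolarising
response (fit window 3× a 63 %-crossing initial guess, minimum 30 ms,
with the crossing estimate as fallback if the fit degenerates); sag is
the trough-versus-steady-state fraction of the trough deflection on the
largest hyperpolarising sweep, steady state being the last 100 ms of
the step. Train analysis uses the sweep with AP count closest to 10
(ties toward lower current). A leading run of ≤ 3 ISIs each < 15 ms is
flagged as the initial burst and excluded from adaptation-ratio and
SD-of-ISI indexing (adaptation ratio = last/3rd ISI after the burst; SD
over ISI 3–9), while `isi1..isi3` and per-AP fields report the raw
train. The AHP change is the raw trough-voltage difference last − first
AP (negative when the AHP deepens), whereas per-AP fAHP amplitudes are
threshold-referenced — both conventions are emitted because the
published sign patterns require the former and the amplitude scale the
latter. Maximum firing frequency is count-based (APs per 1 s step).

**Synaptic analysis.** Sweeps are aligned on the first presynaptic AP
peak before averaging; failures are included, so the mean is a
potency-weighted amplitude. Amplitude of pulse $k$ is the maximum of
the mean trace in $(t_k + 1\,\mathrm{ms},\ t_k + \min(\Delta t, 90\,\mathrm{ms}))$
minus a pulse-local baseline — the [−10, −1] ms pre-train window for
pulse 1, the 2 ms immediately before $t_k$ for later pulses (raw
amplitudes on the summating train; decay subtraction exists behind a
flag but is off, matching the published PPR definition). PPR is
computed on the mean trace, not as a mean of per-sweep ratios, which
are unstable when $A_1 \approx 0$; it is flagged undefined when $A_1$
does not exceed 3× the baseline SD of the mean trace.

**Drug responses.** The baseline must fluctuate < 1 mV (max − min of
the 1-s-median-filtered trace) over the 3 min before application; the
filter is applied to the whole trace before windowing because running
medians are edge-contaminated. $\Delta V_m$ is the extremum of the
median-filtered trace (onset → 60 s past offset) farthest from the
60 s pre-onset baseline mean. The raw extremum of a noisy plateau is
biased outward by the expected extremum of the filtered noise — an
effect that does not vanish with averaging and therefore can never meet
a 3-SEM recovery bound. The default estimator removes it by Monte
Carlo: the windowed trace is smoothed (20 s running mean) to an
estimate of the response shape, circularly shifted segments of the
trace's own filtered baseline noise are laid over the shape, and the
mean excess of the perturbed extremum over the shape's extremum —
plus the analogous second-order term for the residual noise the shape
itself retains — is subtracted. The correction uses only the trace
itself and vanishes for noise-free data; `bias_correct = FALSE`
restores the raw extremum. Classification: spiking if any AP falls in
the application window, otherwise by sign when $|\Delta V_m| \ge 1$ mV
(the stability criterion reused as the smallest meaningful excursion —
the boundary between "weak depolarisation" and "no response" is this
package's convention), else none.

**Morphometry.** Coordinates: $x$ lateral, $y$ cortical depth (pia = 0),
$z$ slice depth. Shrinkage correction scales $x, y$ by 1.1 and $z$ by
2.1; thickness normalisation scales depth (and layer boundaries) to a
reference pia–WM distance, preserving relative depth exactly. Cable
length is the sum of parent–child Euclidean distances, segments typed
by the child node. A *branch* is an unbranched section between
soma/bifurcation/termination points (counted as nodes whose child count
≠ 1), a convention invariant under continuation-node insertion; whether
published counts are sections or tips is usually unstated, and this
choice is recorded in the output metadata. Field spans are 1-D lateral
extents (max − min), not hull diameters. Soma perimeter/area use the
cutting-plane circle of the soma radius.

**Density maps.** Each segment's length is apportioned to 50 μm voxels
by exact parametric clipping against voxel boundary planes (a
fine-sampling oracle at 0.1 μm subdivision guards this in the tests);
totals are conserved to machine precision and grids auto-expand rather
than truncate. Per-neuron maps are computed soma-centered and
translated into the barrel-centered frame (lateral origin at the barrel
center, absolute cortical depth) for group averaging on the unioned,
zero-padded grid. Smoothing is separable Gaussian convolution
(σ = 50 μm, kernel truncated at 4σ and renormalised, grid padded by 4σ
so mass is conserved), applied after averaging. The 80th-percentile
threshold is computed over strictly positive voxels only — including
the zero background would make the threshold of any sparse map 0 — by
linear interpolation. 1-D depth profiles are reported against the
L6/WM border, increasing toward the pia.

**Statistics.** The Mann–Whitney U test is exact (full null
distribution by the count-partitions recursion, equivalent to
enumerating all rank labelings; complete enumeration when ties are
present and the split count is feasible) whenever both groups have ≤ 10
observations, otherwise a tie- and continuity-corrected normal
approximation. The signed-rank test enumerates all $2^n$ sign patterns
up to n = 12; zero differences are dropped (Pratt handling behind a
flag). Two-sided p doubles the smaller tail, capped at 1. Because the
exact null is discrete, the achievable level at nominal α = 0.05 is
slightly conservative (0.0433 at n = 10 vs 10), which the acceptance
suite checks explicitly. Quartiles use linear interpolation (type 7);
whiskers extend to the farthest points within 1.5 IQR. Group summaries
are mean ± sample SD (n − 1), with SD 0 flagged at n = 1.

## Problem sizes and numerical choices

The shipped analyses are sized for a single CPU: 10 neurons per
phenotype cohort (26-step protocols, 1 s steps at 10 kHz equivalents),
16 + 13 + 7 connections × 40 sweeps, 50 drug traces per cohort at
0.3 mV noise, and 6 morphologies per archetype; the full test suite and
the recovery script each run in minutes. Sweep containers are
per-sweep CSV with a JSON protocol sidecar; density maps serialise to
CSV profiles with JSON metadata — plain-text formats keep fixtures
inspectable. Integration uses a 0.025 ms step; the exponential spike
drive is capped so the upstroke completes in a few samples without
overflow, and trajectories below −200 mV abort with an error naming the
parameter set. Quality control (series resistance > 40 MΩ or initial
membrane potential above −55 mV, strict inequalities) is applied at
ingestion; whether excluded cells ever enter partial analyses is a
choice the original workflow leaves open.

## Known limitations

The generator's phenotypes are caricatures: no depolarising
afterpotential, no conductance-based sag (sag in the presets arises
from subthreshold adaptation and is larger than typical), no AP-shape
realism at the 0.1 ms scale (AdEx spikes are ~0.05 ms wide at
half-amplitude, so synthetic half-widths do not match biological
values — the half-width *estimator* is instead validated on constructed
piecewise-linear waveforms with known geometry). Release is
deterministic at the mean (no quantal variability or failures beyond
additive noise), so across-sweep variability is optimistic. Density
maps implement the threshold-and-mask product, not isosurface meshes.
Group comparisons reproduce the statistical machinery, not the
biological conclusions: nothing here classifies real neurons.
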