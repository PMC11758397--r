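# l6ephys

Quantification of layer-6 corticothalamic (CT) and corticocortical (CC)
excitatory neuron physiology and morphology.

Deep cortical layer 6 holds two sharply distinct excitatory cell
classes — FOXP2-expressing CT pyramidal cells and FOXP2-negative CC
neurons — that differ in firing pattern, synaptic output,
neuromodulator sensitivity and morphology. This package implements, as
tested reusable R code, the measurement pipeline used to characterise
such classes from patch-clamp and reconstruction data:

- **Current-clamp features** from step protocols: passive properties
  (resting potential, input resistance `R_in`, membrane time constant
  `τ_m`, voltage sag), single-AP properties at rheobase (threshold,
  amplitude, half-width, latency, fAHP amplitude/latency), and
  repetitive-firing properties at ~10 APs (F–I slope, adaptation ratio
  = last/3rd ISI excluding initial bursts, SD of ISIs 3–9, per-AP
  amplitudes/half-widths, AHP change).
- **Paired-recording synaptic analysis**: sweeps aligned to presynaptic
  AP peaks, mean unitary EPSP amplitude `A_k = max(window) − baseline`,
  and the paired-pulse ratio `PPR = A_2/A_1` at 10 Hz.
- **Neuromodulator responses**: baseline stability (< 1 mV over 3 min),
  `ΔV_m` as the filtered peak excursion from baseline (with a
  noise-extremum bias correction), response classification
  (depolarizing / hyperpolarizing / spiking / none) and responder
  fractions.
- **Morphometry and density maps** from SWC reconstructions: shrinkage
  correction (×1.1 in-plane, ×2.1 slice depth), pia–WM thickness
  normalisation, per-compartment cable lengths / branch counts / field
  spans, and voxelised length-density maps (50 μm voxels, exact
  segment–voxel clipping, group averaging, σ = 50 μm Gaussian
  smoothing, 80th-percentile isosurface threshold, 2D/1D projections
  referenced to the L6/WM border).
- **Exact rank statistics**: Mann–Whitney U and Wilcoxon signed-rank
  tests with exact small-sample p-values by enumeration, tie-corrected
  normal approximations otherwise; boxplot summaries and mean ± SD
  tables.

Because raw recordings of this kind are not publicly deposited, the
package ships a first-class synthetic-data generator with exact ground
truth for every stage: adaptive exponential integrate-and-fire (AdEx)
spiking presets for the four firing phenotypes, a Tsodyks–Markram (TM)
release model calibrated so its *analytic* first-pulse amplitude and
PPR equal the published group means, drug-application traces with known
`ΔV_m`, and morphology archetypes (upright / inverted / multipolar)
with exact cable-length bookkeeping. Every estimator is validated
against these ground truths; see `vignettes/l6-quantification-methods.Rmd`
for the models, conventions and their rationale.

## Worked example

Simulate a facilitating CT-type connection calibrated to the published
FOXP2+ group means (0.22 mV, PPR 2.57), then measure it:

```r
library(l6ephys)

pars <- tm_preset("foxp2_pos")
sim  <- simulate_connection(pars, n_aps = 10, n_sweeps = 40, seed = 1001)
m    <- align_and_average(sim$paired)
pr   <- paired_pulse_ratio(m)
round(c(a1 = pr$a1_mv, ppr = pr$ppr,
        analytic_a1 = sim$ground_truth$amplitudes_mv[1],
        analytic_ppr = sim$ground_truth$ppr), 3)
#>           a1          ppr  analytic_a1 analytic_ppr
#>        0.228        2.463        0.220        2.570
```

A single connection's PPR is noisy (A1 ≈ 0.22 mV against ~0.016 mV of
measurement noise on 40-sweep means); the cohort grand means converge
to the calibrated values — running
`analysis/02_synaptic_connections.R` prints:

```
foxp2_pos  (n=16): EPSP1 0.227 +/- 0.017 mV (analytic 0.22), PPR 2.53 +/- 0.22 (analytic 2.57)
foxp2_neg  (n=13): EPSP1 0.510 +/- 0.012 mV (analytic 0.51), PPR 0.89 +/- 0.04 (analytic 0.88)
ct_l6b     (n= 7): EPSP1 0.333 +/- 0.016 mV (analytic 0.33), PPR 2.29 +/- 0.13 (analytic 2.30)
```

i.e. weak facilitating CT connections versus stronger depressing CC
connections, with the deep-layer CT cohort's larger unitary amplitude.

The numbered scripts under `analysis/` run the other stages the same
way (intrinsic physiology of the four firing phenotypes, cholinergic
`ΔV_m` recovery, morphometry and density maps) and write their tables
under `results/`.

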