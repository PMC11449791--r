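---
title: "Estimating hippocampal E:I balance from theta-cycle spectral slopes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating hippocampal E:I balance from theta-cycle spectral slopes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(eislope)
```

## The scientific problem

The balance between excitatory and inhibitory synaptic drive (E:I
balance) shapes hippocampal computation, and shifts in that balance are
a candidate mechanism for the circuit effects of neurotrophic
treatments. A practical, non-invasive proxy for E:I balance is the
aperiodic ("1/f") decay of the local field potential (LFP) power
spectrum: circuit models and pharmacological work indicate that a
flatter (less negative) log-log spectral slope in the low-gamma range
accompanies a shift toward excitation. `eislope` implements a complete
pipeline for this readout in awake, exploring rodents: the slope of the
CA1 power spectrum over 30-50 Hz, estimated from individual theta
cycles detected during locomotion, with group-level inference. A
companion morphometry module quantifies the structural correlates of
the same question (synaptic puncta densities and E/I ratios, dendritic
spines, boutons, Sholl profiles, densitometry, stereological volumes,
isotope ratios, co-expression percentages).

Every stage is verifiable offline: a synthetic-data module generates
LFP recordings, neuron morphologies, spine tables and puncta images
with embedded ground truth.

## The spectral-slope model

The analysis models band power as a power law,

\[
\log_{10} \mathrm{PSD}(f) = a + b \cdot \log_{10} f + \varepsilon,
\qquad f \in [30, 50]\ \mathrm{Hz},
\]

and reads the fitted `b` as the E:I proxy (flatter = more excitation).
Two estimators are provided, mirroring the two levels at which the
readout is used:

* **Pooled**: all detected theta cycles of a recording are concatenated
  (valley to valley, in time order) and a Welch PSD of the
  concatenation is fitted once. This is the per-animal/group-level
  quantity.
* **Per-cycle**: a Hamming periodogram of each single cycle snippet is
  fitted separately, giving a distribution of slopes whose mean is
  compared between groups with Welch's *t* test.

### Processing chain

1. **Conditioning** (`preprocess()`): Fourier-domain downsampling to
   1 kHz (exactly zero-phase; anti-alias cutoff 0.45 x target rate),
   zero-phase Butterworth notch at 50 Hz and harmonics, z-scoring
   (sample SD). The notch applies odd-reflection padding because a
   forward-backward IIR filter otherwise rings at the record edges; the
   pad length scales with the inverse stopband width.
2. **Band decomposition** (`emd()`, `band_combine()`): classical
   empirical mode decomposition (cubic-spline envelopes through the
   local extrema, mirror extension at the boundaries), then each
   intrinsic mode function is assigned by its amplitude-weighted mean
   instantaneous frequency to the low (<5 Hz), theta ([5, 12) Hz) or
   supra-theta (>=12 Hz) component.
3. **Cycle detection** (`movement_mask()`, `detect_cycles()`): only
   periods with running speed strictly above 2 cm/s (epochs >= 0.5 s)
   are searched. A cycle is a theta-band local maximum flanked by two
   consecutive minima, all exceeding (in absolute value) the amplitude
   envelope of the low band, with valley separation between 71 ms
   (~14 Hz) and 200 ms (~5 Hz); candidates are accepted greedily left
   to right, so cycles never overlap.
4. **Spectra and fits** (`pooled_theta_psd()`, `cycle_slopes()`,
   `fit_slope()`): Welch PSDs use 5 s Hamming windows with 50% overlap
   on a 0.2 Hz grid; short snippets are zero-padded onto the same grid.
   Ordinary least squares on log-log axes over 30-50 Hz (inclusive)
   gives `a`, `b`, `r2`.

### Numerical choices that matter

These choices were all forced by measurable artifacts and are exposed
as arguments, so the raw variants remain available:

* **Slope fits exclude the notch stopbands.** The notch digs a hole at
  the band's upper edge; left in, the 49-51 Hz points bias the 30-50 Hz
  regression downward. The pipeline widens the exclusion by 0.5 Hz for
  the filter shoulder, and uses a narrow (+/- 0.5 Hz) notch so that at
  most ~2% of the fit band is lost.
* **Spectrum interpolation across the notch hole**
  (`spectral_repair()`). A single theta cycle is ~125 ms, so its
  periodogram smooths the spectrum with a kernel ~15 Hz wide; the
  notch hole smears across the upper half of the fit band and steepens
  per-cycle slopes measurably. Interpolating the hole (log-linear
  amplitude between 1 Hz flanks, phases kept) restores a smooth
  background; the interpolated bins are still excluded from the fits.
* **Below-band removal for the estimators.** Theta at its detection
  amplitude carries 30-40 dB more power than the 30-50 Hz floor; a
  125 ms Hamming window cannot reject it by tapering. The per-cycle
  path therefore interpolates across the 4-13.5 Hz region before
  snipping; the pooled path removes content below 15 Hz exactly
  (`spectral_highpass()`), which also prevents every splice between
  concatenated snippets from injecting a broadband step (the dominant
  artifact is the low-frequency amplitude mismatch at the splice
  points). Splices are cross-faded over 5 ms. None of these operations
  can alter true 30-50 Hz content.
* **Sifting stop.** The default is the Rilling envelope criterion
  (|envelope mean| below 5% of the envelope amplitude on 95% of
  samples and below 50% everywhere; <= 100 sift iterations, <= 12
  IMFs); the classical Cauchy energy criterion is available via
  `stop_method = "cauchy"`. On theta-dominated records the aggregate
  energy criterion is satisfied after one or two sifts and leaves
  theta/low mode mixing that costs a measurable fraction of detected
  cycles; the pointwise envelope criterion keeps sifting where the
  mode is still asymmetric. Sifting aborts an iteration that inflates
  the mode RMS threefold (spline envelopes through sparse extrema can
  overshoot and diverge) and stops decomposing once the residual
  reaches numerical noise. The sift loop is compiled (C++), as in the
  field's EMD implementations.

## Group-level statistics

`compare_mean_psd_slopes()` fits each group's mean PSD and tests the
slope difference through the group x log-frequency interaction of a
pooled regression. The per-cycle route uses `welch_t()`
(unequal-variance *t*, Welch-Satterthwaite df) on the two slope
samples, gated in practice by `shapiro_wilk()`; `mann_whitney_u()` is
the nonparametric fallback (exact null distribution when the smaller
sample has at most 8 tie-free observations), `grubbs_test()` the
outlier screen (two-sided, single outlier per call; iterate manually
after removal), and `summarize_mean_sem()` the reporting convention
(mean +/- SEM; the SEM of a single observation is returned as 0 with a
warning). The unit of inference in the per-cycle test is the theta
cycle, not the animal; users who prefer animal-level inference should
aggregate `slopes` per recording first.

## What the synthetic recordings emulate

`generate_lfp()` builds `colored noise + movement-gated theta +
theta-coupled gamma + mains line`, with a velocity trace (50 samples/s,
linearly mapped onto the LFP time base) that exceeds 2 cm/s exactly
during the movement epochs:

* **Background**: spectral-synthesis colored noise with analytic
  exponent `beta` (amplitudes proportional to `f^(-beta/2)`, uniform
  phases). Below a 1 Hz knee the spectrum is flat: a pure power law
  down to the lowest resolvable frequency would place ~10^8 times more
  power there than in the fit band, and window-sidelobe leakage from
  that mass measurably flattens every tapered PSD estimate - real LFP
  spectra plateau at low frequencies. The knee leaves the 30-50 Hz
  ground truth untouched (`knee_hz = 0` restores the pure law).
* **Theta**: amplitude 3 (noise-SD units), frequency-modulated across
  6-10 Hz by default so instantaneous-frequency estimation is
  exercised; it starts at a zero-crossing because a record opening
  exactly on an extremum is a degenerate boundary case for
  envelope-based analyses that no real recording presents.
* **Gamma bursts**: a 30-50 Hz narrowband-noise carrier (real CA1
  gamma is stochastic, not a coherent tone) amplitude-locked to the
  theta peak. Its amplitude is specified relative to the background RMS
  inside the gamma band (default 0.5, bursts peaking at half the local
  background level): an absolute amplitude would vanish against a
  shallow background and swamp a steep one, making the contamination
  condition incomparable across exponents.
* **Line**: 50 Hz plus one harmonic at 30% amplitude.

What the generator does **not** emulate: spike waveforms, ripples,
theta harmonics and cross-frequency asymmetries, non-stationary
behavioral states, electrode drift, or volume-conduction artifacts.
Passing the synthetic acceptance checks therefore demonstrates
correctness of the estimator chain under a controlled spectral model,
not robustness to every pathology of in vivo data.

The problem sizes used by the validation suite - 120 s recordings at
1 kHz, 20 seeds per exponent for slope recovery, 8 seed-paired recordings per group
for the effect-size check - give sampling errors comfortably below the
tolerances being checked while keeping a full run in minutes.

### Known estimator behavior

The mean of per-cycle slopes is noisier than the pooled fit (the
per-cycle slope SD is ~4-5 with ~125 ms windows, so hundreds of cycles
are needed for a stable mean) and tends to run slightly steeper; the
pooled estimator is the more accurate of the two and the per-cycle
distribution is best used for inference, not point estimation.

## Morphometric decision rules

All image- and geometry-level rules are deterministic and documented in
their help pages; the conventions fixed where the verbal rules are
ambiguous are:

* **Spines** (`classify_spine()`): stubby strictly below 1 um without a
  neck; mushroom requires a discernible head at least 1.5x (inclusive)
  the average neck length and total length < 1.5 um; 1.5 um itself
  belongs to thin. The head-to-neck comparison is implemented exactly
  as stated (a diameter against a length). The class-conditional
  generator samples strictly inside these regions, so classifier
  agreement must be exact.
* **Segment densities** (`spine_density()`): half-open `[lo, hi)`
  segments with the final segment closed so a spine at the dendrite end
  is kept.
* **Boutons** (`detect_boutons()`): the axonal backbone statistic is
  the median (robust); the axon-crossing exclusion is a manual input
  flag, not computed.
* **Sholl** (`sholl()`): Euclidean 3D distances from the soma;
  crossings are counted per parent-child segment from the convexity of
  the interior distance function; a node exactly on a sphere counts
  once (for the segment ending on it) and tangencies are ignored. The
  test suite checks exact agreement against a dense-sampling oracle on
  random morphologies.
* **Puncta** (`puncta_count()`): rolling-ball-style background
  subtraction (grayscale opening), 8-bit conversion, fixed threshold,
  Gaussian blur + re-threshold to split apposed puncta, connected
  components. The neuropil E/I analysis applies no area filter; the
  perisomatic analysis (`perisomatic_density()`) keeps components of
  0.15-2.5 um^2 inside a 1.25 um dilation ring. Counts are monotone
  non-increasing in the threshold for flat-top objects; pixel noise
  near an object's intensity can fragment it and locally break
  monotonicity.
* **Densitometry** (`optical_density()`):
  `OD = -log10(G / G_max)` with zero grey clamped to one count,
  normalized by subtracting the internal white-matter OD.
* **Stereology** (`cavalieri_volume()`, `fractionator_count()`):
  exact arithmetic on section areas (x thickness x series factor) and
  marker counts.

## Limitations

* Classical EMD is used (ensemble and multivariate variants are out of
  scope); intermittent low-amplitude fast noise can still mix modes
  locally, which shows up as a few percent of theta cycles lost under
  adverse noise, not as slope bias.
* The 30-50 Hz band contains gamma by design; a strong gamma bump
  biases any straight-line fit. The package fits the line anyway,
  as the field's analyses do, and the synthetic default keeps the bump
  at a realistic fraction of the background.
* Per-cycle periodograms of ~125 ms windows have ~2-3 independent
  spectral degrees of freedom in the fit band; treat single-cycle
  slopes as draws, never as estimates.
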