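---
title: "Methods: fEPSP slope analysis, LTP classification and MRF super-resolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fEPSP slope analysis, LTP classification and MRF super-resolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(med64ltp)
```

## The measurement problem

A planar 64-electrode (8 × 8, 150 µm pitch) probe records evoked field
excitatory postsynaptic potentials (fEPSPs) from a brain slice. Two
electrodes act as stimulation sites: a superficial-layer site S1 that
receives a strong theta-burst train (4 pulses at 100 Hz per burst, 5
bursts per train, 5 trains: 4 × 5 × 5) and a deep-layer site S2 that
receives a single weak train (4 × 5 × 1) thirty minutes later. The
question of interest is heterosynaptic: whether the weak input's
early-phase potentiation is converted into late-phase LTP (L-LTP) by the
plasticity-related products of the strong train — synaptic tagging — and
how that capture, the LTP itself, and the recruitment of initially
silent electrodes change between experimental groups.

`med64ltp` implements the complete measurement chain on this design:
slope extraction from raw sweeps, binning and baseline normalisation,
baseline-stability gating, per-channel LTP classification, group
summaries, activation-area hulls, two-group tests, and maximum a
posteriori (MAP) super-resolution of the sparse 8 × 8 observations on a
latent N × N Markov random field. A synthetic recording generator
reproduces the experiment's statistical structure so that every step is
testable without instrument data.

## Slope extraction

The initial slope of the negative-going fEPSP indexes synaptic strength.
Because no operational definition is universal, the package fixes one
and exposes its knobs:

* the pre-stimulus segment of each sweep provides the DC baseline and
  the noise floor (3 × its SD by default);
* a sweep with no deflection beyond the floor is a *no response* (slope
  0, flagged);
* otherwise the slope is the least-squares line through the raw samples
  between the 20% and 80% crossings of the peak negativity on the rising
  phase, after masking 2 ms of stimulus artifact.

One numerical subtlety matters: the crossing times and the peak are
located on a lightly smoothed copy of the trace (0.5 ms moving average)
and interpolated, while the fit itself uses raw samples inside the
crossing window. Selecting raw samples by their own noisy value
systematically flattens the fitted slope — samples enter the window
preferentially when their noise pushes them toward it — and the bias is
larger at small amplitudes, which would distort baseline-normalised
time courses. Detection on the smoothed trace removes that
self-selection while leaving the estimator a plain linear fit.
`fepsp_slope()` is DC-invariant and exactly linear in trace amplitude.

Responses are sampled every 2 min and averaged in pairs into 4-min bins
(an odd trailing sweep is kept as a flagged singleton). Normalisation
divides each bin's slope magnitude by the channel's mean over the
baseline bins, in percent, so the baseline mean is exactly 100%.

The admission rule for a slice is the recording convention: a channel is
*unstable* when the coefficient of variation of its baseline bins
reaches 5% (strict), and the slice passes when at most 10% (inclusive)
of active channels are unstable. "Variation" is interpreted as the CV of
baseline slope bins — scale-free and consistent with a percentage
criterion.

## Channel classification

A channel is *activated* when its mean baseline amplitude reaches 10 µV
and at least one baseline sweep responds; stimulation channels are
excluded throughout, since their trace is stimulus artifact. Each
channel is referred to the nearest stimulated site that actually
received a train.

Potentiation of a window is a mean normalised slope at or above 120% of
baseline — the conventional field-potential cut-off; the threshold is a
parameter, not a claim. The classes are:

* **L-LTP** — potentiated over the final 30 min of the recording, which
  must extend at least 3 h past the train (the protein-synthesis
  -dependent late phase);
* **E-LTP** — potentiated at 30–60 min post-train but not in the final
  window;
* **non-LTP** — neither.

A *tagging-like* channel is an activated S2 channel classified L-LTP
when the tagging train followed the strong train within the capture
window (30 min by design). The tagging induction ratio of a slice is
the percentage of activated S2 channels that are tagging-like; group
values are per-slice ratios averaged across slices. Recruited channels
(silent at baseline, amplitude crossing 10 µV after the train) are
counted cumulatively by hour and are excluded from class-ratio
denominators; that choice is recorded in the output metadata.

Group comparisons use the two-sample t-test with pooled variance
(Welch's correction available), two-sided, matching the convention of
the field; no multiple-testing correction is applied, also by
convention of the design being reproduced.

## MAP super-resolution on a partially observed MRF

The 8 × 8 slope map for a time bin is treated as a sparse observation of
a smooth latent field with `N × N` sites (`N = 256` by default). The
estimate minimises

$$\Phi(X) = \sum_{i \in \text{obs}} (o_i - x_i)^2
  + \lambda \sum_i \sum_{j \in \mathcal N(i)} a_{ij} (x_i - x_j)^2
  + \varepsilon\,\lVert X - \bar o \rVert^2,$$

with Lanczos smoothness weights
$a_{ij} = L(\lVert i - j\rVert / s)$, $L(d) = \alpha \sin(\pi d)\sin(\pi
d/\alpha)/(\pi d)^2$, $\alpha = 3$, over a 5 × 5 window. Electrode
$(r, c)$ of the 8 × 8 grid is embedded at the centre of its latent cell,
$(\lfloor (r - \tfrac12) N/8 \rfloor + 1, \lfloor (c - \tfrac12) N/8
\rfloor + 1)$. Several parameters the field's formula leaves open are
fixed as follows, each exposed as an argument:

* **Kernel scale** `s = 2.5`: the Lanczos kernel is exactly zero at
  integer arguments, so evaluating it at raw lattice offsets would null
  the pairwise term entirely; dividing the offset by 2.5 yields strictly
  positive weights across the 5 × 5 window while preserving the window
  size. The kernel argument is the isotropic Euclidean offset — the
  window is two-dimensional, so a 1-D argument must be extended; a
  separable product is a near-identical alternative.
* **Clipping**: negative Lanczos lobes can make $\Phi$ indefinite;
  weights are clipped at zero by default, which together with the ridge
  makes the system symmetric positive definite and the minimiser unique.
* **Balance** $\lambda$: pairwise terms outnumber unary terms by orders
  of magnitude at `N = 256`; the default
  $\lambda = n_\text{unary}/n_\text{pairwise}$ (term-count balance,
  counted per frame) keeps the reconstruction anchored to observations
  at any `N`.
* **Ridge** $\varepsilon = 10^{-6}$, centred on the observation mean:
  fixes the null directions of unobserved border regions without visibly
  biasing the field.
* **Masking**: the stimulation channel's value is artifact and is
  excluded from the unary term by default in the pipeline entry points.

The normal equations are solved by direct sparse Cholesky factorisation
(`Matrix`), which at `N = 256` takes seconds and is deterministic; the
residual norm of the normal equations is stored with the fit (the
gradient norm at the solution is twice that), so every solve certifies
itself. `tidy()` and `glance()` expose the field and its diagnostics.

For a sequence of frames, the joint estimate adds temporal smoothness.
The printed form of the spatio-temporal pairwise term couples same-frame
pairs inside a temporal neighbourhood, which would make the temporal sum
vacuous (identical copies of the spatial term). Two non-vacuous readings
exist: couple every spatial offset across every frame offset (a full
5 × 5 × 5 coupling), or keep spatial smoothing within frames and couple
each site to itself across frames with the linear taper
$a_t = (\beta - |t|)/\beta$, $\beta = 3$. The package implements the
second. The deciding property: with observations constant in time, the
temporal differences vanish at the replicated spatial solution, so each
frame reproduces the per-frame spatial estimate exactly — full
cross-coupling instead adds spurious extra spatial smoothing that grows
with the number of frames. `T = 1` reduces to the spatial solve
identically. Border windows are truncated, not padded, in both space
and time.

For display, fields are stretched affinely from their state range onto
the 8-bit range 0–255 (clipped, rounded half-to-even), and rendered
either as deterministic perspective surfaces (fixed camera and colour
ramp, so renders are regression-testable) or as `ggplot2` rasters.

## The synthetic recording generator

`simulate_slice()` emulates the study conditions; its defaults *are*
those conditions, calibrated to the reproduced experiment's printed
group statistics as a fidelity contract (not an independent estimate):

* geometry: 8 × 8 grid, S1 at channel 26, S2 at channel 46 (the probe's
  published example sites); baseline amplitude decays exponentially with
  distance from the stimulated site, length constant 300 µm and 25 µV at
  the site, which activates ~8 channels per site at the 10 µV threshold;
* timeline: 60 min baseline, strong train at 60 min, tagging train at
  90 min, recording to 330 min; sweeps every 2 min;
* S1 channels rise smoothly (smoothstep over 40 min) to a slice-level
  plateau drawn from Normal(148.0, 8)% for the adult preset and
  Normal(128.0, 8)% for the middle-aged preset;
* each activated S2 channel is tagging-like with probability
  `p_capture` (0.7333 adult, 0.3333 middle-aged, 1.0 for the rescued
  presets): captured channels sustain a plateau, the rest show early
  LTP — an immediate 36.5% jump decaying exponentially with τ = 75 min,
  so the early window (30–60 min) is just potentiated and the response
  is back within 5% of baseline by 2.5 h. The sustained plateau is
  solved from the preset's S2 mixture target (175.2% adult, 114.4%
  middle-aged): `P_tag = (target − (1 − p)·E_resid)/p`, with `E_resid`
  the binned final-30-min mean of the decayed early-LTP shape, so the
  expected S2 group mean equals the target by construction. The
  slice-level draw (SD 8%) applies to the plateau itself, exactly as at
  S1 — drawing the mixture target instead would scale the plateau SD by
  `1/p` and censor captured channels below the 120% criterion, biasing
  the tagging ratio away from `p_capture`;
* recruitment is Poisson per hour and site (1.2/h adult, 0.3/h
  middle-aged, from the published recruited-channel counts), assigned to
  the nearest silent electrodes, ramping to plateau amplitudes around
  Normal(24, 1) µV;
* noise: multiplicative Normal(1, 5%) per sweep and channel — 4-min
  bins then have ≈3.5% SD, so the 5% baseline-CV gate passes at the
  default and fails when the noise is forced to 20% — plus slice-level
  plateau variability (8%) and, in the raw-waveform output, 1 µV
  additive sample noise on a double-exponential fEPSP template (τ rise
  1 ms, decay 5 ms) scaled per sweep.

Ground-truth labels are the classes implied by the *noise-free*
trajectory (so a slice whose plateau draw lands below 120% is truthfully
non-LTP); the Bernoulli capture branch is recorded separately.

What the generator does **not** emulate — and hence what passing tests
do not show about real recordings: correlated within-slice channel
noise (channels are conditionally independent given slice effects),
bimodal group structure (some published groups mix responders and
non-responders; the generator draws unimodal plateaus), drug
pharmacokinetics (rescued presets only move the capture and plateau
parameters), volume conduction, and real waveform morphology beyond the
two-exponential template.

One margin is structurally thin and worth knowing: with τ = 75 min the
ratio between the early-LTP shape's 30–60 min mean and its 2.5 h
residual is fixed at ≈4.1, so any jump that satisfies "within 5% of
baseline at 2.5 h" leaves the early window mean only ≈0.4% above the
120% criterion. Noisy early-LTP channels therefore sit near the E/non
boundary; label recovery is evaluated over all channels, and the
capture probability estimate is unaffected (captured plateaus clear the
criterion by tens of points).

## Problem sizes and tolerances used in the tests

The test-suite study sizes are the package's own choices: oracle
equivalence of the MAP solver is checked on twenty randomised instances
with latent sides 6–16 and up to three frames against a conjugate
-gradient minimiser run to a 10⁻¹⁰ gradient norm, at 10⁻⁶ relative
error; group calibration runs n = 5 slices through the raw-waveform
path at the documented study seed and n = 1000 slices through the
slope-table path; capture-probability recovery uses the pooled 95%
binomial margin. Determinism is asserted byte-for-byte on data
artifacts and pixel-for-pixel on rendered figures.

## Known limitations

* The published 256 × 256 surfaces cannot be matched bit-for-bit: the
  kernel's distance units, the unary/pairwise balance and the electrode
  embedding are not specified by the field's formula, so the
  reconstruction is verified by its mathematical properties instead.
* Channel numbering on the physical probe is a convention (1–64,
  row-major from the top-left of the probe image); instrument files
  with a different convention must be mapped on import.
* The classifier's windows assume the standard timeline (≥3 h follow-up
  past each train); shorter recordings are rejected rather than
  classified optimistically.
* `slice_summary()` reports hull areas over baseline-activated and
  recruited channel sets; with fewer than three non-collinear channels
  the area is legitimately zero.
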