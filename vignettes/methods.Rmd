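---
title: "Methods: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synaptodev)
```

This vignette is the package's own account of the quantitative procedures it
implements: the models behind each read-out, the tunable parameters and their
defaults, what the synthetic-data generators do and do not emulate, and the
numerical choices made where the underlying lab conventions left the design
open.

## EPSC decay kinetics

Evoked NMDAR-mediated EPSCs recorded at +50 mV decay with two kinetic
components, a fast one contributed mainly by GluN2A-containing receptors
(time constant around 50 ms) and a slow one by GluN2B-containing receptors
(around 300 ms). `fit_biexp_decay()` fits the decay phase with

$$Y(t) = A_f e^{-t/\tau_f} + A_s e^{-t/\tau_s},$$

after subtracting the pre-stimulus baseline, and summarises the balance of
the two components with the amplitude-weighted time constant

$$\tau_w = \tau_f \frac{A_f}{A_f + A_s} + \tau_s \frac{A_s}{A_f + A_s},$$

computed by `weighted_tau()`. Rise time is the interval from the stimulus
onset to the peak (`rise_time()`); the stimulus-onset reference was adopted
because the stimulus artefact, not a fractional-amplitude crossing, is the
marked time zero in this recording convention.

Numerical choices:

* **Fit window.** Default is peak-to-end of sweep, matching the
  "decay phase" convention. The window start may be moved later explicitly;
  the model has no plateau term, so the baseline must be subtracted first
  (done internally from the pre-stimulus mean).
* **Amplitude reference.** The optimiser estimates amplitudes at the window
  start; these are extrapolated back along each exponential to the stimulus
  onset before fractions are formed. Without this, $A_f/(A_f+A_s)$ would
  depend on each cell's rise time, which mixes an unrelated quantity into
  the subunit-balance read-out.
* **Optimiser.** Levenberg–Marquardt (`minpack.lm::nls.lm`) with data-driven
  starts ($\tau_{f,0}$ = time to fall to $1/e$ of the peak,
  $\tau_{s,0} = 6\tau_{f,0}$, amplitudes split evenly) and bounds
  $\tau \in [1, 5000]$ ms, $A \ge 0$. Components are ordered afterwards so
  $\tau_f < \tau_s$ regardless of which slot converged where.
* **Degeneracy.** When the two time constants converge to within a ratio of
  1.2 the fit is reported but flagged `quasi_single_exp`; on genuinely
  single-exponential data the redundant component takes essentially zero
  amplitude and $\tau_w$ collapses to the single $\tau$, which is the
  correct limit.
* **Unconstrained amplitudes.** Whether the original analysis constrained
  $A_f + A_s$ to the peak is not recorded; the fit here is unconstrained,
  with ordering, which empirically recovers generating parameters to ~1%
  on noiseless traces.

The generators add a saturating rise filter $(1 - e^{-t/\tau_{rise}})$,
default $\tau_{rise} = 2$ ms, in front of the biexponential so that rise
time is testable. The first ~10 ms after the peak therefore deviate from a
pure biexponential by up to ~2%; with the default peak-to-end window this
contributes about 1% bias on $\tau_f$, which is why the sharpest recovery
tests open the window a few rise constants after the peak.

## Dendritic calcium pipeline

The movie analysis mirrors a stack-profile workflow: a segmented line ROI
(default width 50 px) is traced along a dendrite, each frame yields an
intensity profile along the polyline (mean over `width_px` bilinear samples
along the local perpendicular, 1-px arc steps), and profiles are stacked
into a frames × positions kymograph (`extract_kymograph()`). Calibration
defaults are 7 frames/s and 10/65 µm/px (65 px = 10 µm; 350 frames = 50 s);
both are arguments everywhere they matter.

`compute_dff()` computes ΔF/F0 per position. F0 is *per position*, not a
single scalar: the inactive-state language of the original macro is
ambiguous on this point, and per-position baselining is what preserves the
spatial structure on which diffusion distance depends. The automatic rule
takes each position's lowest-decile frames as its inactive state; an
explicit baseline frame set can be supplied instead.

Per-site read-outs, computed from the spatial ΔF/F0 profile averaged over
each site's event-peak frames (`average_site_transients()`):

* **AUC** (`site_auc()`): trapezoidal integral of the above-baseline span
  containing the peak, in ΔF/F0·px, including the bounding baseline samples
  so a unit plateau over 10 px scores 10.
* **Diffusion distance** (`diffusion_distance()`): length of the contiguous
  span around the peak where the profile stays at or above a fraction
  *f* of the peak, converted to µm. The threshold fraction is not recorded
  anywhere in the source conventions — only a shaded region in the figures —
  so it is configurable with default *f* = 0.1; *f* = 0.5 gives the FWHM,
  2.355σ for a Gaussian profile.
* **Frequency** (`transient_frequency()`): event count × 500 / frames
  analysed, the "# transients/500 frames" convention.
* **Synchrony** (`synchrony()`): Pearson correlation matrix of up to 20
  randomly sampled site-centre time courses over a 500-frame window
  (central by default); each site's score is the mean of its off-diagonal
  row. Constant traces are dropped with a warning, since their correlation
  is undefined.

**Transient detection** (`detect_transients()`) is intentionally simple and
fully stated, since the original rule is unrecorded: a site-centre trace
crosses threshold $k_{sd} \times$ baseline SD (MAD-estimated, so sparse
events do not inflate it) for at least `min_frames` consecutive frames
(defaults 3 SD, 2 frames at 7 fps). Two guards matter in practice:

* an absolute ΔF/F0 floor (default 0.05) bounds the threshold from below —
  it governs when the baseline variance is ~0 (noiseless simulations) and
  keeps sub-physiological noise blips out when the SD estimate is tiny;
* each above-threshold run is split by hysteresis: after the trace falls at
  least one threshold below the running peak, a rise of one threshold above
  the intervening minimum opens a new event. With ~2 s decay tails at
  realistic event rates, runs frequently contain several transients;
  without the split, frequency is underestimated by tens of percent.

`identify_sites()` (a convenience the original workflow did manually) takes
local maxima of the temporal-max spatial profile above a ΔF/F0 threshold
(default 0.1), greedily separated by `min_separation` px. Events spanning a
drug-application boundary are assigned by peak frame and flagged
(`split_before_after()`).

## Particle quantification

`find_particles()` reproduces analyze-particles semantics: 8-connected
components ("adjacent" = 8-neighbourhood, the host program's default),
area in pixels, and circularity $4\pi \cdot \text{area}/\text{perimeter}^2$
clamped to 1. The perimeter comes from the component's Moore boundary chain
with the Vossepoel–Smeulders correction (0.980 per axial step, 1.406 per
diagonal, −0.091 per corner), which converges to the true outline length
for smooth shapes — a raw chain-code length would leave disc circularity
stuck near 0.9. A single-pixel particle is assigned the 4-edge outline
(circularity π/4).

The filter presets encode the study's rules: lysosomes need circularity
> 0.5 (so clusters are not counted as one unit); AL deposits need
circularity > 0.4 and *more than eight* adjacent pixels, read strictly, so
an 8-pixel component is rejected and a 9-pixel one retained.
`quantify_soma()` computes cytosolic area as thresholded soma (MAP2) area
minus nucleus (DAPI) area and expresses AL and lysosome particle areas as
percentages of it; `percent_area_column()` averages thresholded percent
area across an image set under one fixed threshold. Thresholds are always
explicit per-channel values (`threshold_spec()`) applied identically across
a comparison — no automatic thresholding, by design.

## Assays and statistics

`normalize_viability()` expresses each well as a percentage of the same
plate's vehicle-well mean; pooling across runs happens after normalization.
`apegs_ratio()` implements the gel-shift bookkeeping: palmitoylated signal
is the sum of all PEG-shifted bands, non-palmitoylated is the band matched
to the −HA control, and the reported ratio is (palm/nonpalm)/actin within
lane. `compare_groups()` wraps the plain two-sample t-test (Welch optional,
off by default to match the reporting convention), one-factor ANOVA with
Tukey's post-hoc, and two-factor ANOVA with interaction; per-group s.e.m.
is $sd/\sqrt{n}$ with *n* = independent experiments —
`average_repetitions()` collapses technical repetitions first, and two-way
designs average repetitions out rather than modelling them as a factor.

## What the generators emulate — and what they don't

Every generator consumes a single seed and reproduces its output
bit-exactly; ground truth is recorded by code independent of the analysis
path (pixel counts from rasterization, iso-contour perimeters, generative
event lists).

* `gen_epsc()`: rise-filtered biexponential plus white Gaussian noise. No
  stimulus artefact, series-resistance error, or sweep-to-sweep drift.
* `gen_calcium_movie()`: a dendrite band whose baseline fluorescence is
  multiplied by Gaussian-in-space, exponential-in-time event kernels, so
  the peak ΔF/F0 at a site centre equals the generator amplitude exactly.
  Event times are per-frame Bernoulli draws at `transient_rate/500`;
  synchrony is injected by mixing a shared event stream with independent
  ones at weight `common_drive`, which preserves the per-site rate and is
  monotone in the synchrony statistic. Defaults follow the study
  conditions: 7 fps, 10/65 µm/px, 500–600 analysed frames, rates of a few
  transients per 500 frames, σ of a few px for compartmentalized and tens
  of px for diffuse signals. Not modelled: microscope PSF, shot noise,
  bleaching, motion, z-structure. One consequence worth knowing: in the
  diffuse regime neighbouring sites genuinely see each other's events
  (a 40-px spacing at σ = 20 px leaves 13% crosstalk), so per-site
  frequency rises — that is the physics of diffuse influx, not a detection
  artefact, and it is why detection accuracy is scored on
  compartmentalized movies.
* `gen_soma_image()`: four flat-intensity channels with circular lysosomes
  and round-to-irregular AL blobs placed without overlap in the cytosol;
  truth circularity uses an iso-contour perimeter (R's contouring), a
  deliberately different algorithm from the analysis module's boundary
  chain. No texture, blur, or intensity gradients.
* `gen_plate()`: well fluorescence = vehicle mean × viability × (1 +
  Normal(0, cv)). No edge effects or plate gradients.

Passing tests therefore demonstrate correctness of the *computations* under
clean, known-truth conditions; they do not certify performance on raw
microscope data with drift, bleed-through or focus artefacts.

## Problem sizes

The test and verification runs use 600-frame movies with 5–8 sites,
100-trace EPSC recovery cohorts at SNR 20, 50 random 64×64 masks for the
labeling cross-check, 192-px soma images, and 1000-replicate null
simulations for the type-I error check — sizes at which every stochastic
read-out is stable to well inside its acceptance band while a full run of
the suite stays in the tens of seconds.
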