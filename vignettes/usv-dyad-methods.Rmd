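---
title: "Methods: detecting, assigning and comparing mouse ultrasonic vocalizations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting, assigning and comparing mouse ultrasonic vocalizations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Adult mice of both sexes emit ultrasonic vocalizations (USVs, roughly
30–110 kHz) during social interaction, but a freely moving mouse shows no
visible sign of vocalizing, so attributing a call to an individual requires
acoustic localization. `usvdyad` implements a complete analysis chain for
male–female pairs ("dyads") recorded in a square arena (0.762 m a side)
surrounded by an 8-microphone array sampling at 250 kHz, with video tracking
at 30 frames/s providing each animal's body ellipse:

1. **Segmentation** — find vocal signals as connected regions of the
   time–frequency plane;
2. **Localization and assignment** — estimate each signal's source and
   decide which mouse emitted it;
3. **Acoustic features** — seven per-signal measurements;
4. **Behavioral context** — classify following / followed / not-close bouts
   from the trajectories and label each call with its emitter's context;
5. **Sex statistics** — Mann–Whitney comparisons, Pearson correlations, and
   a Monte-Carlo median-difference index that controls for the large
   male–female sample-size imbalance.

A sixth module simulates all of the above with known ground truth; the test
suite and the acceptance script rest on it because raw multichannel
recordings of this kind are far too large to ship.

## Segmentation

Each channel is bandpass filtered to 30–110 kHz (4th-order Butterworth,
applied forward–backward so the phase is untouched). Overlapping windows of
64, 128 and 256 samples (hop = half the window) are tapered with K = 5
discrete prolate spheroidal sequences at time–bandwidth product NW = 3, and
Thomson's harmonic F statistic is computed per time–frequency bin. Under
the locally-white noise null the statistic is F(2, 2K−2); bins with
p < 0.05 are marked significant. Exact digital silence yields a 0/0
statistic, which we define as 0 (never significant) rather than propagate
NaN.

The F statistic is invariant to the noise scale: on background of any
amplitude it flags ~5% of bins per channel and scale by construction, so a
detector built on significance alone drowns once masks are OR-ed. A bin is
therefore kept only when it is *both* line-like (F-test, p < 0.05) and
locally prominent — multitaper power above `power_floor` (default 4, about
6 dB) times the median power of its frequency row on that channel and
scale. The row median is an uncontaminated background estimate as long as
signals occupy a row less than half the time, which holds for transient
USVs; a tone present throughout a recording would be treated as narrowband
background. On digitally silent audio the floor is numerically zero and
the criterion reduces to the F-test alone.

Significance masks from all channels and all three window lengths are
nearest-neighbour resampled onto one grid — time step of the shortest hop
(32 samples = 0.128 ms), frequency step of the finest resolution
(250 kHz / 256 ≈ 977 Hz) — and OR-ed. The combined mask is convolved with
an 11 (frequency) × 15 (time) box of ones and any bin the kernel touches is
set, filling small gaps (the fill requires `box_min` significant pixels
under the kernel; the default derives it from the mask's overall density
as a 1e-9 binomial tail bound, which reduces to "any pixel" on clean
audio and rejects residual background fill otherwise). 8-connected
components with at least 1500 pixels become individual signals. Pixel counts are grid-dependent, so the 1500
threshold is meaningful only on this default grid and is exposed as a
configuration parameter (`min_pixels`).

Two refinements matter in practice:

* A signal's **time support** is taken from the pre-convolution significant
  pixels inside its component. The box kernel exists to define
  connectivity; letting it also dilate onsets/offsets would add ~1 ms to
  every duration.
* The **frequency contour** (power-weighted mean frequency per occupied
  time column) is evaluated on the power spectrogram of the signal's single
  loudest channel, recomputed with one Slepian taper and windows hopped at
  the fused grid's own step, over the pixel set dilated ±5 rows in
  frequency. Each choice removes a distinct bias: summing channels smears a
  frequency-modulated call along its sweep by the inter-microphone delay
  spread (up to ~2.7 ms across a 0.76 m arena); averaging five tapers
  widens the spectral lobe of a line component; and an asymmetrically
  truncated lobe drags a weighted mean sideways. Columns whose power is
  below 10⁻⁶ of the signal's peak column (windows that do not overlap the
  signal at all) are dropped — their weighted means are numerically
  meaningless. The plain channel-summed contour remains available
  (`contour_channels = "sum"`).

Overlapping detections whose temporal overlap exceeds 90% of the shorter
signal and whose median contour frequencies are integer multiples
(|ratio − round(ratio)| < 0.1, round(ratio) ≥ 2) are treated as one
harmonic stack: the lowest-frequency member is kept and flagged, and all
features are computed from that fundamental.

## Localization and the mouse probability index

The per-subset point estimator measures time differences of arrival for
every microphone pair by GCC-PHAT (phase-transform-whitened
cross-correlation, parabolic sub-sample peak refinement, search limited to
physically possible lags) and solves for the planar source by nonlinear
least squares on the delay residuals, multi-started from a coarse grid and
clamped to the arena. The speed of sound is fixed at 343 m/s and the
geometry is two-dimensional, matching the two-dimensional tracking.

Each microphone is then left out once: eight 7-microphone estimates per
signal. Their coordinate-wise mean is the overall estimate, and a bivariate
normal centred there — covariance equal to the jackknife scatter inflated
by (m−1)²/m with every eigenvalue floored at (1 cm)² — summarizes the
uncertainty as a density over the cage. The floor prevents a singular
density when all eight estimates coincide; 1 cm is well below the scale of
a mouse body. Each animal receives the density value D at its **nose**
(centroid + half the ellipse's major axis along the heading — one shared
definition used by the simulator, the localizer and the behavior module),
and the mouse probability index is

MPI_n = D_n / Σ_i D_i.

A signal is assigned only when one animal's MPI **strictly exceeds 0.95**;
ties, sub-threshold maxima, and all-zero densities (numerical underflow far
from the estimate) leave it unassigned. More than two invalid leave-one-out
estimates mark the signal unlocalizable.

## Acoustic features

From the contour: high frequency (maximum), low frequency (minimum),
bandwidth (high − low, an identity the feature table asserts), duration
(last minus first contour time), and mean fundamental frequency
(power-weighted mean). Slope is the coefficient of an
iteratively-reweighted least-squares line of frequency on time (Tukey
bisquare, tuning constant 4.685, ≤ 50 iterations); on an exact line, where
the robust scale estimate degenerates, ordinary least squares is used —
the two coincide there. Contours with fewer than three points have
undefined slope.

Amplitude fits a single sine wave (free amplitude, frequency, phase,
offset) to each channel's raw voltage trace over the signal interval and
takes the largest fitted amplitude (peak minus midpoint) across channels.
The frequency search — the only non-convex part — is initialized at the
magnitude peak of an 8× zero-padded FFT near the signal's mean contour
frequency and refined on the exact least-squares objective. For strongly
frequency-modulated calls a single sine is a poor model and the fitted
amplitude underestimates the trace envelope; we keep the procedure because
it is the study's stated definition, and the units are simply the audio
file's voltage units (labelled mV only when the recording is calibrated).

## Behavioral context

Per-frame velocity is a central difference of the centroid smoothed with a
5-frame moving average (raw 30 Hz differencing is too noisy; the window is
configurable); movement direction is undefined below 1 cm/s. "B follows A"
at a frame requires all four criteria: movement directions within 25°,
centroid distance < 5 cm, both speeds > 20 cm/s, and B behind A — the
vector from B to A projects positively on A's movement direction while the
reverse test fails. "Not close" requires centroid separation ≥ 15 cm.
Criteria must hold for ≥ 10 consecutive frames to form a bout; a pursuit
run yields a *following* interval for the pursuer and an identically-framed
*followed* interval for the leader. Centroids (not noses) measure distance
in all three contexts — one definition instead of an undocumented
asymmetry. A vocalization's context is the kind of its emitter's interval
containing the **onset** frame (the emission decision point; midpoint
labelling is a config option); outside every interval the context is
"other"; unassigned signals are excluded from context tables.

## Sex statistics

All group comparisons are two-sided Mann–Whitney U tests: exact permutation
p-values when the smaller group has ≤ 8 observations and no ties, otherwise
the normal approximation with tie and continuity corrections (the reported
z is always the corrected one). Percentiles interpolate linearly between
order statistics. No multiple-testing correction is applied, matching the
study design (per-feature tests at α = 0.05). A one-sample
Kolmogorov–Smirnov check against a moment-matched normal justifies the
nonparametric choice in the run report.

The Monte-Carlo index draws 1000 independent subsamples of 500 male and
500 female signals (without replacement within a subsample — a "sample of
500 signals" — unstratified across sessions), computes per-sex medians and
the index (male − female)/(male + female). Positive values are male-driven.
Slope, the one signed feature, is first shifted by the absolute value of
the most negative slope over **all** assigned signals pooled globally, so
the minimum maps to zero, the index's nonnegativity precondition holds, and
every subsample uses the same constant. Adding a constant cannot reorder
medians, so direction counts are unaffected by the shift's scope. Sessions
whose male emitted strictly more than 2200 signals form the high-vocalizer
group; each female inherits her partner's label.

## The synthetic-data generator

The generator is first-class, tested code that defines the study
conditions used everywhere:

* **Trajectories.** Both mice run a circle (radius 25 cm) at 25 cm/s; the
  scripted bout kind switches the inter-animal gap — under 5 cm for
  pursuit, 20 cm for not-close, 9 cm for neutral frames — with gap changes
  realized as forward jumps so speed never dips and direction never
  reverses. Consequently the classifier's criteria flip exactly at scripted
  frame boundaries, which is what makes frame-exact recovery a meaningful
  test. Real mice do not teleport; the construction trades physical realism
  at bout edges for exact ground truth.
* **Calls.** Linear-FM chirps, 10–30 ms, inside 30–110 kHz, with 1 ms
  raised-cosine ramps (fast on/offsets, as in recorded USVs; a linear sweep
  makes the slope ground truth exact).
* **Array audio.** Free-field propagation: per-channel delay = distance /
  343 m/s, gain ∝ 1/distance, independent Gaussian noise per channel. No
  echoes (the recordings this emulates were made in an anechoic chamber),
  no directional microphone gain, no Doppler. Sources sit at the emitter's
  nose at onset.
* **Feature tables.** Positive features are log-normal matched to per-sex
  median and quartiles (log-quartile symmetry holds well for the reported
  values); slope is a two-piece (asymmetric) Laplace matched to the median
  and both quartiles — peaked and heavy-tailed, decisively non-Gaussian.
  High frequency is derived as low + bandwidth so the bandwidth identity
  holds by construction, and mean frequency as low + u·bandwidth with
  u ~ Beta(2, 2); their medians are therefore emergent, not set. The
  printed slope medians carry a garbled exponent in the source material, so
  the generator takes the "×10 kHz/s" notation literally; only signs and
  orderings of slopes are treated as meaningful. Per-session counts are
  log-normal (male median 3318, female median 477) coupled by a Gaussian
  copula (ρ = 0.9), so males out-vocalize females in essentially every
  session and paired counts correlate strongly.

What passing tests on this generator do **not** show: robustness to
reverberation, overlapping simultaneous calls from both animals,
nonstationary cage noise, tracking identity swaps, or non-linear (jump,
harmonic-rich) call types. The harmonic-stack rule is exercised on
constructed stacks, not on biomechanically realistic harmonics.

## Problem sizes and numerical choices

The shipped validation runs use a 6.6 s, 8-channel, 250 kHz session with 50
planted chirps for the front end (the full statistical back end runs on
generated tables with ~40–70k rows); these sizes exercise every code path
at full sampling rate while keeping a complete run in minutes on one core.
Window-length resolution limits are inherent rather than incidental: a
0.26–1.0 ms analysis window averages a frequency sweep over its support, so
contour endpoints — hence bandwidth — carry an error of order
|slope| × window/4 even noise-free, and the OR across differently-delayed
channels adds up to the arena's delay spread to any duration measured from
multichannel audio. The recovery tests' tolerances (5% on bandwidth and
slope; ~1 ms-scale on durations) reflect those limits.

Degenerate inputs are defined, not crashed on: empty masks give empty
signal lists; single-point contours are flagged; constant samples give
degenerate KS and correlation flags; identical groups give p = 1; zero
densities leave a signal unassigned with an underflow flag.

## Known limitations

* The per-subset point estimator (GCC-PHAT + least squares) is this
  package's own substitute for the original system's estimator, whose
  internals are outside our source material; the jackknife/MPI layer above
  it is estimator-agnostic.
* The density over the cage is modelled as a bivariate normal from the
  jackknife scatter; the original density's functional form is not
  recoverable from the text.
* Estimates falling outside the arena are clamped to its boundary.
* Sine-fit amplitudes of strongly modulated calls underestimate the
  physical envelope (see above) and are in uncalibrated voltage units.
* The 1500-pixel threshold cannot be made exactly equivalent to the
  original detector's, because the original fusion grid is undocumented;
  it is calibrated to this package's default grid.
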