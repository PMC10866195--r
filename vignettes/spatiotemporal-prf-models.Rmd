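---
title: "Spatiotemporal pRF models: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatiotemporal pRF models: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`prfst` implements an image-computable framework for estimating
*spatiotemporal population receptive fields* (pRFs) from fMRI: forward models
that map a binarized space–time visual stimulus to a predicted BOLD time
course, a synthesizer that produces noisy simulated voxels, and a
coarse-to-fine solver that recovers the model parameters per voxel. This
vignette documents the models, the numerical choices, and the reasoning
behind the places where the design was genuinely open.

## The two-stage forward model

Every model shares the same architecture: a *neural* stage at 10 ms
resolution followed by a *hemodynamic* stage.

1. The stimulus is a binarized movie $I(X, Y, t)$ on a $61 \times 61$ pixel
   grid spanning $[-12, 12]^\circ$ of visual angle, at 10 ms frames.
2. The spatial stage computes the drive
   $d(t) = \sum_{X,Y} I(X,Y,t)\,\mathrm{RF}(X,Y)$ with an isotropic 2D
   Gaussian $\mathrm{RF}(X,Y) = e^{-((X-x)^2 + (Y-y)^2)/2\sigma^2}$
   (unnormalized, value 1 at the center $(x, y)$; $\sigma$ is the pRF size).
3. A model-specific temporal stage turns the drive into predicted neural
   activity $p(t)$ (below).
4. $p(t)$ is convolved with a two-gamma HRF, averaged into 1 s bins to match
   the fMRI sampling rate, and scaled by gain weights estimated by ordinary
   least squares.

**Spatial model** — $p(t) = d(t)$: purely linear, no temporal parameters.

**CST (compressive spatiotemporal)** — three channels with identical spatial
RFs and different temporal impulse responses: a sustained gamma kernel
$h_1(t) = \frac{(t/\kappa\tau)^{m-1} e^{-t/\kappa\tau}}{\kappa\tau\,(m-1)!}$
with $\kappa = 1$, $m = 9$; an on-transient kernel
$h_2 = h_1 - h_{\mathrm{inh}}$ (the inhibitory gamma uses $\kappa = 1.33$,
$m = 10$, so $h_2$ is biphasic, integrates to zero, and peaks before $h_1$);
and an off-transient kernel $h_3 = -h_2$. Each channel is rectified and
compressed, $p_i(t) = [\mathrm{ReLU}(h_i \ast d)]^{n}$ with
$n \in [0.1, 1]$. The on- and off-transient channels are summed into a
single transient regressor (their rectified responses never overlap in
time), so two gains $\beta_{sus}, \beta_{tran}$ are estimated.

**DN-ST (delayed normalization)** — a single nonlinear channel
$$p(t) = \frac{|r(t)|^{n}}{\sigma_{DN}^{\,n} + \left[|r(t)| \ast
h_2\right]^{n}},\qquad r = h_1 \ast d,$$
with impulse response $h_1(t) = t\,e^{-t/\tau_1}$ and exponential-decay
low-pass $h_2(t) = e^{-t/\tau_2}$. The bracketed term is implemented as a
causal convolution of $|r|$ with the decay filter (the delayed-normalization
convention); a pointwise product would remove the "delayed" character of
the normalization pool.

### Units and the CST $\tau$

Internally the neural stage runs in 10 ms samples. DN-ST $\tau_1, \tau_2$
are in seconds (bounds $[0.01, 1]$ s). The CST $\tau$ is carried in 10 ms
samples, matching its search bounds $[4, 100]$: $\tau = 100$ is one second.
Two conversions are exported because the literature labels this parameter
inconsistently: `cst_tau_ms()` ($\tau \times 10$ ms) and `cst_peak_ms()`
(the derived gamma time-to-peak, $(m-1)\kappa\tau$ samples, i.e. $80\tau$
ms at the defaults). Reported "time-to-peak in ms" values in the source
literature are smaller than $8\kappa\tau$ would suggest for the printed
bounds; we expose both quantities rather than resolving the ambiguity.

### Kernel discretization

All continuous kernels are evaluated at frame midpoints and renormalized to
unit sum, so that gains and the DN-ST semisaturation constant are invariant
to the sampling interval. Supports are truncated where the underlying gamma
distribution has $10^{-4}$ upper-tail mass; because the synthesizer and the
solver share the same discretized kernels, this truncation does not bias
parameter recovery. Convolutions are causal, zero-padded on the left, and
restart at run boundaries (runs are recorded independently). $(m-1)!$ is
evaluated through the log-gamma function, so non-integer shape parameters
are admissible.

## Stimulus designs

The *spatiotemporal mapping* design sweeps a 3°-wide bar across a 12°-radius
field in 9 steps (0.375° overlap between adjacent bars) along 4 angles (0°,
45°, 90°, 135°), 5 s per bar location. Each location runs one of nine
temporal conditions that vary image duration, inter-stimulus interval, and
image count (including three conditions with a matched 4 s total on-time,
and one uninterrupted 5 s presentation). Across the 9 runs of a session each
condition occurs exactly once at each bar location; the counterbalance is a
seeded cyclic assignment with a random phase per location. Epoch boundaries
are laid out at exact millisecond times and rounded per boundary to the
10 ms frame grid, so rounding never accumulates and conditions whose nominal
periods are not frame multiples (e.g. 15 images in 5 s) still fit their
slot. Blank periods between sweeps are not modeled (none are specified for
the design); a run is exactly $4 \times 9 \times 5 = 180$ s.

The *toonotopy* contrast design uses 12 steps of 2 s each (0.27° overlap;
the implied bar width, $(24 + 11 \times 0.27)/12 \approx 2.25°$, makes the
steps tile the field exactly) with images refreshing at 8 Hz. Because the
movie is binarized, a continuously visible bar whose content changes has no
canonical binarization. By default each 125 ms image epoch is rendered with
a one-frame off gap at the refresh, so the design's 8 Hz presentation rate
actually reaches the transient channels — a rendering with no within-step
temporal structure (`refresh_gaps = FALSE`) would make the simulated design
blind to the very property that defines it, and yields center-recovery
errors far beyond what this design is reported to support.
Adjacent-bar overlap is split symmetrically about the bar center in both
designs.

## Hemodynamics

The HRF is a difference of two gamma densities, each parameterized by peak
latency and FWHM (defaults 5.4/5.2 s and 10.9/7.35 s — the Vistasoft
parameterization). The mapping (peak, FWHM) → (shape, scale) uses
peak = $(k-1)\theta$ with the FWHM solved numerically. The undershoot
amplitude is not part of that parameterization; we subtract the
peak-normalized undershoot gamma at a conventional weight of 0.35 and
normalize the kernel maximum to 1. The subtraction pulls the combined peak
slightly (~0.15 s) before the nominal first-gamma latency, which is inherent
to any two-gamma difference. Voxel-wise HRF optimization alternates a
36-condition GLM (one condition per bar location and orientation, coded as
full-slot boxcars that deliberately ignore the within-slot temporal
structure; per-run intercepts included) with bounded derivative-free updates
of the four latency/width parameters, to a relative-RSS tolerance of
$10^{-4}$ and at most 50 outer iterations.

Downsampling to 1 s is the mean over each 100-frame bin. Both stages are
implemented together: convolving with the HRF-convolved-with-boxcar kernel
and sampling every 100th frame, which is algebraically identical and much
cheaper. Predicted time courses are mean-removed per run, matching the
percent-signal-change convention of preprocessed fMRI data.

## The synthesizer and its noise model

Ground-truth populations sample $x, y$ iid from $N(0, 5^2)$ rejected to
eccentricity $\le 10°$ (a normal distribution spanning the 0–10°
eccentricity range of the experiment), $\sigma$ from $N(1.6, 0.7^2)$
truncated to $[0.2, 3]°$ (the stated range, centered, SD a quarter of the
range), and temporal parameters uniformly within the solver's search
bounds. All three models share identical spatial ground truth for
cross-model comparisons. Gains are 1; the noise calibration makes overall
scale irrelevant.

Noise is a per-voxel composite of white Gaussian noise, "physiological"
sinusoids (cardiac ~1.17 Hz and respiratory ~0.3 Hz, random phases), and a
slow per-run cosine drift, mixed at 50/25/25 power and scaled so that the
realized SNR — $10\log_{10}$ of the demeaned power ratio — hits the target
exactly (closed-loop, per voxel). The *study noise level* used by the
validation pipeline is expressed through the variance explained it leaves
for the true prediction: for zero-mean signal and independent noise, the
non-centered $R^2$ of the true prediction against signal-plus-noise is
$S/(S+N)$, so a target $R^2_\ast = 0.3$ (the typical level of the empirical
experiment this framework targets) corresponds to
$10\log_{10}(0.3/0.7) \approx -3.68$ dB, via `snr_db_for_r2()`. We anchor
the default noise level to the variance-explained target rather than to a
dB figure because $R^2$ is the quantity the calibration is meant to
reproduce, and because dB conventions (amplitude vs. power, demeaned or
not) vary between toolboxes while the induced $R^2$ does not.

What the generator does *not* emulate: spatially correlated noise across
voxels, scanner spikes and motion, HRF variability across voxels (synthesis
and solving use the identical HRF by design, to isolate solver accuracy),
and non-Poisson image content within the binarized apertures. Passing
recovery tests therefore demonstrates the *solvability* of the models under
the designed stimulus and realistic noise power — not robustness to every
artifact of real data.

## The solver

**Grid stage.** Centers on a 0.4° lattice over the 24° stimulus extent
(3721 positions), 96 log-linearly spaced $\sigma$ in $[0.1, 12]°$, CST
$n \in \{0.25, 0.5, 0.75, 1\}$, DN-ST temporal parameters fixed at
$\tau_1 = 0.05$, $\tau_2 = 0.1$, $n = 2$, $\sigma_{DN} = 0.1$. Scoring all
~357k grid points per voxel is made tractable by surrogates that are linear
in the 36 per-aperture overlaps of the candidate Gaussian: exact for the
Spatial model (grid $R^2$ reduces to two matrix products against
precomputed Gram matrices); *slot-factorized* for CST (the BOLD response of
each 5 s slot is precomputed per temporal condition and scales with the
compressed overlap $g_k^n$ — exact up to channel responses straddling slot
boundaries); linear localization for DN-ST (whose normalization does not
factorize), followed by exact re-scoring of the best spatial candidates
over a coarse factorial of normalization parameters — with the temporal
defaults alone, DN-ST fits systematically converge to boundary-pinned
local minima. The top-ranked candidates (~20) are then re-scored with the
exact forward model and the best exact $R^2$ wins; ties break toward
smaller $\sigma$, then smaller eccentricity. For CST the grid stage
evaluates a coarse $\tau$ grid $\{4.93, 20, 45, 90\}$ (the first value is
the conventional default): with a single fixed $\tau$, sluggish
ground-truth pRFs (response delay $8\tau$ up to ~7 s) have their apparent
position displaced along the sweep directions by more than the ±5° box the
fine stage is allowed to search, so a τ-blind grid can place the fine
search in the wrong basin. Gain weights are solved linearly at every grid
point (jointly for the two CST regressors).

**Fine stage.** All parameters are optimized simultaneously by bounded
Levenberg–Marquardt (finite-difference Jacobian, box bounds by projection,
gains profiled out by OLS at every evaluation), from three restarts: the
first at the grid estimate, the others with temporal parameters drawn
uniformly within the search bounds (seeded, recorded in the result). The
best restart by the non-centered variance explained
$R^2 = 1 - \sum_t(\mathrm{model}-\mathrm{data})^2 / \sum_t \mathrm{data}^2$
is returned, after a short extra polish. A least-squares method was chosen
over simplex/pattern search because the objective is a smooth
sum-of-squares in all parameters; it reaches the same optima in several
times fewer forward evaluations, which is what makes noiseless recovery to
better than 99% accuracy practical at full problem size. Spatial bounds are
±5° around the grid estimate ($\sigma$ floored at 0.05°); temporal bounds
are the model bounds above. Convergence tolerances are $10^{-7}$ (relative
SS and parameter change), iteration caps 40/15/15 per restart plus a
15-iteration polish; restarts are skipped once a fit exceeds
$R^2 = 0.9999$, since restarts exist to escape local minima and a
numerically perfect fit leaves nothing to escape.

**Degenerate inputs.** All-zero voxels are flagged (`degenerate`), not
solved; all-zero predictions (pRFs entirely outside the stimulated field)
get zero gains. Voxels are never silently deleted: `low_r2` flags $R^2 <
0.1$ (single-model reporting policy) and `tau_at_bound` flags CST fits
pinned at $\tau = 100$ (excluded from temporal-parameter summaries
downstream); cross-model comparisons use all voxels.

**Cross-validation.** Threefold: six runs to fit (including gains), the
held-out three to evaluate the non-centered $R^2$; fold scores are averaged.
Run counts not divisible by three require an explicit fold specification.

## Validation scale

The packaged benchmark (`recovery_benchmark()`, also behind
`scripts/acceptance.R`) uses 30 voxels per model for the noiseless arm,
80 per model for the noisy arm, and the first 50 of the CST set for the
design comparison — a deliberate
desk-scale of the original 300-voxel simulations, chosen so the full
benchmark completes in well under half an hour on one CPU while keeping
the median-based recovery statistics reasonably stable (the
median-percentage metric inherits considerable draw-to-draw variance from
its near-zero `|x|`, `|y|` denominators, which is why the noisy arm uses
more than the minimal population). The benchmark reports medians of
90th-percentile-trimmed error distributions, the convention of the
recovery tables it is compared against; `mape()` defaults to untrimmed
medians.

## Known limitations

* The binarized stimulus cannot represent image *content*: a solid aperture
  carries none of the 8 Hz texture flicker of the real toonotopy stimulus,
  which is the stimulus property that would otherwise constrain pRF size
  under that design (small pRFs see the flicker, large pRFs average it
  out). Under the solid-aperture toonotopy rendering, compressive-model
  size estimates are close to unidentifiable — they slide along the
  size-compression valley toward the search bounds while fitting the noisy
  series slightly *better* than the true parameters — so the design
  comparison shows a much larger size error than a simulation whose movie
  retains image content would.
* DN-ST temporal parameters, especially $\tau_2$, are weakly constrained by
  designs with few prolonged presentations; expect broader recovery error
  there than for the CST $\tau$.
* The percentage-error metric is undefined at zero ground truth and
  unstable near it; pRFs with near-zero $|x|$ or $|y|$ dominate the tails
  of center-recovery error distributions.
* The grid surrogates are ranking devices; their approximation error is
  absorbed by exact re-scoring and the fine stage, but a pathological voxel
  could in principle be mis-ranked. The fine stage's ±5° spatial box is the
  hard limit on how far the coarse stage may err.
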