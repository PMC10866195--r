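# prfst — spatiotemporal population receptive field modeling

fMRI population receptive field (pRF) mapping traditionally estimates only
the *spatial* tuning of each voxel: the center `(x, y)` and size `σ` of a 2D
Gaussian in visual space. Yet the neurons pooled by a voxel also integrate
over *time*, on scales (tens to hundreds of milliseconds) two orders of
magnitude faster than the BOLD signal. `prfst` is an image-computable
framework for recovering those spatiotemporal receptive fields from 1 s
fMRI samples. It is aimed at visual-neuroscience researchers who want to
simulate, fit, and validate spatiotemporal pRF models against traveling-bar
mapping designs.

The package implements three forward models that map a binarized space–time
stimulus `I(X, Y, t)` (61 × 61 px, 10 ms frames) to predicted BOLD:

* **Spatial** — linear: `BOLD = β ([I ⋅ RF] ∗ HRF)`, with
  `RF(X,Y) = exp(−((X−x)² + (Y−y)²) / 2σ²)`.
* **CST** (compressive spatiotemporal) — sustained, on- and off-transient
  temporal channels (gamma and difference-of-gamma impulse responses with a
  shared time constant τ), each rectified and compressed:
  `p_i(t) = [ReLU(h_i ∗ d)]^n`, then
  `BOLD = β_sus (p₁ ∗ HRF) + β_tran ([p₂ + p₃] ∗ HRF)`.
* **DN-ST** (delayed normalization) — divisive normalization with a delayed
  pool: `p(t) = |r|^n / (σ_DN^n + [|r| ∗ e^{−t/τ₂}]^n)` with
  `r = (t e^{−t/τ₁}) ∗ d`.

Around the models sit the pieces needed to validate them end to end: the
spatiotemporal bar-sweep stimulus generator (9 temporal conditions,
counterbalanced across 9 runs) and an 8 Hz "toonotopy" contrast design; a
two-gamma HRF with voxel-wise optimization; a synthesizer that produces
noisy simulated voxels at a calibrated noise level; a two-stage
coarse-to-fine solver (full grid search with fast exact/surrogate scoring,
then bounded Levenberg–Marquardt with three restarts); and recovery metrics
(median absolute percentage error, Pearson r, permutation model comparison,
eccentricity binning, temporal-window summaries).

## Worked example

Simulate three CST voxels under the full 9-run spatiotemporal design, add
noise at the study level (ground-truth prediction explains ~0.3 of the
variance), and solve them:

```r
library(prfst)

stim <- stim_spatiotemporal(seed = 1)          # 9 runs x 180 s, 10 ms frames
gt   <- sample_ground_truth("cst", n = 3, seed = 11)
bold <- synthesize_bold(gt, stim)              # noiseless, 1 s sampling
noisy <- add_noise(bold, noise_spec(target_snr_db = snr_db_for_r2(0.3),
                                    seed = 42))
fit <- solve_prf(noisy, stim, "cst", seed = 1)
round(fit[, c("x", "y", "sigma", "tau", "n_exp", "r2")], 2)
round(gt[, c("x", "y", "sigma", "tau", "n_exp")], 2)
```

```
      x     y sigma   tau n_exp   r2
1 -2.40 -0.19  0.10 85.44  0.57 0.32
2  8.34 -2.48  0.82 74.72  0.93 0.31
3 -4.67  7.00  2.07 15.02  0.25 0.30
      x     y sigma   tau n_exp
1 -2.96  0.13  0.64 82.90  0.67
2  8.47 -2.77  0.84 77.28  0.72
3 -4.67  6.62  2.01 16.01  0.26
```

Each row is one voxel (fitted above, ground truth below): from data in
which the true model explains only ~30% of the variance (`r2`), the solver
recovers the pRF centers to a few tenths of a degree and the CST temporal
constant τ to within a few samples (τ is in 10 ms samples, so τ = 83 is an
830 ms gamma time constant; see `cst_tau_ms()` / `cst_peak_ms()`). Size σ
is the hardest parameter at this noise level — voxel 1's small pRF comes
back too small, a known σ–compression trade-off. The `recovery_report()` /
`recovery_benchmark()` functions aggregate such fits into per-parameter
median absolute percentage errors against the ground truth.

The command-line front end in `inst/cli/prfst` wraps the same functions
(`simulate-stimulus`, `synthesize`, `solve`, `validate`, `report`).

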