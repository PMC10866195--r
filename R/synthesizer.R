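# solver search bounds, shared by the ground-truth sampler and fine search
CST_BOUNDS <- list(tau = c(4, 100), n_exp = c(0.1, 1))
DNST_BOUNDS <- list(tau1 = c(0.01, 1), tau2 = c(0.01, 1),
                    sigma_dn = c(0.01, 0.5), n_dn = c(1, 6))

#' Sample a ground-truth pRF population
#'
#' Spatial parameters: `x` and `y` are iid N(0, 5^2), rejection-sampled so
#' the eccentricity stays within the 10 deg extent that the mapping stimulus
#' covers well; sigma is N(1.6, 0.7^2) truncated to \[0.2, 3\] deg.
#' Model-specific temporal parameters are uniform within the solver's
#' fine-search bounds. Gains are 1 (the synthesizer's noise calibration makes
#' overall scale irrelevant).
#'
#' @param model_kind `"spatial"`, `"cst"`, or `"dnst"`.
#' @param n Number of voxels (default 300).
#' @param seed RNG seed.
#' @param spatial_from Optional ground-truth set whose spatial parameters
#'   (x, y, sigma) are reused, for cross-model comparisons with identical
#'   spatial ground truth.
#' @return Data frame (class `ground_truth`) with one row per voxel and
#'   attributes `model_kind` and `seed`.
#' @export
sample_ground_truth <- function(model_kind = c("spatial", "cst", "dnst"),
                                n = 300L, seed = 1L, spatial_from = NULL) {
  model_kind <- match.arg(model_kind)
  stopifnot(n >= 1)
  # spatial parameters are drawn voxel by voxel so that (a) all model kinds
  # with the same seed share identical spatial ground truth (spatial draws
  # precede the temporal stream) and (b) the first k voxels of a size-n set
  # equal a size-k set (prefix stability, used by the design comparison)
  if (is.null(spatial_from)) {
    x <- y <- sigma <- numeric(n)
    withr::with_seed(seed, {
      for (i in seq_len(n)) {
        repeat {
          cx <- rnorm(1, 0, 5)
          cy <- rnorm(1, 0, 5)
          if (cx^2 + cy^2 <= 100) break
        }
        x[i] <- cx
        y[i] <- cy
        sigma[i] <- rtrunc_norm(1, 1.6, 0.7, 0.2, 3)
      }
    })
  } else {
    stopifnot(nrow(spatial_from) >= n)
    x <- spatial_from$x[seq_len(n)]
    y <- spatial_from$y[seq_len(n)]
    sigma <- spatial_from$sigma[seq_len(n)]
  }
  out <- data.frame(voxel = seq_len(n), x = x, y = y, sigma = sigma)
  withr::with_seed(seed + 1000003L, {
    if (model_kind == "cst") {
      u <- matrix(runif(2 * n), ncol = 2, byrow = TRUE)
      out$tau <- CST_BOUNDS$tau[1] + diff(CST_BOUNDS$tau) * u[, 1]
      out$n_exp <- CST_BOUNDS$n_exp[1] + diff(CST_BOUNDS$n_exp) * u[, 2]
    } else if (model_kind == "dnst") {
      u <- matrix(runif(4 * n), ncol = 4, byrow = TRUE)
      out$tau1 <- DNST_BOUNDS$tau1[1] + diff(DNST_BOUNDS$tau1) * u[, 1]
      out$tau2 <- DNST_BOUNDS$tau2[1] + diff(DNST_BOUNDS$tau2) * u[, 2]
      out$sigma_dn <- DNST_BOUNDS$sigma_dn[1] +
        diff(DNST_BOUNDS$sigma_dn) * u[, 3]
      out$n_dn <- DNST_BOUNDS$n_dn[1] + diff(DNST_BOUNDS$n_dn) * u[, 4]
    }
  })
  structure(out, model_kind = model_kind, seed = seed,
            class = c("ground_truth", "data.frame"))
}

# rejection-free truncated normal via inverse CDF
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  p <- runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd))
  qnorm(p, mean, sd)
}

#' @importFrom stats pnorm qnorm
NULL

gt_params <- function(gt, i) {
  kind <- attr(gt, "model_kind")
  r <- gt[i, ]
  switch(kind,
    spatial = spatial_prf(r$x, r$y, r$sigma),
    cst = cst_prf(r$x, r$y, r$sigma, r$tau, r$n_exp),
    dnst = dnst_prf(r$x, r$y, r$sigma, r$tau1, r$tau2, r$sigma_dn, r$n_dn))
}

#' Synthesize noiseless BOLD time courses
#'
#' Runs the forward model of the ground-truth set's kind for every voxel:
#' neural prediction at 10 ms, convolution with the HRF, averaging to 1 s, and
#' per-run mean removal (percent-signal-change convention). Deterministic.
#'
#' @param gt A [sample_ground_truth()] set.
#' @param stim A `stim_sequence`.
#' @param hrf_par [hrf_params()] used for the projection (default Vistasoft).
#' @return Matrix (1 s samples x voxels) of class `voxel_timecourses`, with
#'   attributes `n_runs`, `ground_truth`.
#' @export
synthesize_bold <- function(gt, stim, hrf_par = hrf_default()) {
  hrf <- two_gamma_hrf(hrf_par)
  gbar <- hrf_bin_kernel(hrf)
  a <- stim_cpp_args(stim)
  kind <- attr(gt, "model_kind")
  n_sec <- stim$n_runs * stim$frames_per_run / SAMPLES_PER_SEC
  out <- matrix(0, n_sec, nrow(gt))
  for (i in seq_len(nrow(gt))) {
    p <- gt_params(gt, i)
    g <- aperture_overlap(stim, p)
    out[, i] <- switch(kind,
      spatial = {
        drv <- cpp_drive(a$run, a$s, a$e, a$ap, g, a$n_runs, a$T_run)
        cpp_bold_from_neural(drv, gbar, a$n_runs, a$T_run, TRUE)
      },
      cst = {
        k1 <- cum_kernel(sustained_irf(p$tau))
        k2 <- cum_kernel(transient_irfs(p$tau)$on)
        pr <- cpp_bold_cst(a$run, a$s, a$e, a$ap, g, a$n_runs, a$T_run,
                           k1$C, k1$tail, k2$C, k2$tail, p$n_exp, gbar, TRUE)
        pr[, 1] * p$beta_sus + pr[, 2] * p$beta_tran
      },
      dnst = {
        kk <- dnst_irfs(p$tau1, p$tau2)
        k1 <- cum_kernel(kk$h1)
        pr <- cpp_bold_dnst(a$run, a$s, a$e, a$ap, g, a$n_runs, a$T_run,
                            k1$C, k1$tail, kk$lambda2, p$n_dn, p$sigma_dn,
                            gbar, TRUE)
        pr[, 1] * p$beta
      })
  }
  structure(out, n_runs = stim$n_runs, ground_truth = gt,
            class = c("voxel_timecourses", "matrix", "array"))
}

#' Noise specification
#'
#' Composite fMRI-like additive noise: white Gaussian, "physiological"
#' sinusoids (cardiac ~1.17 Hz and respiratory ~0.3 Hz aliases with random
#' phases), and a slow per-run cosine drift. Component powers are mixed at
#' `weights` and the composite is scaled so the realized signal-to-noise
#' ratio ([measure_snr_db()], demeaned power ratio) matches `target_snr_db`
#' exactly per voxel.
#'
#' @param target_snr_db Target SNR in dB (`Inf` for no noise). The default
#'   0.1 dB means nearly equal signal and noise power.
#' @param weights Power mix of the white / physiological / drift components.
#' @param cardiac_hz,resp_hz Physiological frequencies (Hz).
#' @param drift_period_factor Drift period as a multiple of run length.
#' @param seed RNG seed (per-voxel streams are derived from it).
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(target_snr_db = 0.1,
                       weights = c(white = 0.5, physio = 0.25, drift = 0.25),
                       cardiac_hz = 1.17, resp_hz = 0.3,
                       drift_period_factor = 1.5, seed = 1L) {
  stopifnot(length(weights) == 3, all(weights >= 0), sum(weights) > 0)
  structure(list(target_snr_db = target_snr_db,
                 weights = weights / sum(weights),
                 cardiac_hz = cardiac_hz, resp_hz = resp_hz,
                 drift_period_factor = drift_period_factor, seed = seed),
            class = "noise_spec")
}

#' Measure a signal-to-noise ratio in decibels
#'
#' `10 log10(P_signal / P_noise)` with power the mean squared deviation from
#' the series mean.
#'
#' @param signal,noise Equal-length numeric vectors.
#' @return SNR in dB.
#' @export
measure_snr_db <- function(signal, noise) {
  stopifnot(length(signal) == length(noise))
  10 * log10(mean((signal - mean(signal))^2) / mean((noise - mean(noise))^2))
}

#' SNR that yields a given ground-truth variance explained
#'
#' For zero-mean signal and independent additive noise, the variance explained
#' of the true prediction against the noisy series is `R2 = S / (S + N)`, so
#' the SNR (power ratio) producing a target `R2` is `R2 / (1 - R2)`:
#' `10 log10(R2 / (1 - R2))` dB. Used to express the simulation noise level
#' in terms of the typical empirical variance explained (~0.3, i.e. -3.68 dB).
#'
#' @param r2 Target variance explained in (0, 1).
#' @return SNR in dB.
#' @export
snr_db_for_r2 <- function(r2) {
  stopifnot(r2 > 0, r2 < 1)
  10 * log10(r2 / (1 - r2))
}

#' Add calibrated composite noise to synthetic time courses
#'
#' Each voxel receives an independent composite noise draw (white +
#' physiological sinusoids + low-frequency drift, mixed at the configured
#' power weights), scaled so the realized demeaned power SNR equals the target
#' exactly. All components are zero-mean.
#'
#' @param bold Matrix (1 s samples x voxels) or vector; typically from
#'   [synthesize_bold()].
#' @param spec A [noise_spec()].
#' @param n_runs Number of runs the samples span (taken from the `bold`
#'   attribute when present).
#' @return Noisy series with the same shape; attribute `noise_spec` records
#'   the calibration.
#' @export
add_noise <- function(bold, spec = noise_spec(), n_runs = NULL) {
  vec_in <- is.null(dim(bold))
  m <- as.matrix(bold)
  if (is.null(n_runs)) n_runs <- attr(bold, "n_runs")
  if (is.null(n_runs)) n_runs <- 1L
  if (is.infinite(spec$target_snr_db)) return(bold)
  n_sec <- nrow(m)
  for (v in seq_len(ncol(m))) {
    s <- m[, v]
    if (sd(s) == 0) {
      stop("cannot calibrate SNR: voxel ", v, " has zero-variance signal")
    }
    u <- withr::with_seed(spec$seed + v - 1L,
                          composite_noise(n_sec, n_runs, spec))
    scale <- sd_pop(s) / (10^(spec$target_snr_db / 20) * sd_pop(u))
    m[, v] <- s + scale * u
  }
  out <- if (vec_in) m[, 1] else m
  keep <- setdiff(names(attributes(bold)), c("dim", "dimnames", "names"))
  for (nm in keep) attr(out, nm) <- attr(bold, nm)
  attr(out, "noise_spec") <- spec
  out
}

sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

composite_noise <- function(n_sec, n_runs, spec) {
  t_s <- seq_len(n_sec) - 1
  white <- rnorm(n_sec)
  physio <- sin(2 * pi * spec$cardiac_hz * t_s + runif(1, 0, 2 * pi)) +
    sin(2 * pi * spec$resp_hz * t_s + runif(1, 0, 2 * pi))
  run_len <- n_sec / n_runs
  drift <- unlist(lapply(seq_len(n_runs), function(r) {
    tt <- seq_len(run_len) - 1
    cos(2 * pi * tt / (spec$drift_period_factor * run_len) +
          runif(1, 0, 2 * pi))
  }))
  comp <- cbind(white, physio, drift)
  comp <- sweep(comp, 2, apply(comp, 2, mean))             # zero-mean
  pw <- apply(comp, 2, function(z) mean(z^2))
  pw[pw == 0] <- 1
  as.vector(comp %*% (sqrt(spec$weights / pw)))
}
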