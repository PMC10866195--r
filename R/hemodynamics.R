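#' Two-gamma HRF parameters
#'
#' The hemodynamic response function is a difference of two gamma densities,
#' each parameterized by its peak latency and full width at half maximum
#' (FWHM) in seconds, with the second (undershoot) gamma subtracted at
#' relative amplitude `undershoot_weight`. Defaults are the Vistasoft values
#' (peaks 5.4 and 10.9 s, FWHMs 5.2 and 7.35 s); the undershoot amplitude is
#' not part of that parameterization and defaults to a conventional 0.35.
#'
#' @param peak1_s,fwhm1_s First (positive) gamma peak latency and FWHM (s).
#' @param peak2_s,fwhm2_s Undershoot gamma peak latency and FWHM (s).
#' @param undershoot_weight Relative undershoot amplitude (on peak-normalized
#'   gammas).
#' @return An object of class `hrf_params`.
#' @export
hrf_params <- function(peak1_s = 5.4, fwhm1_s = 5.2, peak2_s = 10.9,
                       fwhm2_s = 7.35, undershoot_weight = 0.35) {
  if (peak1_s <= 0 || peak2_s <= 0 || fwhm1_s <= 0 || fwhm2_s <= 0) {
    stop("parameter-domain: HRF peaks and widths must be > 0")
  }
  if (peak2_s <= peak1_s) {
    stop("parameter-domain: undershoot peak must follow the first peak")
  }
  structure(list(peak1_s = peak1_s, fwhm1_s = fwhm1_s, peak2_s = peak2_s,
                 fwhm2_s = fwhm2_s, undershoot_weight = undershoot_weight),
            class = "hrf_params")
}

#' @rdname hrf_params
#' @export
hrf_default <- function() hrf_params()

# ---- (peak, fwhm) -> gamma (shape, scale) ---------------------------------
# peak = (k - 1) * theta; FWHM scales with theta, so FWHM/peak pins the shape
# k through the unit-scale width u(k) (solved numerically and memoized).

gamma_unit_fwhm <- function(k) {
  m <- k - 1
  fm <- dgamma(m, shape = k)
  half <- function(t) dgamma(t, shape = k) - fm / 2
  lo_t <- m * 0.5
  while (half(lo_t) > 0 && lo_t > 1e-300) lo_t <- lo_t * 0.25
  lo <- uniroot(half, c(lo_t, m), tol = 1e-12)$root
  hi_t <- m + 4 * sqrt(k)
  while (half(hi_t) > 0) hi_t <- hi_t + 4 * sqrt(k)
  hi <- uniroot(half, c(m, hi_t), tol = 1e-12)$root
  hi - lo
}

.gamma_shape_cache <- new.env(parent = emptyenv())

gamma_from_peak_fwhm <- function(peak, fwhm) {
  key <- sprintf("%.8g_%.8g", peak, fwhm)
  hit <- .gamma_shape_cache[[key]]
  if (!is.null(hit)) return(hit)
  ratio <- fwhm / peak
  f <- function(k) gamma_unit_fwhm(k) / (k - 1) - ratio
  k <- uniroot(f, c(1.02, 2000), tol = 1e-9)$root
  out <- list(shape = k, scale = peak / (k - 1))
  .gamma_shape_cache[[key]] <- out
  out
}

#' Two-gamma hemodynamic response kernel
#'
#' Builds the HRF kernel at 10 ms resolution: the positive gamma minus
#' `undershoot_weight` times the undershoot gamma (each peak-normalized
#' before weighting), finally normalized so the kernel maximum is 1.
#'
#' @param params An [hrf_params()].
#' @param dt_ms Sampling interval, default 10 ms.
#' @param span_s Kernel support in seconds (default 30 s, ample for the
#'   default parameters).
#' @return Numeric kernel with attributes `dt_ms` and `params`.
#' @export
two_gamma_hrf <- function(params = hrf_default(), dt_ms = 10, span_s = 30) {
  g1 <- gamma_from_peak_fwhm(params$peak1_s, params$fwhm1_s)
  g2 <- gamma_from_peak_fwhm(params$peak2_s, params$fwhm2_s)
  t_s <- (seq_len(round(span_s * 1000 / dt_ms)) - 0.5) * dt_ms / 1000
  a1 <- dgamma(t_s, shape = g1$shape, scale = g1$scale)
  a2 <- dgamma(t_s, shape = g2$shape, scale = g2$scale)
  h <- a1 / max(a1) - params$undershoot_weight * (a2 / max(a2))
  h <- h / max(h)
  structure(h, dt_ms = dt_ms, params = params)
}

# HRF combined with 1 s bin averaging: convolving a neural series with Gbar
# and sampling every 100th frame equals convolving with the HRF and then
# averaging each 1 s bin.
hrf_bin_kernel <- function(hrf) {
  spf <- SAMPLES_PER_SEC
  g <- convolve(c(as.numeric(hrf), numeric(spf)), rev(rep(1 / spf, spf)),
                type = "open")[seq_len(length(hrf) + spf - 1)]
  # drop the numerically negligible tail
  keep <- max(which(abs(g) > 1e-7 * max(abs(g))))
  g[seq_len(keep)]
}

#' Project a neural time course to BOLD
#'
#' Convolves each neural channel (10 ms) with the HRF, averages into 1 s bins,
#' and combines channels with gain weights. For the three-channel CST neural
#' output the on- and off-transient channels are first summed into a single
#' transient regressor, so `betas` has length 2 (sustained, transient).
#' Convolution restarts at run boundaries.
#'
#' @param neural A `neural_timecourse` from [predict_neural()], or any
#'   frames-x-channels matrix.
#' @param hrf Kernel from [two_gamma_hrf()].
#' @param betas Channel gains (recycled from the `prf_params` defaults of 1).
#' @param n_runs Number of equal-length runs the rows span.
#' @param demean_runs Subtract each run's mean (percent-signal-change
#'   convention)? Default `FALSE`.
#' @return Numeric vector at 1 s sampling, length `floor(frames / 100)` per
#'   run times `n_runs`.
#' @export
neural_to_bold <- function(neural, hrf, betas = NULL, n_runs = 1L,
                           demean_runs = FALSE) {
  reg <- bold_regressors(neural, hrf, n_runs = n_runs,
                         demean_runs = demean_runs)
  if (is.null(betas)) betas <- rep(1, ncol(reg))
  if (length(betas) != ncol(reg)) {
    stop("shape: expected ", ncol(reg), " betas, got ", length(betas))
  }
  as.vector(reg %*% betas)
}

#' @rdname neural_to_bold
#' @export
bold_regressors <- function(neural, hrf, n_runs = 1L, demean_runs = FALSE) {
  m <- as.matrix(neural)
  if (nrow(m) %% (n_runs * SAMPLES_PER_SEC) != 0) {
    stop("shape: frames (", nrow(m), ") must divide into ", n_runs,
         " runs of whole seconds")
  }
  ch <- colnames(m)
  if (!is.null(ch) && all(c("transient_on", "transient_off") %in% ch)) {
    m <- cbind(sustained = m[, "sustained"],
               transient = m[, "transient_on"] + m[, "transient_off"])
  }
  gbar <- hrf_bin_kernel(hrf)
  T_run <- nrow(m) / n_runs
  out <- vapply(seq_len(ncol(m)), function(j) {
    cpp_bold_from_neural(m[, j], gbar, n_runs, T_run, demean_runs)
  }, numeric(nrow(m) / SAMPLES_PER_SEC))
  colnames(out) <- colnames(m)
  out
}

# ---- voxel-wise HRF optimization ------------------------------------------

#' Bar-location condition design
#'
#' One condition per bar location and orientation (9 steps x 4 angles = 36 for
#' the spatiotemporal design), coded as a full-slot boxcar that disregards the
#' within-slot temporal profile.
#'
#' @param stim A `stim_sequence`.
#' @return List with the condition interval table and dimensions, used by
#'   [hrf_condition_regressors()].
#' @export
condition_design <- function(stim) {
  sl <- stim$slots
  cond_id <- sl$ap  # aperture index == location x orientation
  list(run = sl$run, start0 = sl$t0_frame,
       end0 = sl$t0_frame + stim$frames_per_slot, cond = cond_id,
       n_cond = ncol(stim$apertures), n_runs = stim$n_runs,
       T_run = stim$frames_per_run)
}

#' GLM regressors for a condition design under an HRF
#'
#' @param design From [condition_design()].
#' @param hrf Kernel from [two_gamma_hrf()].
#' @return Matrix (1 s samples x conditions).
#' @export
hrf_condition_regressors <- function(design, hrf) {
  gbar <- hrf_bin_kernel(hrf)
  Hc <- c(0, cumsum(gbar))
  n_sec <- design$T_run / SAMPLES_PER_SEC
  X <- matrix(0, design$n_runs * n_sec, design$n_cond)
  base <- seq_len(n_sec) * SAMPLES_PER_SEC - 1  # 0-based frame of each bin end
  lookup <- function(d) Hc[pmin(pmax(d + 1, 1), length(Hc))]
  for (i in seq_along(design$cond)) {
    rows <- (design$run[i] - 1) * n_sec + seq_len(n_sec)
    X[rows, design$cond[i]] <- X[rows, design$cond[i]] +
      lookup(base - design$start0[i]) - lookup(base - design$end0[i])
  }
  X
}

#' Voxel-wise HRF optimization
#'
#' Alternating scheme: given the current HRF, condition amplitudes are fit by
#' ordinary least squares (with per-run intercepts); the four latency/width
#' parameters are then updated by bounded derivative-free (Nelder-Mead on a
#' logistic box transform) minimization of the residual sum of squares, with
#' the amplitudes re-profiled at every objective evaluation. Iterates until
#' the relative RSS improvement falls below `tol`.
#'
#' @param data Voxel time course at 1 s (vector over concatenated runs).
#' @param design From [condition_design()].
#' @param init Initial [hrf_params()].
#' @param tol Relative RSS convergence tolerance.
#' @param max_iter Maximum outer iterations.
#' @param free_undershoot Also optimize the undershoot amplitude?
#' @return List: `hrf` (optimized [hrf_params()]), `betas`, `rss_trace`.
#' @export
optimize_voxel_hrf <- function(data, design, init = hrf_default(),
                               tol = 1e-4, max_iter = 50,
                               free_undershoot = FALSE) {
  n_sec <- design$T_run / SAMPLES_PER_SEC
  run_of <- rep(seq_len(design$n_runs), each = n_sec)
  intercepts <- outer(run_of, seq_len(design$n_runs), `==`) * 1
  fit_rss <- function(p) {
    pars <- hrf_params(p[1], p[2], p[3], p[4],
                       if (free_undershoot) p[5] else init$undershoot_weight)
    X <- cbind(hrf_condition_regressors(design, two_gamma_hrf(pars)),
               intercepts)
    qr_x <- qr(X)
    if (qr_x$rank < ncol(X)) stop("singular-design: GLM design is rank deficient")
    res <- qr.resid(qr_x, data)
    list(rss = sum(res^2), pars = pars, qr = qr_x)
  }
  p0 <- c(init$peak1_s, init$fwhm1_s, init$peak2_s, init$fwhm2_s,
          if (free_undershoot) init$undershoot_weight)
  lower <- c(2, 1, 5, 2, if (free_undershoot) 0)
  upper <- c(10, 12, 20, 16, if (free_undershoot) 1)
  cur <- fit_rss(p0)
  trace <- cur$rss
  p <- p0
  for (it in seq_len(max_iter)) {
    opt <- bounded_nm(function(q) {
      r <- try(fit_rss(q)$rss, silent = TRUE)
      if (inherits(r, "try-error")) Inf else r
    }, p, lower, upper, maxit = 200)
    if (opt$value < cur$rss - 1e-12) {
      p <- opt$par
      prev <- cur$rss
      cur <- fit_rss(p)
      trace <- c(trace, cur$rss)
      if ((prev - cur$rss) / max(prev, .Machine$double.eps) < tol) break
    } else {
      trace <- c(trace, cur$rss)
      break
    }
  }
  betas <- qr.coef(cur$qr, data)
  list(hrf = cur$pars, betas = betas[seq_len(design$n_cond)],
       rss_trace = trace)
}

# Nelder-Mead inside a box via a logistic reparameterization.
bounded_nm <- function(fn, par, lower, upper, maxit = 500) {
  w <- upper - lower
  eps <- 1e-6
  frac <- pmin(pmax((par - lower) / w, eps), 1 - eps)
  z0 <- log(frac / (1 - frac))
  to_par <- function(z) lower + w / (1 + exp(-z))
  res <- stats::optim(z0, function(z) fn(to_par(z)), method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-10))
  list(par = to_par(res$par), value = res$value)
}
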