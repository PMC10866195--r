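#' @useDynLib prfst, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats dgamma qgamma rnorm runif median convolve uniroot
#'   p.adjust cor sd quantile
NULL

# time base: neural stage at dt = 10 ms; tau for the CST gamma kernels is
# expressed in these 10 ms samples (so tau = 100 is one second), matching the
# solver bounds; DN-ST tau1/tau2 are in seconds.
DT_MS <- 10
SAMPLES_PER_SEC <- 100

#' Parameter constructors
#'
#' Per-voxel pRF parameter bundles for the three forward models. Spatial
#' parameters are shared: center `(x, y)` and size `sigma`, all in degrees of
#' visual angle. The CST model adds a temporal constant `tau` (in 10 ms model
#' samples; the sustained gamma kernel peaks at `8 * tau` samples) and a
#' compressive exponent `n_exp` applied after rectification, with channel
#' gains `beta_sus`, `beta_tran`. The DN-ST model adds the impulse-response
#' constant `tau1` (s), the normalization decay constant `tau2` (s), the
#' semisaturation constant `sigma_dn` and exponent `n_dn`, with gain `beta`.
#'
#' @param x,y pRF center (deg).
#' @param sigma pRF size (deg), > 0.
#' @param tau CST temporal constant (10 ms samples).
#' @param n_exp CST compressive exponent in \[0.1, 1\].
#' @param beta_sus,beta_tran,beta Channel gains.
#' @param tau1,tau2 DN-ST time constants (s), in \[0.01, 1\].
#' @param sigma_dn DN-ST semisaturation constant, in \[0.01, 0.5\].
#' @param n_dn DN-ST exponent, in \[1, 6\].
#' @return A classed list (`spatial_prf`, `cst_prf`, or `dnst_prf`; all also
#'   `prf_params`).
#' @name prf_params
NULL

#' @rdname prf_params
#' @export
spatial_prf <- function(x, y, sigma, beta = 1) {
  stopifnot(is.finite(sigma))
  if (sigma <= 0) stop("parameter-domain: sigma must be > 0")
  structure(list(x = x, y = y, sigma = sigma, beta = beta),
            class = c("spatial_prf", "prf_params"))
}

#' @rdname prf_params
#' @export
cst_prf <- function(x, y, sigma, tau, n_exp, beta_sus = 1, beta_tran = 1) {
  if (sigma <= 0) stop("parameter-domain: sigma must be > 0")
  if (tau <= 0) stop("parameter-domain: tau must be > 0")
  if (n_exp < 0.1 - 1e-9 || n_exp > 1 + 1e-9) {
    stop("parameter-domain: n_exp must lie in [0.1, 1]")
  }
  structure(list(x = x, y = y, sigma = sigma, tau = tau, n_exp = n_exp,
                 beta_sus = beta_sus, beta_tran = beta_tran,
                 kappa_sus = 1, m_sus = 9, kappa_inh = 1.33, m_inh = 10),
            class = c("cst_prf", "prf_params"))
}

#' @rdname prf_params
#' @export
dnst_prf <- function(x, y, sigma, tau1, tau2, sigma_dn, n_dn, beta = 1) {
  if (sigma <= 0) stop("parameter-domain: sigma must be > 0")
  if (tau1 <= 0 || tau2 <= 0) stop("parameter-domain: tau1, tau2 must be > 0")
  if (sigma_dn <= 0) stop("parameter-domain: sigma_dn must be > 0")
  structure(list(x = x, y = y, sigma = sigma, tau1 = tau1, tau2 = tau2,
                 sigma_dn = sigma_dn, n_dn = n_dn, beta = beta),
            class = c("dnst_prf", "prf_params"))
}

#' Convert the CST temporal constant between model samples and milliseconds
#'
#' `tau` is carried internally in 10 ms model samples. `cst_tau_ms()` converts
#' to milliseconds; `cst_peak_ms()` gives the derived time-to-peak of the
#' sustained gamma kernel, `(m - 1) * kappa * tau` samples (80 ms per unit tau
#' at the default kappa = 1, m = 9).
#'
#' @param tau Temporal constant in 10 ms samples.
#' @param kappa,m Gamma kernel shape constants.
#' @return Milliseconds.
#' @export
cst_tau_ms <- function(tau) tau * DT_MS

#' @rdname cst_tau_ms
#' @export
cst_peak_ms <- function(tau, kappa = 1, m = 9) (m - 1) * kappa * tau * DT_MS

#' Isotropic 2D Gaussian receptive field
#'
#' `exp(-((X - x)^2 + (Y - y)^2) / (2 sigma^2))`, unnormalized (value 1 at the
#' center), evaluated at pixel centers.
#'
#' @param x,y,sigma Center and size in degrees.
#' @param grid A [pixel_grid()] (or any list with flattened meshes `X`, `Y`).
#' @return Numeric vector over pixels (same order as `grid$X`).
#' @export
gaussian_rf <- function(x, y, sigma, grid) {
  if (!is.finite(sigma) || sigma <= 0) {
    stop("parameter-domain: sigma must be > 0")
  }
  exp(-((grid$X - x)^2 + (grid$Y - y)^2) / (2 * sigma^2))
}

#' Spatial drive of a receptive field by the stimulus
#'
#' The dot product between each stimulus frame and the spatial receptive
#' field: `drive(t) = sum_pixels I(X, Y, t) * rf(X, Y)`, at 10 ms resolution.
#'
#' @param stim A `stim_sequence`.
#' @param rf Pixel-wise weight vector (e.g. from [gaussian_rf()]).
#' @return Numeric vector, one value per frame.
#' @export
spatial_drive <- function(stim, rf) {
  if (length(rf) != nrow(stim$apertures)) {
    stop("shape: rf has ", length(rf), " pixels, stimulus grid has ",
         nrow(stim$apertures))
  }
  g <- as.vector(crossprod(stim$apertures, rf))
  iv <- stim$intervals
  cpp_drive(iv$run, iv$start0, iv$end0, iv$ap, g, stim$n_runs,
            stim$frames_per_run)
}

# ---- neural temporal impulse response kernels ------------------------------

# quantile cutoff for kernel supports: mass beyond it is dropped (the same
# truncated kernels are used on the synthesis and solving sides)
KERNEL_Q <- 1 - 1e-4

#' Sustained (monophasic gamma) impulse response kernel
#'
#' Gamma density `(t / (kappa tau))^(m-1) exp(-t / (kappa tau)) / (kappa tau
#' (m-1)!)` sampled at frame midpoints and renormalized to unit sum. Time is
#' in model samples (10 ms); the kernel value at index `l` applies at lag `l`
#' frames. The peak sits at `(m - 1) * kappa * tau`.
#'
#' @param tau Temporal constant in 10 ms samples (> 0).
#' @param kappa,m Shape constants (defaults 1 and 9; `(m-1)!` is evaluated
#'   through the gamma function so non-integer `m` is allowed).
#' @return Numeric kernel vector (unit sum).
#' @export
sustained_irf <- function(tau, kappa = 1, m = 9) {
  if (!is.finite(tau) || tau <= 0) stop("parameter-domain: tau must be > 0")
  L <- ceiling(qgamma(KERNEL_Q, shape = m) * kappa * tau)
  t_mid <- seq_len(L) - 0.5
  h <- dgamma(t_mid, shape = m, scale = kappa * tau)
  h / sum(h)
}

#' Transient (biphasic) impulse response kernels
#'
#' The on-transient kernel is the difference of two unit-area gamma kernels:
#' the sustained excitatory gamma (kappa = 1, m = 9) minus a slower inhibitory
#' gamma (kappa = 1.33, m = 10), yielding a biphasic response whose positive
#' lobe peaks earlier than the sustained kernel and which integrates to ~0.
#' The off-transient kernel is its sign flip.
#'
#' @inheritParams sustained_irf
#' @return List with `on` and `off` kernel vectors.
#' @export
transient_irfs <- function(tau, kappa = 1, m = 9, kappa_inh = 1.33,
                           m_inh = 10) {
  if (!is.finite(tau) || tau <= 0) stop("parameter-domain: tau must be > 0")
  hA <- sustained_irf(tau, kappa, m)
  hB <- sustained_irf(tau, kappa_inh, m_inh)
  L <- max(length(hA), length(hB))
  h2 <- c(hA, numeric(L - length(hA))) - c(hB, numeric(L - length(hB)))
  list(on = h2, off = -h2)
}

#' DN-ST temporal filters
#'
#' The DN-ST impulse response is `h1(t) = t exp(-t / tau1)` (a gamma of shape
#' 2), discretized at 10 ms and normalized to unit sum so the semisaturation
#' scale is invariant to dt. The delayed-normalization term low-pass filters
#' the response with an exponential decay `h2(t) = exp(-t / tau2)`, likewise
#' unit-sum (a geometric kernel, applied as an exact first-order recursion).
#'
#' @param tau1,tau2 Time constants in seconds.
#' @return List with `h1` (kernel vector) and `lambda2`, the per-sample decay
#'   factor `exp(-dt / tau2)` of the recursive low-pass filter.
#' @export
dnst_irfs <- function(tau1, tau2) {
  if (tau1 <= 0 || tau2 <= 0) stop("parameter-domain: tau1, tau2 must be > 0")
  tau1_s <- tau1 * SAMPLES_PER_SEC
  L <- max(2, ceiling(qgamma(KERNEL_Q, shape = 2) * tau1_s))
  t_mid <- seq_len(L) - 0.5
  h1 <- dgamma(t_mid, shape = 2, scale = tau1_s)
  list(h1 = h1 / sum(h1),
       lambda2 = exp(-1 / (tau2 * SAMPLES_PER_SEC)))
}

#' Causal convolution with an impulse-response kernel
#'
#' Reference (FFT-based) causal convolution used by the plain-R prediction
#' path and as the oracle for the compiled one:
#' `y[t] = sum_{l>=1} h[l] x[t - l + 1]`, zero-padded on the left. Kernels
#' are sampled at frame midpoints, so `h[1]` weights the frame in which an
#' input arrives.
#'
#' @param x Input series.
#' @param h Kernel.
#' @return Series of the same length as `x`.
#' @export
apply_irf <- function(x, h) {
  n <- length(x)
  full <- convolve(c(x, numeric(length(h))), rev(h), type = "open")
  out <- full[seq_len(n)]
  out[abs(out) < 1e-12] <- 0
  out
}

# interval-table arguments for the compiled forward paths
stim_cpp_args <- function(stim) {
  iv <- stim$intervals
  list(run = iv$run, s = iv$start0, e = iv$end0, ap = iv$ap,
       n_runs = stim$n_runs, T_run = stim$frames_per_run)
}

# aperture overlap vector g (length K) for spatial params
aperture_overlap <- function(stim, params) {
  rf <- gaussian_rf(params$x, params$y, params$sigma, stim$grid)
  as.vector(crossprod(stim$apertures, rf))
}

# cumulative kernels for the compiled conv
cum_kernel <- function(h) list(C = cumsum(h), tail = sum(h))

#' Predicted neural time course of a pRF model
#'
#' Applies the forward model of the parameter class to a stimulus sequence and
#' returns the neural-stage prediction at 10 ms resolution.
#'
#' * `spatial_prf`: the linear spatial drive (one channel).
#' * `cst_prf`: three channels (sustained, on-transient, off-transient), each
#'   the rectified, compressed (`relu(.)^n_exp`) output of the drive convolved
#'   with the channel kernel.
#' * `dnst_prf`: one channel, `|r|^n / (sigma_dn^n + (|r| * h2)^n)` where `r`
#'   is the drive convolved with `h1` and `*` is causal convolution with the
#'   exponential-decay filter.
#'
#' Convolutions are causal, zero-padded, and restart at run boundaries.
#'
#' @param stim A `stim_sequence`.
#' @param params A [prf_params] object.
#' @return Matrix (frames x channels) of class `neural_timecourse` with
#'   attributes `dt_ms` and `channels`.
#' @export
predict_neural <- function(stim, params) UseMethod("predict_neural", params)

#' @export
predict_neural.spatial_prf <- function(stim, params) {
  rf <- gaussian_rf(params$x, params$y, params$sigma, stim$grid)
  out <- matrix(spatial_drive(stim, rf), ncol = 1)
  neural_tc(out, "drive")
}

#' @export
predict_neural.cst_prf <- function(stim, params) {
  a <- stim_cpp_args(stim)
  g <- aperture_overlap(stim, params)
  k1 <- cum_kernel(sustained_irf(params$tau, params$kappa_sus, params$m_sus))
  k2 <- cum_kernel(transient_irfs(params$tau, params$kappa_sus, params$m_sus,
                                  params$kappa_inh, params$m_inh)$on)
  out <- cpp_neural_cst(a$run, a$s, a$e, a$ap, g, a$n_runs, a$T_run,
                        k1$C, k1$tail, k2$C, k2$tail, params$n_exp)
  neural_tc(out, c("sustained", "transient_on", "transient_off"))
}

#' @export
predict_neural.dnst_prf <- function(stim, params) {
  a <- stim_cpp_args(stim)
  g <- aperture_overlap(stim, params)
  kk <- dnst_irfs(params$tau1, params$tau2)
  k1 <- cum_kernel(kk$h1)
  out <- cpp_neural_dnst(a$run, a$s, a$e, a$ap, g, a$n_runs, a$T_run,
                         k1$C, k1$tail, kk$lambda2, params$n_dn,
                         params$sigma_dn)
  neural_tc(out, "dnst")
}

neural_tc <- function(m, channels) {
  colnames(m) <- channels
  structure(m, dt_ms = DT_MS, channels = channels,
            class = c("neural_timecourse", class(m)))
}

#' DN-ST neural response for an arbitrary linear drive
#'
#' Exposes the DN-ST nonlinearity on a raw response series (used for
#' sign-invariance and limit checks): `|r|^n / (sigma_dn^n + lowpass(|r|)^n)`.
#'
#' @param r Linear response series at 10 ms.
#' @param tau2,sigma_dn,n_dn DN-ST normalization parameters.
#' @return Series of the same length.
#' @export
dnst_nonlinearity <- function(r, tau2, sigma_dn, n_dn) {
  lambda <- exp(-1 / (tau2 * SAMPLES_PER_SEC))
  a <- abs(r)
  y <- as.numeric(stats::filter((1 - lambda) * a, lambda, method = "recursive"))
  a^n_dn / (sigma_dn^n_dn + y^n_dn)
}
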