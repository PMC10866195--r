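#' Median absolute percentage error
#'
#' For each pair, `100 * |estimate - truth| / |truth|`; the summary statistic
#' is the median across pairs. Pairs with zero ground truth are undefined and
#' excluded from the median (their count is reported in the attribute
#' `n_undefined`). Optionally trims errors beyond the 90th percentile before
#' the median (distribution-display policy; the default headline median is
#' untrimmed since the median is already robust).
#'
#' @param estimates,truths Numeric vectors of equal length.
#' @param trim_q Optional quantile (e.g. 0.9) above which errors are dropped.
#' @return Median percentage error with attributes `errors` (per-pair) and
#'   `n_undefined`.
#' @export
mape <- function(estimates, truths, trim_q = NULL) {
  stopifnot(length(estimates) == length(truths))
  undef <- truths == 0
  err <- 100 * abs(estimates - truths) / abs(truths)
  err[undef] <- NA_real_
  use <- err[!undef & !is.na(err)]
  if (!is.null(trim_q)) use <- use[use <= quantile(use, trim_q)]
  structure(median(use), errors = err, n_undefined = sum(undef))
}

#' Parameter-recovery report
#'
#' Compares solved parameters with the generating ground truth: per-parameter
#' median absolute percentage error and Pearson correlation.
#'
#' @param solved Data frame from [solve_prf()] (must contain the model's
#'   parameter columns and `voxel`).
#' @param gt The [sample_ground_truth()] set that generated the data.
#' @param trim_q Optional MAPE trim quantile (see [mape()]).
#' @return Data frame (class `recovery_report`) with one row per parameter:
#'   `parameter`, `mape`, `pearson_r`, `n_voxels`.
#' @export
recovery_report <- function(solved, gt, trim_q = NULL) {
  kind <- attr(gt, "model_kind")
  nm <- model_param_names(kind)
  idx <- match(solved$voxel, gt$voxel)
  stopifnot(!anyNA(idx))
  ok <- !solved$degenerate & solved$converged
  rows <- lapply(nm, function(p) {
    est <- solved[[p]][ok]
    tru <- gt[[p]][idx][ok]
    data.frame(parameter = p,
               mape = as.numeric(mape(est, tru, trim_q = trim_q)),
               pearson_r = suppressWarnings(cor(est, tru)),
               n_voxels = sum(ok))
  })
  structure(do.call(rbind, rows), model_kind = kind,
            class = c("recovery_report", "data.frame"))
}

#' Temporal integration window of a CST pRF
#'
#' Full width at half maximum of the sustained neural impulse response
#' (gamma kernel) in milliseconds. Scales linearly with `tau` for fixed
#' shape constants.
#'
#' @param tau CST temporal constant(s), in 10 ms samples.
#' @param kappa,m Gamma shape constants.
#' @return FWHM in ms (vectorized over `tau`).
#' @export
temporal_window_fwhm <- function(tau, kappa = 1, m = 9) {
  # FWHM of a gamma density is scale-invariant up to the scale factor:
  # fwhm = kappa * tau * u(m), u from the unit-scale density (memoized).
  u <- gamma_unit_fwhm(m)
  kappa * tau * u * DT_MS
}

#' Average spatiotemporal pRF profile
#'
#' Zero-centers every pRF (x = y = 0), takes the spatial cross-section along
#' one dimension, multiplies it pointwise with the channel's temporal impulse
#' response (space x time outer product), and averages across voxels.
#'
#' @param params_list Data frame of pRF parameters (needs `sigma` and the
#'   temporal parameters of the model kind), e.g. from [solve_prf()].
#' @param model_kind `"cst"` (channels `"sustained"`/`"transient_on"`) or
#'   `"dnst"` (impulse response `h1`).
#' @param channel Channel to profile (CST only).
#' @param space_deg Cross-section coordinates (deg).
#' @param t_max_ms Temporal extent of the profile (ms).
#' @return List of class `strf_profile`: `profile` (space x time matrix),
#'   `space_deg`, `time_ms`, `n_voxels`.
#' @export
average_strf <- function(params_list, model_kind = c("cst", "dnst"),
                         channel = c("sustained", "transient_on"),
                         space_deg = seq(-6, 6, by = 0.25), t_max_ms = 1000) {
  model_kind <- match.arg(model_kind)
  channel <- match.arg(channel)
  n_t <- ceiling(t_max_ms / DT_MS)
  time_ms <- (seq_len(n_t) - 0.5) * DT_MS
  acc <- matrix(0, length(space_deg), n_t)
  n <- nrow(params_list)
  for (i in seq_len(n)) {
    row <- params_list[i, ]
    spatial <- exp(-space_deg^2 / (2 * row$sigma^2))  # zero-centered
    h <- if (model_kind == "cst") {
      if (channel == "sustained") sustained_irf(row$tau)
      else transient_irfs(row$tau)$on
    } else {
      dnst_irfs(row$tau1, row$tau2)$h1
    }
    h <- c(h, numeric(max(0, n_t - length(h))))[seq_len(n_t)]
    acc <- acc + outer(spatial, h)
  }
  structure(list(profile = acc / n, space_deg = space_deg, time_ms = time_ms,
                 n_voxels = n, channel = channel), class = "strf_profile")
}

#' Paired permutation test for model comparison
#'
#' Fisher sign-flip permutation test on paired differences (e.g. per-
#' participant mean cross-validated R-squared of two models): the two-sided
#' p-value is the fraction of sign assignments whose mean absolute difference
#' is at least the observed one. Enumerates all `2^n` assignments when
#' feasible, otherwise Monte Carlo with `n_iter` draws. When matrices of
#' paired scores are supplied (columns = areas), p-values are
#' Benjamini-Hochberg corrected across columns.
#'
#' @param r2_a,r2_b Paired score vectors (or matrices with matching columns).
#' @param n_iter Permutation iterations (default 50000).
#' @param seed RNG seed for Monte Carlo sampling.
#' @return Single p-value, or a vector of FDR-corrected p-values for matrix
#'   input.
#' @export
compare_models_permutation <- function(r2_a, r2_b, n_iter = 50000L,
                                       seed = 1L) {
  if (is.matrix(r2_a)) {
    stopifnot(identical(dim(r2_a), dim(r2_b)))
    p <- vapply(seq_len(ncol(r2_a)), function(j) {
      compare_models_permutation(r2_a[, j], r2_b[, j], n_iter, seed + j)
    }, 0)
    return(p.adjust(p, method = "BH"))
  }
  stopifnot(length(r2_a) == length(r2_b))
  d <- r2_a - r2_b
  n <- length(d)
  obs <- abs(mean(d))
  if (n <= 20 && 2^n <= n_iter) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    stat <- abs(as.vector(signs %*% d)) / n
    mean(stat >= obs - 1e-15)
  } else {
    withr::with_seed(seed, {
      stat <- vapply(seq_len(n_iter), function(i) {
        abs(mean(d * sample(c(-1, 1), n, replace = TRUE)))
      }, 0)
      (sum(stat >= obs - 1e-15) + 1) / (n_iter + 1)
    })
  }
}

#' Bin pRF summaries by eccentricity
#'
#' Assigns each voxel to a fixed-width eccentricity bin (from its `(x, y)`
#' center) and reports the per-bin median of a chosen value column with
#' counts. Empty bins are reported with count 0 and no value.
#'
#' @param params_list Data frame with `x`, `y` and the value column.
#' @param value Column to summarize (e.g. `"sigma"` or a temporal-window
#'   column).
#' @param width_deg Bin width (default 2 deg).
#' @param max_ecc Upper edge of the last bin.
#' @return Data frame: `ecc_lo`, `ecc_hi`, `n`, `median`.
#' @export
bin_by_eccentricity <- function(params_list, value = "sigma", width_deg = 2,
                                max_ecc = 12) {
  ecc <- sqrt(params_list$x^2 + params_list$y^2)
  edges <- seq(0, max_ecc, by = width_deg)
  idx <- findInterval(ecc, edges, rightmost.closed = FALSE)
  idx[idx > length(edges) - 1] <- NA  # beyond the last bin
  out <- lapply(seq_len(length(edges) - 1), function(b) {
    vals <- params_list[[value]][which(idx == b)]
    data.frame(ecc_lo = edges[b], ecc_hi = edges[b + 1], n = length(vals),
               median = if (length(vals)) median(vals) else NA_real_)
  })
  do.call(rbind, out)
}
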