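#' Grid-search specification
#'
#' The coarse stage enumerates pRF centers on a 0.4 deg lattice covering the
#' 24 deg stimulus extent (corner coordinates 0..24 deg, i.e. -12..12 deg
#' around fixation), 96 log-linearly spaced sizes in \[0.1, 12\] deg, and for
#' the CST model compressive exponents {0.25, 0.5, 0.75, 1}. Temporal
#' parameters are held at fixed defaults during the grid stage (CST tau =
#' 4.93 samples; DN-ST tau1 = 0.05 s, tau2 = 0.1 s, n_dn = 2, sigma_dn = 0.1).
#'
#' @param xy_step Center lattice step (deg).
#' @param sigma_range,sigma_steps Size range (deg) and number of log-linear
#'   steps.
#' @param cst_n CST exponent grid.
#' @param cst_tau_default,dnst_defaults Fixed temporal defaults for the grid
#'   stage.
#' @param cst_tau_grid Coarse tau values scanned by the CST grid stage (the
#'   printed default is the first; a tau-blind grid can displace the spatial
#'   estimate beyond the fine stage's search box for sluggish pRFs).
#' @param dnst_temporal_grid Data frame of coarse DN-ST temporal
#'   combinations re-scored at the best spatial candidates (default: a small
#'   factorial over the search bounds).
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(xy_step = 0.4, sigma_range = c(0.1, 12),
                      sigma_steps = 96L, cst_n = c(0.25, 0.5, 0.75, 1),
                      cst_tau_default = 4.93,
                      cst_tau_grid = c(4.93, 20, 45, 90),
                      dnst_defaults = list(tau1 = 0.05, tau2 = 0.1,
                                           n_dn = 2, sigma_dn = 0.1),
                      dnst_temporal_grid = NULL) {
  if (is.null(dnst_temporal_grid)) {
    dnst_temporal_grid <- expand.grid(tau1 = c(0.05, 0.3),
                                      tau2 = c(0.1, 0.5),
                                      sigma_dn = c(0.03, 0.1, 0.35),
                                      n_dn = c(2, 4))
  }
  structure(list(xy_step = xy_step, sigma_range = sigma_range,
                 sigma_steps = as.integer(sigma_steps), cst_n = cst_n,
                 cst_tau_default = cst_tau_default,
                 cst_tau_grid = cst_tau_grid,
                 dnst_defaults = dnst_defaults,
                 dnst_temporal_grid = dnst_temporal_grid),
            class = "grid_spec")
}

#' Fine-search specification
#'
#' Bounded least-squares refinement (Levenberg-Marquardt with box bounds,
#' gains profiled out by OLS) started from the grid estimate with
#' `n_restarts` initializations: the first uses the grid-stage temporal
#' defaults, the others draw temporal parameters uniformly within the search
#' bounds. Spatial bounds are +/- `spatial_margin` deg around the grid
#' estimate; temporal bounds are the model's solver bounds (CST tau in
#' \[4, 100\] samples, n in \[0.1, 1\]; DN-ST tau1, tau2 in \[0.01, 1\] s,
#' sigma_dn in \[0.01, 0.5\], n_dn in \[1, 6\]).
#'
#' @param n_restarts Number of restarts (best non-centered R-squared wins).
#' @param spatial_margin Half-width of the spatial box (deg).
#' @param maxiter LM iteration caps, recycled across restarts.
#' @param sigma_floor Lower clamp for sigma (deg).
#' @param skip_restart_r2 Skip remaining restarts once a fit exceeds this
#'   R-squared (restarts exist to escape local minima; a numerically perfect
#'   fit leaves nothing to escape).
#' @param ftol,ptol Levenberg-Marquardt convergence tolerances (relative
#'   sum-of-squares and parameter change).
#' @return An object of class `fine_spec`.
#' @export
fine_spec <- function(n_restarts = 3L, spatial_margin = 5,
                      maxiter = c(30L, 6L, 6L), sigma_floor = 0.1,
                      skip_restart_r2 = 1 - 1e-7, ftol = 1e-7, ptol = 1e-7) {
  structure(list(n_restarts = as.integer(n_restarts),
                 spatial_margin = spatial_margin,
                 maxiter = rep_len(as.integer(maxiter), n_restarts),
                 sigma_floor = sigma_floor,
                 skip_restart_r2 = skip_restart_r2, ftol = ftol, ptol = ptol,
                 polish_iter = 8L),
            class = "fine_spec")
}

model_param_names <- function(kind) {
  switch(kind,
    spatial = c("x", "y", "sigma"),
    cst = c("x", "y", "sigma", "tau", "n_exp"),
    dnst = c("x", "y", "sigma", "tau1", "tau2", "sigma_dn", "n_dn"))
}

# ---- cached per-design machinery ------------------------------------------

.solver_cache <- new.env(parent = emptyenv())

#' Clear the solver's per-design cache
#' @export
clear_solver_cache <- function() {
  rm(list = ls(.solver_cache), envir = .solver_cache)
  invisible(NULL)
}

stim_key <- function(stim) {
  # content-based: two stimuli with the same geometry but different
  # schedules must never share cached bases
  iv <- stim$intervals
  paste(stim$design_label, stim$n_runs, stim$frames_per_run,
        ncol(stim$apertures), nrow(iv),
        sum(iv$start0 * iv$ap), sum(iv$end0 * seq_len(nrow(iv))),
        sum(stim$frame_ap != 0L), sum(as.double(stim$frame_ap)),
        sep = "|")
}

hrf_key <- function(hrf_par) paste(unlist(hrf_par), collapse = "|")

grid_key <- function(grid) {
  paste(grid$xy_step, paste(grid$sigma_range, collapse = ","),
        grid$sigma_steps, paste(grid$cst_n, collapse = ","),
        paste(grid$cst_tau_grid, collapse = ","), sep = "|")
}

# linear BOLD basis: one regressor per aperture, full HRF projection of the
# aperture's on/off step series, demeaned per run. Built with the cumulative
# binned-HRF lookup (exact for step inputs).
linear_basis <- function(stim, gbar) {
  iv <- stim$intervals
  spf <- SAMPLES_PER_SEC
  n_sec <- stim$frames_per_run / spf
  K <- ncol(stim$apertures)
  Hc <- c(0, cumsum(gbar))
  lookup <- function(d) Hc[pmin(pmax(d + 1, 1), length(Hc))]
  base <- seq_len(n_sec) * spf - 1
  B <- matrix(0, stim$n_runs * n_sec, K)
  for (i in seq_len(nrow(iv))) {
    rows <- (iv$run[i] - 1) * n_sec + seq_len(n_sec)
    B[rows, iv$ap[i]] <- B[rows, iv$ap[i]] +
      lookup(base - iv$start0[i]) - lookup(base - iv$end0[i])
  }
  demean_runs_mat(B, stim$n_runs)
}

demean_runs_mat <- function(m, n_runs) {
  n_sec <- nrow(m) / n_runs
  for (r in seq_len(n_runs)) {
    rows <- (r - 1) * n_sec + seq_len(n_sec)
    m[rows, ] <- sweep(m[rows, , drop = FALSE], 2,
                       colMeans(m[rows, , drop = FALSE]))
  }
  m
}

# squared distances between grid centers and pixel centers (shared by sigma
# chunks); grid centers live on the xy lattice of the grid spec.
grid_geometry <- function(stim, grid) {
  r <- stim$geometry$field_radius_deg
  centers <- seq(-r, r, by = grid$xy_step)
  px <- stim$grid
  pos_x <- rep(centers, times = length(centers))
  pos_y <- rep(centers, each = length(centers))
  D2 <- outer(pos_x, px$X, `-`)^2 + outer(pos_y, px$Y, `-`)^2
  sigma <- exp(seq(log(grid$sigma_range[1]), log(grid$sigma_range[2]),
                   length.out = grid$sigma_steps))
  list(pos_x = pos_x, pos_y = pos_y, sigma = sigma, D2 = D2)
}

# G: aperture overlaps of every (position, sigma) grid point; rows ordered
# position-fastest within sigma blocks.
build_G <- function(gg, A) {
  n_pos <- length(gg$pos_x)
  K <- ncol(A)
  G <- matrix(0, n_pos * length(gg$sigma), K)
  for (j in seq_along(gg$sigma)) {
    RF <- exp(gg$D2 / (-2 * gg$sigma[j]^2))
    G[(j - 1) * n_pos + seq_len(n_pos), ] <- RF %*% A
  }
  G
}

# DN-ST coarse probes: the normalization regime (saturated vs linear, fast
# vs sluggish) changes the response shape so much that spatial localization
# must be scored jointly with it.
dnst_probe_pars <- function(grid, r_field) {
  dn <- grid$dnst_defaults
  probes <- list(
    c(tau1 = dn$tau1, tau2 = dn$tau2, sigma_dn = dn$sigma_dn,
      n_dn = dn$n_dn),
    c(tau1 = 0.3, tau2 = 0.5, sigma_dn = 0.03, n_dn = 4),
    c(tau1 = 1.0, tau2 = 0.3, sigma_dn = 0.07, n_dn = 4),
    c(tau1 = 0.1, tau2 = 0.3, sigma_dn = 0.35, n_dn = 2))
  net_xy <- expand.grid(x = seq(-0.75 * r_field, 0.75 * r_field,
                                length.out = 5),
                        y = seq(-0.75 * r_field, 0.75 * r_field,
                                length.out = 5))
  net_pars <- list()
  for (sg in c(0.7, 1.8)) {
    for (i in seq_len(nrow(net_xy))) {
      for (pr in probes) {
        net_pars[[length(net_pars) + 1]] <-
          c(x = net_xy$x[i], y = net_xy$y[i], sigma = sg, pr)
      }
    }
  }
  list(probes = probes, net_pars = net_pars)
}

design_basis <- function(stim, hrf_par, grid) {
  key <- paste(stim_key(stim), hrf_key(hrf_par), grid_key(grid), sep = "##")
  hit <- .solver_cache[[key]]
  if (!is.null(hit)) return(hit)
  hrf <- two_gamma_hrf(hrf_par)
  gbar <- hrf_bin_kernel(hrf)
  gg <- grid_geometry(stim, grid)
  env <- new.env(parent = emptyenv())
  env$gbar <- gbar
  env$gg <- gg
  env$B <- linear_basis(stim, gbar)
  env$M_lin <- crossprod(env$B)
  env$get_G <- local({
    built <- NULL
    function() {
      if (is.null(built)) built <<- build_G(gg, stim$apertures)
      built
    }
  })
  env$get_lin_denom <- local({
    val <- NULL
    function() {
      if (is.null(val)) {
        G <- env$get_G()
        val <<- rowSums((G %*% env$M_lin) * G)
      }
      val
    }
  })
  env$get_cst_surrogate <- local({
    val <- NULL
    function() {
      if (is.null(val)) val <<- build_cst_surrogate(stim, gbar, grid)
      val
    }
  })
  env$get_dnst_net <- local({
    val <- NULL
    function() {
      if (is.null(val)) {
        pp <- dnst_probe_pars(grid, stim$geometry$field_radius_deg)
        a <- stim_cpp_args(stim)
        P <- vapply(pp$net_pars, function(par) {
          as.vector(exact_predictors("dnst", par, stim, a, gbar))
        }, numeric(stim$n_runs * stim$frames_per_run / SAMPLES_PER_SEC))
        val <<- list(pars = pp$net_pars, probes = pp$probes, P = P,
                     ss = pmax(colSums(P^2), 1e-300))
      }
      val
    }
  })
  env$get_cst_denoms <- local({
    val <- NULL
    function() {
      if (is.null(val)) {
        G <- env$get_G()
        sur <- env$get_cst_surrogate()
        val <<- vector("list", length(sur))
        for (nexp in unique(vapply(sur, `[[`, 0, "n"))) {
          idx <- which(vapply(sur, `[[`, 0, "n") == nexp)
          Gn <- if (nexp == 1) G else G^nexp
          # one quadratic form per (tau, n) combo; kept combo-by-combo to
          # bound peak memory (each product is n_grid x K)
          for (j in idx) {
            s <- sur[[j]]
            Sss <- rowSums((Gn %*% s$Mss) * Gn)
            Stt <- rowSums((Gn %*% s$Mtt) * Gn)
            Sst <- rowSums((Gn %*% s$Mst) * Gn)
            val[[j]] <<- list(Sss = Sss, Stt = Stt, Sst = Sst,
                              det = pmax(Sss * Stt - Sst^2, 1e-300))
          }
          rm(Gn)
        }
      }
      val
    }
  })
  .solver_cache[[key]] <- env
  env
}

# slot-factorized CST surrogate: BOLD responses to each within-slot temporal
# profile under each coarse tau, aggregated per aperture, so that the grid
# prediction is linear in the compressed aperture overlaps g^n. Exact when
# channel responses do not straddle slot boundaries; used only to rank grid
# candidates before exact re-scoring. Returns one entry per (tau, n) combo.
build_cst_surrogate <- function(stim, gbar, grid) {
  spf <- SAMPLES_PER_SEC
  n_sec_run <- stim$frames_per_run / spf
  K <- ncol(stim$apertures)
  sl <- stim$slots
  out <- list()
  for (tau in grid$cst_tau_grid) {
    h1 <- sustained_irf(tau)
    h2 <- transient_irfs(tau)$on
    segs <- lapply(stim$profiles, function(prof) {
      pad <- max(length(h1), length(h2))
      x <- c(prof, numeric(pad))
      list(r1 = apply_irf(x, h1), r2 = apply_irf(x, h2))
    })
    for (nexp in grid$cst_n) {
      Qs <- matrix(0, K, stim$n_runs * n_sec_run)
      Qt <- matrix(0, K, stim$n_runs * n_sec_run)
      bolds <- lapply(segs, function(sg) {
        ps <- pmax(sg$r1, 0)^nexp
        pt <- abs(sg$r2)^nexp
        len <- ceiling((length(ps) + length(gbar)) / spf) * spf
        list(s = cpp_bold_from_neural(c(ps, numeric(len - length(ps))), gbar,
                                      1L, len, FALSE),
             t = cpp_bold_from_neural(c(pt, numeric(len - length(pt))), gbar,
                                      1L, len, FALSE))
      })
      for (i in seq_len(nrow(sl))) {
        b <- bolds[[sl$prof_id[i]]]
        col0 <- (sl$run[i] - 1) * n_sec_run + sl$t0_frame[i] / spf
        nmax <- min(length(b$s), sl$run[i] * n_sec_run - col0)
        cols <- col0 + seq_len(nmax)
        Qs[sl$ap[i], cols] <- Qs[sl$ap[i], cols] + b$s[seq_len(nmax)]
        Qt[sl$ap[i], cols] <- Qt[sl$ap[i], cols] + b$t[seq_len(nmax)]
      }
      Qs <- t(demean_runs_mat(t(Qs), stim$n_runs))
      Qt <- t(demean_runs_mat(t(Qt), stim$n_runs))
      out[[length(out) + 1]] <-
        list(tau = tau, n = nexp, Qs = Qs, Qt = Qt,
             Mss = tcrossprod(Qs), Mtt = tcrossprod(Qt), Mst = Qs %*% t(Qt))
    }
  }
  out
}

# ---- scoring helpers -------------------------------------------------------

#' Variance explained (non-centered)
#'
#' `R^2 = 1 - sum((pred - data)^2) / sum(data^2)`: residual sum of squares
#' over the raw (not mean-centered) sum of squares of the data.
#'
#' @param pred,data Equal-length numeric vectors.
#' @return R-squared (can be negative); `NA` with attribute `degenerate` if
#'   the data are all zero.
#' @export
variance_explained <- function(pred, data) {
  stopifnot(length(pred) == length(data), length(data) >= 1)
  dd <- sum(data^2)
  if (dd == 0) return(structure(NA_real_, degenerate = TRUE))
  1 - sum((pred - data)^2) / dd
}

#' Channel gain estimation by ordinary least squares
#'
#' Unconstrained OLS of the voxel time course on the HRF-convolved channel
#' predictors (for the CST model: sustained and summed on+off transient).
#' Falls back to a small ridge penalty with a warning when the predictors are
#' collinear.
#'
#' @param predictors Matrix (time x channels) of BOLD-stage predictors.
#' @param bold Voxel time course.
#' @return Numeric beta vector, one per predictor column.
#' @export
estimate_betas <- function(predictors, bold) {
  X <- as.matrix(predictors)
  stopifnot(nrow(X) == length(bold))
  if (all(bold == 0)) return(numeric(ncol(X)))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    warning("collinear predictors; using ridge fallback")
    XtX <- crossprod(X)
    lam <- 1e-8 * max(diag(XtX), 1e-300)
    return(as.vector(solve(XtX + diag(lam, ncol(X)), crossprod(X, bold))))
  }
  as.vector(qr.coef(qx, bold))
}

# OLS + non-centered R-squared score for a small predictor matrix;
# tolerant of degenerate
# (all-zero) predictions far from the stimulus.
score_fit <- function(P, d, dd = sum(d^2)) {
  cp <- crossprod(P)
  if (max(diag(cp)) < 1e-30) {
    return(list(beta = numeric(ncol(P)), r2 = 1 - sum(d^2) / dd,
                res = d))
  }
  beta <- tryCatch(as.vector(solve(cp, crossprod(P, d))),
                   error = function(e) {
                     as.vector(solve(cp + diag(1e-10 * max(diag(cp)),
                                               ncol(P)),
                                     crossprod(P, d)))
                   })
  res <- d - as.vector(P %*% beta)
  list(beta = beta, r2 = 1 - sum(res^2) / dd, res = res)
}

# exact BOLD-stage predictors for one parameter set (regressor matrix)
exact_predictors <- function(kind, par, stim, a, gbar, grid = NULL) {
  g <- as.vector(crossprod(stim$apertures,
                           exp(-((stim$grid$X - par[["x"]])^2 +
                                   (stim$grid$Y - par[["y"]])^2) /
                                 (2 * par[["sigma"]]^2))))
  if (kind == "spatial") {
    drv <- cpp_drive(a$run, a$s, a$e, a$ap, g, a$n_runs, a$T_run)
    matrix(cpp_bold_from_neural(drv, gbar, a$n_runs, a$T_run, TRUE), ncol = 1)
  } else if (kind == "cst") {
    k1 <- cum_kernel(sustained_irf(par[["tau"]]))
    k2 <- cum_kernel(transient_irfs(par[["tau"]])$on)
    cpp_bold_cst(a$run, a$s, a$e, a$ap, g, a$n_runs, a$T_run,
                 k1$C, k1$tail, k2$C, k2$tail, par[["n_exp"]], gbar, TRUE)
  } else {
    kk <- dnst_irfs(par[["tau1"]], par[["tau2"]])
    k1 <- cum_kernel(kk$h1)
    cpp_bold_dnst(a$run, a$s, a$e, a$ap, g, a$n_runs, a$T_run,
                  k1$C, k1$tail, kk$lambda2, par[["n_dn"]], par[["sigma_dn"]],
                  gbar, TRUE)
  }
}

# ---- grid search -----------------------------------------------------------

#' Coarse grid search
#'
#' Scores the full (x, y, sigma\[, n\]) grid for every voxel with gains
#' solved linearly per grid point, and returns the best grid point per voxel.
#' The Spatial model is scored exactly in closed form; for CST and DN-ST the
#' grid is ranked with fast factorized/linearized surrogates and the top
#' candidates are re-scored with the exact forward model at the grid-stage
#' temporal defaults (ties broken toward smaller sigma, then smaller
#' eccentricity).
#'
#' @param bold Matrix (1 s samples x voxels) or vector for one voxel.
#' @param stim A `stim_sequence`.
#' @param model_kind `"spatial"`, `"cst"`, or `"dnst"`.
#' @param grid A [grid_spec()].
#' @param hrf_par [hrf_params()] (default Vistasoft HRF).
#' @param n_rescore Exact re-scorings per voxel for the nonlinear models.
#' @return Data frame of coarse estimates, one row per voxel, with `r2` and
#'   `degenerate` flag.
#' @export
grid_search <- function(bold, stim, model_kind = c("spatial", "cst", "dnst"),
                        grid = grid_spec(), hrf_par = hrf_default(),
                        n_rescore = 16L) {
  model_kind <- match.arg(model_kind)
  D <- as.matrix(bold)
  basis <- design_basis(stim, hrf_par, grid)
  gg <- basis$gg
  a <- stim_cpp_args(stim)
  dd <- colSums(D^2)
  degen <- dd == 0
  n_pos <- length(gg$pos_x)
  ecc_pos <- sqrt(gg$pos_x^2 + gg$pos_y^2)

  pick_best <- function(score, j_allowed = NULL) {
    # tie-break: max score, then smallest sigma, then smallest eccentricity
    best <- which.max(score)
    ties <- which(score >= score[best] - 1e-12 * abs(score[best]))
    if (length(ties) > 1) {
      sig_idx <- (ties - 1) %/% n_pos + 1
      pos_idx <- (ties - 1) %% n_pos + 1
      o <- order(gg$sigma[sig_idx], ecc_pos[pos_idx])
      best <- ties[o[1]]
    }
    best
  }
  gp_par <- function(idx) {
    sig_idx <- (idx - 1) %/% n_pos + 1
    pos_idx <- (idx - 1) %% n_pos + 1
    c(x = gg$pos_x[pos_idx], y = gg$pos_y[pos_idx],
      sigma = gg$sigma[sig_idx])
  }

  V <- ncol(D)
  out <- vector("list", V)

  # per-voxel top grid candidates from the slot-factorized CST surrogate
  # (used for CST, and to localize DN-ST whose transient-like responses are
  # poorly served by a purely linear surrogate)
  surrogate_candidates <- function(per_combo) {
    G <- basis$get_G()
    sur <- basis$get_cst_surrogate()
    denoms <- basis$get_cst_denoms()
    cand <- lapply(seq_len(V), function(v) NULL)
    n_vals <- vapply(sur, `[[`, 0, "n")
    for (nexp in unique(n_vals)) {
      Gn <- if (nexp == 1) G else G^nexp
      for (si in which(n_vals == nexp)) {
        s <- sur[[si]]
        dn <- denoms[[si]]
        as_m <- Gn %*% (s$Qs %*% D)
        at_m <- Gn %*% (s$Qt %*% D)
        for (v in seq_len(V)) {
          if (degen[v]) next
          asv <- as_m[, v]; atv <- at_m[, v]
          b1 <- (dn$Stt * asv - dn$Sst * atv) / dn$det
          b2 <- (dn$Sss * atv - dn$Sst * asv) / dn$det
          expl <- b1 * asv + b2 * atv
          top <- head(order(expl, decreasing = TRUE), per_combo)
          cand[[v]] <- rbind(cand[[v]],
                             cbind(idx = top, tau = s$tau, n = nexp,
                                   score = expl[top]))
        }
      }
    }
    cand
  }

  if (model_kind == "spatial") {
    G <- basis$get_G()
    denom <- basis$get_lin_denom()
    c36 <- crossprod(basis$B, D)
    for (v in seq_len(V)) {
      if (degen[v]) { out[[v]] <- degen_row("spatial"); next }
      numer <- as.vector(G %*% c36[, v])
      score <- numer^2 / pmax(denom, 1e-300)
      best <- pick_best(score)
      par <- gp_par(best)
      out[[v]] <- data.frame(t(par), beta = numer[best] / denom[best],
                             r2 = score[best] / dd[v], degenerate = FALSE)
    }
  } else if (model_kind == "cst") {
    sur <- basis$get_cst_surrogate()
    cand <- surrogate_candidates(max(1L, ceiling(n_rescore / length(sur))))
    for (v in seq_len(V)) {
      if (degen[v]) { out[[v]] <- degen_row("cst"); next }
      cc <- cand[[v]]
      cc <- cc[order(cc[, "score"], decreasing = TRUE), , drop = FALSE]
      cc <- head(cc, max(n_rescore, length(sur)))
      best_fit <- NULL
      for (i in seq_len(nrow(cc))) {
        par <- c(gp_par(cc[i, "idx"]), tau = unname(cc[i, "tau"]),
                 n_exp = unname(cc[i, "n"]))
        P <- exact_predictors("cst", par, stim, a, basis$gbar)
        f <- score_fit(P, D[, v], dd[v])
        if (is.null(best_fit) || f$r2 > best_fit$r2) {
          best_fit <- c(f, list(par = par))
        }
      }
      par <- best_fit$par
      out[[v]] <- data.frame(x = par[["x"]], y = par[["y"]],
                             sigma = par[["sigma"]], tau = par[["tau"]],
                             n_exp = par[["n_exp"]],
                             beta_sus = best_fit$beta[1],
                             beta_tran = best_fit$beta[2],
                             r2 = best_fit$r2, degenerate = FALSE)
    }
  } else {  # dnst: linear localization + exact re-scoring
    G <- basis$get_G()
    denom <- basis$get_lin_denom()
    c36 <- crossprod(basis$B, D)
    sur_cand <- surrogate_candidates(1L)
    netinfo <- basis$get_dnst_net()
    probes <- netinfo$probes
    # batched phase-1 net: the (position x sigma x probe) scan predictors
    # are voxel-independent, so all voxels score them in one product
    numer_net <- crossprod(netinfo$P, D)
    for (v in seq_len(V)) {
      if (degen[v]) { out[[v]] <- degen_row("dnst"); next }
      numer <- as.vector(G %*% c36[, v])
      score <- numer^2 / pmax(denom, 1e-300)
      cands <- lapply(head(order(score, decreasing = TRUE), 6), gp_par)
      sc <- sur_cand[[v]]
      sc <- sc[order(sc[, "score"], decreasing = TRUE), , drop = FALSE]
      cands <- unique(c(cands, lapply(head(sc[, "idx"], 6), gp_par)))
      score_par <- function(par) {
        f <- score_fit(exact_predictors("dnst", par, stim, a, basis$gbar),
                       D[, v], dd[v])
        c(f, list(par = par))
      }
      # phase 1: joint spatial x temporal-probe scan (net batched above,
      # per-voxel linear/surrogate candidates scored exactly here)
      net_r2 <- numer_net[, v]^2 / netinfo$ss / dd[v]
      scored <- lapply(head(order(net_r2, decreasing = TRUE), 8),
                       function(i) {
                         list(r2 = net_r2[i],
                              beta = numer_net[i, v] / netinfo$ss[i],
                              par = netinfo$pars[[i]])
                       })
      best_fit <- scored[[1]]
      for (par0 in cands) {
        for (pr in probes) {
          f <- score_par(c(par0, pr))
          scored[[length(scored) + 1]] <- f
          if (f$r2 > best_fit$r2) best_fit <- f
        }
      }
      # phase 2: full coarse temporal grid at the best spatial candidate
      ord <- order(vapply(scored, `[[`, 0, "r2"), decreasing = TRUE)
      keep <- unique(lapply(scored[head(ord, 8)],
                            function(s) s$par[c("x", "y", "sigma")]))[1]
      tg <- grid$dnst_temporal_grid
      for (par0 in keep) {
        for (i in seq_len(nrow(tg))) {
          f <- score_par(c(par0, tau1 = tg$tau1[i], tau2 = tg$tau2[i],
                           sigma_dn = tg$sigma_dn[i], n_dn = tg$n_dn[i]))
          if (f$r2 > best_fit$r2) best_fit <- f
        }
      }
      # phase 3: local spatial refinement at the winning temporal values
      base <- best_fit$par
      for (dx in c(-1.5, 0, 1.5)) for (dy in c(-1.5, 0, 1.5)) {
        for (sm in c(0.5, 1, 2)) {
          if (dx == 0 && dy == 0 && sm == 1) next
          par <- base
          par[["x"]] <- base[["x"]] + dx
          par[["y"]] <- base[["y"]] + dy
          par[["sigma"]] <- base[["sigma"]] * sm
          f <- score_par(par)
          if (f$r2 > best_fit$r2) best_fit <- f
        }
      }
      par <- best_fit$par
      out[[v]] <- data.frame(x = par[["x"]], y = par[["y"]],
                             sigma = par[["sigma"]], tau1 = par[["tau1"]],
                             tau2 = par[["tau2"]],
                             sigma_dn = par[["sigma_dn"]],
                             n_dn = par[["n_dn"]], beta = best_fit$beta[1],
                             r2 = best_fit$r2, degenerate = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res$voxel <- seq_len(V)
  res
}

degen_row <- function(kind) {
  nm <- model_param_names(kind)
  row <- as.data.frame(as.list(setNames(rep(NA_real_, length(nm)), nm)))
  if (kind == "cst") { row$beta_sus <- NA_real_; row$beta_tran <- NA_real_ }
  else row$beta <- NA_real_
  row$r2 <- NA_real_
  row$degenerate <- TRUE
  row
}

#' @importFrom stats setNames
#' @importFrom utils head
NULL

# ---- fine search -----------------------------------------------------------

#' Fine search from a coarse estimate
#'
#' Bounded Levenberg-Marquardt refinement of all model parameters
#' simultaneously, with channel gains profiled out by OLS at every objective
#' evaluation and the best of `fine$n_restarts` restarts (by non-centered
#' R-squared) returned.
#'
#' @param bold Voxel time course (1 s samples).
#' @param stim A `stim_sequence`.
#' @param model_kind Model to fit.
#' @param coarse One-row data frame from [grid_search()] (or a named list of
#'   starting parameters).
#' @param fine A [fine_spec()].
#' @param grid A [grid_spec()] (supplies grid-stage temporal defaults for the
#'   first restart).
#' @param hrf_par [hrf_params()].
#' @param seed Seed for the randomized restarts.
#' @return List of class `solve_result`: `params` (named vector), `betas`,
#'   `r2`, `converged`, `flags`, `restarts` (per-restart diagnostics).
#' @export
fine_search <- function(bold, stim, model_kind = c("spatial", "cst", "dnst"),
                        coarse, fine = fine_spec(), grid = grid_spec(),
                        hrf_par = hrf_default(), seed = 1L) {
  model_kind <- match.arg(model_kind)
  d <- as.vector(bold)
  dd <- sum(d^2)
  if (dd == 0) {
    return(structure(list(params = NULL, betas = NULL, r2 = NA_real_,
                          converged = FALSE,
                          flags = c(degenerate = TRUE), restarts = list()),
                     class = "solve_result"))
  }
  a <- stim_cpp_args(stim)
  hrf <- two_gamma_hrf(hrf_par)
  gbar <- hrf_bin_kernel(hrf)
  m <- fine$spatial_margin
  lower <- c(x = coarse$x - m, y = coarse$y - m,
             sigma = max(fine$sigma_floor, coarse$sigma - m))
  upper <- c(x = coarse$x + m, y = coarse$y + m, sigma = coarse$sigma + m)
  if (model_kind == "cst") {
    lower <- c(lower, tau = CST_BOUNDS$tau[1], n_exp = CST_BOUNDS$n_exp[1])
    upper <- c(upper, tau = CST_BOUNDS$tau[2], n_exp = CST_BOUNDS$n_exp[2])
  } else if (model_kind == "dnst") {
    lower <- c(lower, tau1 = DNST_BOUNDS$tau1[1], tau2 = DNST_BOUNDS$tau2[1],
               sigma_dn = DNST_BOUNDS$sigma_dn[1], n_dn = DNST_BOUNDS$n_dn[1])
    upper <- c(upper, tau1 = DNST_BOUNDS$tau1[2], tau2 = DNST_BOUNDS$tau2[2],
               sigma_dn = DNST_BOUNDS$sigma_dn[2], n_dn = DNST_BOUNDS$n_dn[2])
  }
  nm <- model_param_names(model_kind)
  spatial0 <- c(x = coarse$x, y = coarse$y, sigma = coarse$sigma)
  inits <- lapply(seq_len(fine$n_restarts), function(k) {
    if (k == 1) {
      temporal <- switch(model_kind,
        spatial = NULL,
        cst = c(tau = if (!is.null(coarse$tau)) coarse$tau else
                  grid$cst_tau_default,
                n_exp = if (!is.null(coarse$n_exp)) coarse$n_exp else 0.5),
        dnst = c(tau1 = if (!is.null(coarse$tau1)) coarse$tau1 else
                   grid$dnst_defaults$tau1,
                 tau2 = if (!is.null(coarse$tau2)) coarse$tau2 else
                   grid$dnst_defaults$tau2,
                 sigma_dn = if (!is.null(coarse$sigma_dn)) coarse$sigma_dn
                   else grid$dnst_defaults$sigma_dn,
                 n_dn = if (!is.null(coarse$n_dn)) coarse$n_dn else
                   grid$dnst_defaults$n_dn))
      c(spatial0, temporal)
    } else {
      withr::with_seed(seed * 1000L + k, {
        temporal <- switch(model_kind,
          spatial = NULL,
          cst = c(tau = runif(1, CST_BOUNDS$tau[1], CST_BOUNDS$tau[2]),
                  n_exp = runif(1, CST_BOUNDS$n_exp[1], CST_BOUNDS$n_exp[2])),
          dnst = c(tau1 = runif(1, DNST_BOUNDS$tau1[1], DNST_BOUNDS$tau1[2]),
                   tau2 = runif(1, DNST_BOUNDS$tau2[1], DNST_BOUNDS$tau2[2]),
                   sigma_dn = runif(1, DNST_BOUNDS$sigma_dn[1],
                                    DNST_BOUNDS$sigma_dn[2]),
                   n_dn = runif(1, DNST_BOUNDS$n_dn[1], DNST_BOUNDS$n_dn[2])))
        c(spatial0, temporal)
      })
    }
  })
  resid_fn <- function(par) {
    par <- setNames(pmin(pmax(par, lower), upper), nm)
    P <- exact_predictors(model_kind, par, stim, a, gbar)
    score_fit(P, d, dd)$res
  }
  restarts <- vector("list", fine$n_restarts)
  best <- NULL
  for (k in seq_len(fine$n_restarts)) {
    if (!is.null(best) && best$r2 >= fine$skip_restart_r2) break
    fit <- tryCatch(
      suppressWarnings(
        minpack.lm::nls.lm(par = inits[[k]], lower = lower, upper = upper,
                           fn = resid_fn,
                           control = minpack.lm::nls.lm.control(
                             maxiter = fine$maxiter[k], ftol = fine$ftol,
                             ptol = fine$ptol))),
      error = function(e) e)
    if (inherits(fit, "error")) {
      restarts[[k]] <- list(ok = FALSE, message = conditionMessage(fit),
                            init = inits[[k]])
      next
    }
    par <- setNames(pmin(pmax(unlist(fit$par), lower), upper), nm)
    sc <- score_fit(exact_predictors(model_kind, par, stim, a, gbar), d, dd)
    restarts[[k]] <- list(ok = TRUE, r2 = sc$r2, par = par,
                          niter = fit$niter, init = inits[[k]],
                          seed = if (k > 1) seed * 1000L + k else NA)
    if (is.null(best) || sc$r2 > best$r2) {
      best <- list(par = par, betas = sc$beta, r2 = sc$r2)
    }
  }
  if (is.null(best)) {
    return(structure(list(params = NULL, betas = NULL, r2 = NA_real_,
                          converged = FALSE,
                          flags = c(failed = TRUE), restarts = restarts),
                     class = "solve_result"))
  }
  # give the winning restart a short extra polish
  if (best$r2 < fine$skip_restart_r2 && fine$polish_iter > 0) {
    fit <- tryCatch(
      suppressWarnings(
        minpack.lm::nls.lm(par = best$par, lower = lower, upper = upper,
                           fn = resid_fn,
                           control = minpack.lm::nls.lm.control(
                             maxiter = fine$polish_iter, ftol = fine$ftol,
                             ptol = fine$ptol))),
      error = function(e) NULL)
    if (!is.null(fit)) {
      par <- setNames(pmin(pmax(unlist(fit$par), lower), upper), nm)
      sc <- score_fit(exact_predictors(model_kind, par, stim, a, gbar), d, dd)
      if (sc$r2 > best$r2) best <- list(par = par, betas = sc$beta,
                                        r2 = sc$r2)
    }
  }
  flags <- c(low_r2 = best$r2 < 0.1)
  if (model_kind == "cst") {
    flags <- c(flags,
               tau_at_bound = best$par[["tau"]] >= CST_BOUNDS$tau[2] - 1e-6)
  }
  structure(list(params = best$par, betas = best$betas, r2 = best$r2,
                 converged = TRUE, flags = flags, restarts = restarts),
            class = "solve_result")
}

#' Solve pRF models for a set of voxels
#'
#' Two-stage coarse-to-fine estimation ([grid_search()] then [fine_search()])
#' for every column of a voxel time-course matrix.
#'
#' @inheritParams grid_search
#' @param fine A [fine_spec()].
#' @param seed Base seed; voxel `v` uses `seed + v` for its restart draws.
#' @param verbose Print progress every 10 voxels?
#' @return Data frame with one row per voxel: parameters, gains, `r2`,
#'   `converged`, and exclusion flags (`low_r2`, and `tau_at_bound` for CST).
#' @export
solve_prf <- function(bold, stim, model_kind = c("spatial", "cst", "dnst"),
                      grid = grid_spec(), fine = fine_spec(),
                      hrf_par = hrf_default(), seed = 1L, verbose = FALSE) {
  model_kind <- match.arg(model_kind)
  D <- as.matrix(bold)
  coarse <- grid_search(D, stim, model_kind, grid, hrf_par)
  rows <- vector("list", ncol(D))
  for (v in seq_len(ncol(D))) {
    if (isTRUE(coarse$degenerate[v])) {
      rows[[v]] <- cbind(degen_row(model_kind),
                         data.frame(converged = FALSE, low_r2 = NA,
                                    tau_at_bound = NA, voxel = v))
      next
    }
    fs <- fine_search(D[, v], stim, model_kind, coarse[v, ], fine, grid,
                      hrf_par, seed = seed + v)
    pr <- as.data.frame(as.list(fs$params))
    if (model_kind == "cst") {
      pr$beta_sus <- fs$betas[1]; pr$beta_tran <- fs$betas[2]
    } else {
      pr$beta <- fs$betas[1]
    }
    pr$r2 <- fs$r2
    pr$degenerate <- FALSE
    pr$converged <- fs$converged
    pr$low_r2 <- unname(fs$flags["low_r2"])
    pr$tau_at_bound <- if (model_kind == "cst") {
      unname(fs$flags["tau_at_bound"])
    } else NA
    pr$voxel <- v
    rows[[v]] <- pr
    if (verbose && v %% 10 == 0) {
      message("solved ", v, "/", ncol(D), " voxels")
    }
  }
  do.call(rbind, rows)
}

#' Threefold cross-validation of model accuracy
#'
#' Splits the runs into three folds; in each fold two thirds of the runs are
#' used to estimate parameters and the non-centered variance explained is
#' evaluated
#' on the held-out third (with the gains estimated on the training runs).
#' Returns the fold-averaged cross-validated R-squared per voxel.
#'
#' @inheritParams solve_prf
#' @param folds Optional list of test-run index vectors (required when the
#'   run count is not divisible by 3).
#' @return List: `cv_r2` (per voxel), `per_fold` (voxels x folds), `folds`.
#' @export
crossvalidate <- function(bold, stim, model_kind = c("spatial", "cst",
                                                     "dnst"),
                          grid = grid_spec(), fine = fine_spec(),
                          hrf_par = hrf_default(), seed = 1L, folds = NULL) {
  model_kind <- match.arg(model_kind)
  D <- as.matrix(bold)
  n_runs <- stim$n_runs
  if (is.null(folds)) {
    if (n_runs %% 3 != 0) {
      stop("run count not divisible by 3; supply an explicit fold spec")
    }
    per <- n_runs / 3
    folds <- lapply(0:2, function(f) f * per + seq_len(per))
  }
  n_sec_run <- stim$frames_per_run / SAMPLES_PER_SEC
  run_rows <- function(runs) {
    unlist(lapply(runs, function(r) (r - 1) * n_sec_run + seq_len(n_sec_run)))
  }
  per_fold <- matrix(NA_real_, ncol(D), length(folds))
  for (f in seq_along(folds)) {
    test_runs <- folds[[f]]
    train_runs <- setdiff(seq_len(n_runs), test_runs)
    stim_tr <- stim_subset_runs(stim, train_runs)
    stim_te <- stim_subset_runs(stim, test_runs)
    fit <- solve_prf(D[run_rows(train_runs), , drop = FALSE], stim_tr,
                     model_kind, grid, fine, hrf_par, seed = seed + 100 * f)
    a_te <- stim_cpp_args(stim_te)
    gbar <- hrf_bin_kernel(two_gamma_hrf(hrf_par))
    for (v in seq_len(ncol(D))) {
      if (isTRUE(fit$degenerate[v])) next
      par <- unlist(fit[v, model_param_names(model_kind)])
      P <- exact_predictors(model_kind, par, stim_te, a_te, gbar)
      betas <- if (model_kind == "cst") {
        c(fit$beta_sus[v], fit$beta_tran[v])
      } else fit$beta[v]
      pred <- as.vector(P %*% betas)
      per_fold[v, f] <- variance_explained(pred,
                                           D[run_rows(test_runs), v])
    }
  }
  list(cv_r2 = rowMeans(per_fold), per_fold = per_fold, folds = folds)
}
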