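test_that("median absolute percentage error handles edge cases", {
  expect_equal(as.numeric(mape(c(1, 2, 3), c(1, 2, 3))), 0)
  expect_equal(as.numeric(mape(1.1, 1.0)), 10)
  expect_equal(as.numeric(mape(c(1, 1.1, 1.2), c(1, 1, 1))), 10)
  m <- mape(c(1, 2), c(1, 0))
  expect_equal(as.numeric(m), 0)
  expect_equal(attr(m, "n_undefined"), 1)
  # trimming drops the largest errors before the median
  est <- c(rep(1.1, 8), 3, 5)
  expect_lt(as.numeric(mape(est, rep(1, 10), trim_q = 0.8)),
            as.numeric(mape(est, rep(1, 10))) + 1e-12)
})

test_that("recovery reports give zero error and unit correlation when exact", {
  gt <- sample_ground_truth("cst", 20, seed = 31)
  solved <- as.data.frame(gt)
  solved$r2 <- 1; solved$degenerate <- FALSE; solved$converged <- TRUE
  rep <- recovery_report(solved, gt)
  expect_equal(rep$parameter, c("x", "y", "sigma", "tau", "n_exp"))
  expect_true(all(rep$mape == 0))
  expect_true(all(rep$pearson_r > 0.999))
  # permuting the voxel pairing destroys the association
  shuf <- solved
  shuf[, c("x", "y", "sigma", "tau", "n_exp")] <-
    withr::with_seed(2, solved[sample(20), c("x", "y", "sigma", "tau",
                                             "n_exp")])
  rep2 <- recovery_report(shuf, gt)
  expect_true(all(abs(rep2$pearson_r) < 0.6))
})

test_that("temporal window FWHM scales linearly with tau", {
  f1 <- temporal_window_fwhm(10)
  expect_gt(f1, 0)
  expect_equal(temporal_window_fwhm(20), 2 * f1)
  expect_equal(temporal_window_fwhm(35) / 35, f1 / 10)
  # matches a direct measurement on the sampled kernel
  h <- sustained_irf(30)
  above <- range(which(h >= max(h) / 2))
  expect_equal(temporal_window_fwhm(30), diff(above) * 10, tolerance = 0.02)
})

test_that("averaged spatiotemporal profiles behave as expected", {
  one <- data.frame(sigma = 1.5, tau = 20)
  p1 <- average_strf(one, "cst", "sustained")
  many <- one[rep(1, 5), ]
  p5 <- average_strf(many, "cst", "sustained")
  expect_equal(p1$profile, p5$profile)          # identical pRFs average to one
  mixed <- data.frame(sigma = c(1, 2.5), tau = c(15, 40))
  pa <- average_strf(mixed, "cst", "sustained")
  pb <- average_strf(mixed[2:1, ], "cst", "sustained")
  expect_equal(pa$profile, pb$profile)          # order invariance
  # wider sigmas widen the spatial half-max of the profile
  wide <- average_strf(data.frame(sigma = rep(2.5, 3), tau = rep(20, 3)),
                       "cst", "sustained")
  narrow <- average_strf(data.frame(sigma = rep(0.8, 3), tau = rep(20, 3)),
                         "cst", "sustained")
  half_width <- function(p) {
    sp <- rowSums(p$profile)
    sum(sp >= max(sp) / 2)
  }
  expect_gt(half_width(wide), half_width(narrow))
})

test_that("sign-flip permutation test matches exhaustive enumeration", {
  a <- c(0.31, 0.28, 0.35, 0.4, 0.22, 0.3, 0.27, 0.33, 0.29, 0.36)
  expect_equal(compare_models_permutation(a, a), 1)  # identical scores
  b <- a - withr::with_seed(5, runif(10, 0.02, 0.1))
  p_enum <- compare_models_permutation(a, b)         # n = 10 -> exhaustive
  d <- a - b
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), 10)))
  stat <- abs(signs %*% d) / 10
  expect_equal(p_enum, mean(stat >= abs(mean(d)) - 1e-15))
  expect_lt(p_enum, 0.01)                            # consistent difference
  # default iteration budget for the Monte Carlo branch
  expect_equal(formals(compare_models_permutation)$n_iter, 50000L)
  # matrix input: BH-corrected p-values per column
  A <- cbind(a, a); B <- cbind(b, a)
  p2 <- compare_models_permutation(A, B)
  expect_length(p2, 2)
  expect_lt(p2[1], 0.05)
  expect_equal(p2[2], 1)
})

test_that("eccentricity binning uses Pythagoras and reports empty bins", {
  df <- data.frame(x = c(3, 0.5, -6), y = c(4, 0.5, 0),
                   sigma = c(1, 2, 3))
  out <- bin_by_eccentricity(df, "sigma", width_deg = 2)
  expect_equal(out$n[out$ecc_lo == 4], 1)       # ecc 5 -> bin [4, 6)
  expect_equal(out$median[out$ecc_lo == 4], 1)
  expect_equal(out$n[out$ecc_lo == 0], 1)
  expect_equal(out$n[out$ecc_lo == 2], 0)       # empty bin, no value
  expect_true(is.na(out$median[out$ecc_lo == 2]))
  # a linear trend in the population is recovered by per-bin medians
  set.seed(3)
  ecc <- runif(300, 0, 10)
  ang <- runif(300, 0, 2 * pi)
  pop <- data.frame(x = ecc * cos(ang), y = ecc * sin(ang),
                    win = 50 + 10 * ecc)
  b <- bin_by_eccentricity(pop, "win", width_deg = 2, max_ecc = 10)
  mid <- (b$ecc_lo + b$ecc_hi) / 2
  expect_equal(b$median, 50 + 10 * mid, tolerance = 0.05)
})
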