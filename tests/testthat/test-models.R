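test_that("gaussian receptive field matches its closed form", {
  geom <- bar_geometry("spatiotemporal")
  g <- pixel_grid(geom)
  rf <- gaussian_rf(0, 0, 1, g)
  at <- function(x, y) rf[which.min((g$X - x)^2 + (g$Y - y)^2)]
  # grid point nearest (1, 0): evaluate the analytic value there instead of
  # asserting exp(-1/2) at an off-grid location
  i <- which.min((g$X - 1)^2 + g$Y^2)
  expect_equal(rf[i], exp(-((g$X[i])^2 + (g$Y[i])^2) / 2))
  expect_equal(max(rf), at(0, 0))
  expect_equal(at(0, 0), 1, tolerance = 1e-6)
  # numeric-integration oracle: grid sum ~ 2 pi sigma^2 / pixel area
  expect_equal(sum(rf) * g$px_deg^2, 2 * pi, tolerance = 0.01)
  expect_error(gaussian_rf(0, 0, -1, g), "parameter-domain")
})

test_that("spatial drive equals the frame-by-frame pixel sums", {
  st <- toy_stim(seed = 3L)
  rf <- gaussian_rf(1, -1, 1.2, st$grid)
  drv <- spatial_drive(st, rf)
  expect_true(all(drv >= 0))
  idx <- c(10L, 333L, 2501L, 7600L)
  frames <- stim_frames(st, idx)
  for (k in seq_along(idx)) {
    expect_equal(drv[idx[k]], sum(as.vector(frames[, , k]) * rf))
  }
  expect_error(spatial_drive(st, rf[-1]), "shape")
})

test_that("sustained gamma kernel peaks at (m-1) kappa tau with unit sum", {
  for (tau in c(5, 20, 80)) {
    h <- sustained_irf(tau)
    expect_equal(which.max(h), 8 * tau, tolerance = 1.5 / (8 * tau))
    expect_true(all(h >= 0))
    expect_equal(sum(h), 1)
    expect_lt(h[1], max(h) / 100)  # starts near zero for m > 1
  }
  expect_error(sustained_irf(-2), "parameter-domain")
})

test_that("transient kernels are biphasic, zero-integral, sign-symmetric", {
  tr <- transient_irfs(20)
  expect_equal(sum(tr$on), 0, tolerance = 1e-12)
  expect_identical(tr$off, -tr$on)
  # positive lobe peaks before the sustained kernel peak
  expect_lt(which.max(tr$on), which.max(sustained_irf(20)))
})

test_that("compiled CST forward equals the plain-R reference", {
  st <- toy_stim(seed = 4L)
  par <- cst_prf(0.5, -0.5, 1.3, tau = 30, n_exp = 0.4)
  nt <- predict_neural(st, par)
  rf <- gaussian_rf(0.5, -0.5, 1.3, st$grid)
  drv <- spatial_drive(st, rf)
  r1 <- apply_irf(drv, sustained_irf(30))
  r2 <- apply_irf(drv, transient_irfs(30)$on)
  expect_equal(nt[, "sustained"], pmax(r1, 0)^0.4, tolerance = 1e-6)
  expect_equal(nt[, "transient_on"], pmax(r2, 0)^0.4, tolerance = 1e-6)
  expect_equal(nt[, "transient_off"], pmax(-r2, 0)^0.4, tolerance = 1e-6)
  expect_true(all(nt >= 0))
})

test_that("CST compression scales as a pure power law", {
  st <- toy_stim(seed = 4L)
  drv <- spatial_drive(st, gaussian_rf(0, 0, 1.5, st$grid))
  r <- apply_irf(drv, sustained_irf(15))
  n <- 0.37
  for (c_scale in c(2, 5.5)) {
    expect_equal(pmax(c_scale * r, 0)^n, c_scale^n * pmax(r, 0)^n,
                 tolerance = 1e-12)
  }
  # zero stimulus gives identically zero channels
  nt0 <- predict_neural(toy_stim_blank(), cst_prf(0, 0, 1, 20, 0.5))
  expect_true(all(nt0 == 0))
  # n = 1 leaves the (nonnegative) sustained response uncompressed
  nt1 <- predict_neural(st, cst_prf(0, 0, 1.5, 15, 1))
  expect_equal(nt1[, "sustained"], pmax(r, 0), tolerance = 1e-6)
})

test_that("a pulse drives matched on-transient and off-transient responses", {
  # pulse longer than the kernel support, so the onset response completes
  # before the offset arrives: the off lobe is then the exact mirror of the
  # on lobe (r2(t) = C2(t - t_on) - C2(t - t_off) with C2 returning to ~0)
  pulse <- c(numeric(50), rep(1, 100), numeric(300))  # 1 s pulse
  r2 <- apply_irf(pulse, transient_irfs(2)$on)
  on_resp <- pmax(r2, 0)
  off_resp <- pmax(-r2, 0)
  expect_equal(max(on_resp), max(off_resp), tolerance = 1e-6)
  # onset and offset responses are separated by the pulse duration
  expect_equal(which.max(off_resp) - which.max(on_resp), 100)
})

test_that("compiled DN-ST forward equals the reference nonlinearity", {
  st <- toy_stim(seed = 4L)
  par <- dnst_prf(0.5, -0.5, 1.3, tau1 = 0.07, tau2 = 0.2, sigma_dn = 0.15,
                  n_dn = 2.5)
  nt <- predict_neural(st, par)
  drv <- spatial_drive(st, gaussian_rf(0.5, -0.5, 1.3, st$grid))
  r <- apply_irf(drv, dnst_irfs(0.07, 0.2)$h1)
  ref <- dnst_nonlinearity(r, 0.2, 0.15, 2.5)
  expect_equal(nt[, 1], ref, tolerance = 1e-8)
  expect_true(all(nt >= 0))
  expect_true(all(predict_neural(toy_stim_blank(), par) == 0))
})

test_that("DN-ST is sign-invariant and subadditive in time", {
  r <- c(numeric(10), rep(2, 60), numeric(130))
  expect_equal(dnst_nonlinearity(r, 0.1, 0.1, 2),
               dnst_nonlinearity(-r, 0.1, 0.1, 2))
  # one 600 ms pulse vs three 200 ms pulses with the same total on-time
  h1 <- dnst_irfs(0.05, 0.1)$h1
  long_drive <- c(numeric(10), rep(1, 60), numeric(230))
  split_drive <- c(numeric(10), rep(c(rep(1, 20), numeric(40)), 3),
                   numeric(110))
  resp <- function(drv) sum(dnst_nonlinearity(apply_irf(drv, h1), 0.1, 0.1, 2))
  expect_lt(resp(long_drive), resp(split_drive))
  # large semisaturation with n = 1 approaches a scaled linear response
  r_pos <- apply_irf(long_drive, h1)
  big <- 1e4
  expect_equal(dnst_nonlinearity(r_pos, 0.1, big, 1), r_pos / big,
               tolerance = 1e-3)
})

test_that("all model outputs are time-shift equivariant", {
  drv <- c(numeric(20), rep(1, 30), numeric(250))
  shift <- 17L
  drv_s <- c(numeric(shift), drv)[seq_along(drv)]
  h <- sustained_irf(10)
  expect_equal(apply_irf(drv_s, h)[(shift + 1):300],
               apply_irf(drv, h)[1:(300 - shift)], tolerance = 1e-10)
  p <- dnst_nonlinearity(apply_irf(drv, dnst_irfs(0.05, 0.1)$h1), 0.1, 0.1, 2)
  p_s <- dnst_nonlinearity(apply_irf(drv_s, dnst_irfs(0.05, 0.1)$h1),
                           0.1, 0.1, 2)
  expect_equal(p_s[(shift + 1):300], p[1:(300 - shift)], tolerance = 1e-8)
})

test_that("the spatial model is the linear drive", {
  st <- toy_stim(seed = 5L)
  par <- spatial_prf(0.3, 0.7, 1.1)
  nt <- predict_neural(st, par)
  drv <- spatial_drive(st, gaussian_rf(0.3, 0.7, 1.1, st$grid))
  expect_equal(nt[, 1], drv)
  # equivalent to the CST sustained channel with n = 1 and an identity kernel
  expect_equal(nt[, 1], pmax(apply_irf(drv, 1), 0), tolerance = 1e-9)
})
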