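test_that("ground-truth sampling respects the stated parameter ranges", {
  gt <- sample_ground_truth("cst", 200, seed = 9)
  ecc <- sqrt(gt$x^2 + gt$y^2)
  expect_true(all(ecc <= 10))
  expect_true(all(gt$sigma >= 0.2 & gt$sigma <= 3))
  expect_true(all(gt$tau >= 4 & gt$tau <= 100))
  expect_true(all(gt$n_exp >= 0.1 & gt$n_exp <= 1))
  gtd <- sample_ground_truth("dnst", 200, seed = 9)
  expect_true(all(gtd$tau1 >= 0.01 & gtd$tau1 <= 1))
  expect_true(all(gtd$sigma_dn >= 0.01 & gtd$sigma_dn <= 0.5))
  expect_true(all(gtd$n_dn >= 1 & gtd$n_dn <= 6))
  # identical seed -> identical draws; same spatial params across model kinds
  expect_identical(sample_ground_truth("cst", 200, seed = 9), gt)
  expect_equal(gtd[, c("x", "y", "sigma")], gt[, c("x", "y", "sigma")])
  # default population size
  expect_equal(nrow(sample_ground_truth("spatial", seed = 1)), 300)
})

test_that("synthesized time courses show one response peak per bar sweep", {
  # deterministic schedule: every bar location continuously on (condition 9)
  geom <- toy_geom()
  sched <- run_schedule(geom, n_runs = 1L, seed = 10L)
  sched$cond <- 9L
  st <- assemble_run(geom, sched)
  gt <- sample_ground_truth("spatial", 1, seed = 1)
  gt$x <- 0; gt$y <- 0; gt$sigma <- 1.5
  bold <- synthesize_bold(gt, st)
  b <- bold[, 1]
  # local maxima above half the peak: one per sweep (4 sweeps per run)
  big <- which(b > max(b) / 2 & b > c(-Inf, head(b, -1)) &
                 b >= c(tail(b, -1), -Inf))
  expect_equal(length(big), 4)
  # per-run mean removal (percent-signal-change convention)
  expect_equal(mean(b), 0, tolerance = 1e-10)
  # re-synthesis is bit-identical
  expect_identical(bold, synthesize_bold(gt, st))
  # a pRF far outside the stimulated field barely responds
  far <- gt; far$x <- 11; far$y <- 11; far$sigma <- 0.2
  class(far) <- class(gt); attr(far, "model_kind") <- "spatial"
  expect_lt(max(abs(synthesize_bold(far, st))), max(abs(b)) * 1e-6)
})

test_that("noise calibration hits the target SNR exactly", {
  st <- toy_stim(n_runs = 2L, seed = 11L)
  gt <- sample_ground_truth("spatial", 5, seed = 2)
  bold <- synthesize_bold(gt, st)
  noisy <- add_noise(bold, noise_spec(target_snr_db = 0.1, seed = 3))
  for (v in 1:5) {
    realized <- measure_snr_db(bold[, v], noisy[, v] - bold[, v])
    expect_equal(realized, 0.1, tolerance = 0.05)
    expect_equal(mean(noisy[, v] - bold[, v]), 0, tolerance = 1e-8)
  }
  # determinism and per-voxel independence
  noisy2 <- add_noise(bold, noise_spec(target_snr_db = 0.1, seed = 3))
  expect_identical(unclass(noisy), unclass(noisy2))
  expect_gt(sd((noisy - bold)[, 1] - (noisy - bold)[, 2]), 0)
  # infinite SNR leaves the input untouched
  expect_identical(add_noise(bold, noise_spec(target_snr_db = Inf)), bold)
  # zero-variance signal cannot be calibrated
  flat <- matrix(1, nrow(bold), 1)
  expect_error(add_noise(flat, noise_spec(), n_runs = 2L), "zero-variance")
})

test_that("SNR measurement follows the demeaned power-ratio definition", {
  s <- sin(seq(0, 20, by = 0.1))
  n <- rnorm(length(s))
  n <- n * sd(s) / sd(n)
  expect_equal(measure_snr_db(s, n), 0, tolerance = 1e-6)
  expect_equal(measure_snr_db(s, n / sqrt(10)), 10, tolerance = 1e-6)
  # dB level that corresponds to a target ground-truth variance explained
  expect_equal(snr_db_for_r2(0.5), 0)
  expect_equal(10^(snr_db_for_r2(0.3) / 10), 3 / 7, tolerance = 1e-12)
})

test_that("noise at the R2-matched level yields ~0.3 variance explained", {
  st <- toy_stim(n_runs = 2L, seed = 12L)
  gt <- sample_ground_truth("spatial", 25, seed = 5)
  bold <- synthesize_bold(gt, st)
  noisy <- add_noise(bold, noise_spec(target_snr_db = snr_db_for_r2(0.3),
                                      seed = 8))
  r2 <- vapply(1:25, function(v) variance_explained(bold[, v], noisy[, v]), 0)
  expect_equal(mean(r2), 0.3, tolerance = 0.15)
})

test_that("models with shared spatial parameters share response peak times", {
  # deterministic continuous-on schedule; moderate temporal parameters so
  # all three models respond within the same sweep
  geom <- toy_geom()
  sched <- run_schedule(geom, n_runs = 1L, seed = 13L)
  sched$cond <- 9L
  st <- assemble_run(geom, sched)
  sp <- sample_ground_truth("spatial", 1, seed = 3)
  sp$x <- 1; sp$y <- 0; sp$sigma <- 1.5
  cs <- sample_ground_truth("cst", 1, seed = 3, spatial_from = sp)
  cs$tau <- 10; cs$n_exp <- 0.5
  dn <- sample_ground_truth("dnst", 1, seed = 3, spatial_from = sp)
  dn$tau1 <- 0.05; dn$tau2 <- 0.1; dn$sigma_dn <- 0.1; dn$n_dn <- 2
  expect_equal(cs$x, sp$x)
  expect_equal(dn$sigma, sp$sigma)
  # first-sweep window: peaks align within a few seconds across models
  n_slot_sec <- geom$n_steps * geom$slot_ms / 1000
  peaks <- vapply(list(sp, cs, dn), function(g) {
    which.max(synthesize_bold(g, st)[seq_len(n_slot_sec), 1])
  }, 0L)
  # peaks fall within two bar steps of each other (models differ in
  # amplitude, latency and width but localize the same sweep position)
  expect_lt(diff(range(peaks)), 2 * geom$slot_ms / 1000 + 1)
})
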