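test_that("geometry validation enforces that steps tile the field", {
  expect_error(bar_geometry("spatiotemporal", n_steps = 7L),
               "invalid-design")
  geom <- bar_geometry("spatiotemporal")
  span <- (geom$n_steps - 1) * (geom$bar_width_deg - geom$overlap_deg) +
    geom$bar_width_deg
  expect_equal(span, 2 * geom$field_radius_deg)
  # implied toonotopy bar width also tiles the field
  toon <- bar_geometry("toonotopy")
  expect_equal((toon$n_steps - 1) * (toon$bar_width_deg - toon$overlap_deg) +
                 toon$bar_width_deg, 24)
})

test_that("bar apertures are binary bands inside the circular field", {
  geom <- bar_geometry("spatiotemporal")
  ap <- build_bar_aperture(geom, 0, 5)
  expect_true(all(ap %in% c(0, 1)))
  g <- pixel_grid(geom)
  outside <- g$X^2 + g$Y^2 > geom$field_radius_deg^2
  expect_true(all(as.vector(ap)[outside] == 0))
  # on-fraction of the center bar matches the analytic band-within-disk area
  band_area <- 2 * integrate(function(u) {
    sqrt(pmax(geom$field_radius_deg^2 - u^2, 0))
  }, -geom$bar_width_deg / 2, geom$bar_width_deg / 2)$value
  frac_expect <- band_area / (2 * geom$field_radius_deg)^2
  # one pixel row of slack: the 3 deg band covers 7.6 pixel widths
  expect_equal(mean(ap), frac_expect, tolerance = 1 / 7.6)
  # and is close to the width/diameter ratio
  expect_equal(mean(ap), 3 / 24, tolerance = 0.15)
})

test_that("adjacent bar steps advance by width minus overlap", {
  geom <- bar_geometry("spatiotemporal")
  g <- pixel_grid(geom)
  centers <- vapply(1:geom$n_steps, function(s) {
    ap <- as.vector(build_bar_aperture(geom, 0, s))
    sum(g$X * ap) / sum(ap)
  }, 0)
  expect_equal(diff(centers), rep(2.625, 8), tolerance = 0.1)
  # 45-degree sweep: centers advance along the diagonal axis
  c45 <- vapply(1:geom$n_steps, function(s) {
    ap <- as.vector(build_bar_aperture(geom, 45, s))
    sum((g$X + g$Y) / sqrt(2) * ap) / sum(ap)
  }, 0)
  expect_equal(diff(c45), rep(2.625, 8), tolerance = 0.15)
  expect_error(build_bar_aperture(geom, 30, 1), "invalid-design")
  expect_error(build_bar_aperture(geom, 0, 10), "invalid-design")
})

test_that("temporal profiles reproduce the nine presentation conditions", {
  tab <- temporal_conditions()
  for (i in 1:9) {
    prof <- build_temporal_profile(tab[i, ])
    expect_length(prof, 500)
    expect_true(all(prof %in% c(0L, 1L)))
    n_epochs <- sum(diff(c(0L, prof)) == 1)
    expect_equal(n_epochs, tab$n_images[i])
    # total on-time within one frame per epoch of n_images * on_ms
    expect_lt(abs(sum(prof) - tab$n_images[i] * tab$on_ms[i] / 10),
              tab$n_images[i] / 2 + 1)
  }
  # conditions 1, 7, 8 share a 4 s total on-time
  for (i in c(1, 7, 8)) {
    expect_equal(sum(build_temporal_profile(tab[i, ])), 400, tolerance = 0.01)
  }
  expect_true(all(build_temporal_profile(9) == 1L))
  overflow <- data.frame(on_ms = 600, isi_ms = 0, n_images = 10L,
                         slot_ms = 5000)
  expect_error(build_temporal_profile(overflow), "schedule-overflow")
})

test_that("the 9-run counterbalance places each condition once per location", {
  geom <- bar_geometry("spatiotemporal")
  sched <- run_schedule(geom, n_runs = 9L, seed = 3L)
  counts <- table(sched$cond, paste(sched$angle, sched$step))
  expect_true(all(counts == 1))
  # every run shows each condition exactly 4 times (once per sweep)
  expect_true(all(table(sched$run, sched$cond) == 4))
})

test_that("assembled frames equal aperture AND temporal profile", {
  st <- toy_stim(n_runs = 1L, seed = 2L)
  tab <- temporal_conditions()
  sl <- st$slots
  for (i in c(1, 7, 20)) {
    prof <- build_temporal_profile(tab[sl$cond[i], ])
    frames <- sl$t0_frame[i] + seq_along(prof)
    expect_equal(st$frame_ap[frames], sl$ap[i] * prof)
  }
  # materialized frames are the aperture exactly when on
  on_frame <- sl$t0_frame[1] + which(st$frame_ap[sl$t0_frame[1] + 1:500] > 0)[1]
  arr <- stim_frames(st, c(on_frame))
  expect_equal(as.vector(arr[, , 1]), st$apertures[, sl$ap[1]])
  expect_true(all(arr %in% c(0, 1)))
})

test_that("stimulus rendering is deterministic in the seed and blanks are zero", {
  a <- stim_spatiotemporal(n_runs = 2L, seed = 5L)
  b <- stim_spatiotemporal(n_runs = 2L, seed = 5L)
  expect_identical(a$frame_ap, b$frame_ap)
  expect_identical(a$intervals, b$intervals)
  d <- stim_spatiotemporal(n_runs = 2L, seed = 6L)
  expect_false(identical(a$frame_ap, d$frame_ap))
  blank <- toy_stim_blank()
  rf <- gaussian_rf(0, 0, 1, blank$grid)
  expect_true(all(spatial_drive(blank, rf) == 0))
})

test_that("toonotopy design has 12 2-s steps per sweep at 8 Hz refresh", {
  st <- stim_toonotopy(n_runs = 1L, refresh_gaps = FALSE)
  expect_equal(st$frames_per_run, 48 * 200)  # 4 sweeps x 12 steps x 2 s
  expect_equal(st$frames_per_slot, 200)
  expect_true(all(st$frame_ap[1:200] == st$slots$ap[1]))  # continuously on
  gaps <- stim_toonotopy(n_runs = 1L)        # default: 8 Hz refresh gaps
  prof <- as.integer(gaps$frame_ap[1:200] > 0)
  expect_equal(sum(diff(c(0L, prof)) == 1), 16)  # 16 refreshes of 125 ms
})
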