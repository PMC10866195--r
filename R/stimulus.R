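#' Bar-sweep stimulus geometry
#'
#' Describes the traveling-bar aperture geometry used by the spatiotemporal
#' mapping design and its conventional 8 Hz counterpart ("toonotopy"). The
#' visual field is a disk of `field_radius_deg` degrees centered at fixation,
#' rasterized onto a square `grid_px` x `grid_px` pixel grid spanning
#' \[-radius, +radius\] in both dimensions (x rightward, y upward; pixel size
#' `2 * field_radius_deg / grid_px` degrees). A bar of width `bar_width_deg`
#' sweeps the field in `n_steps` steps along each of the `angles_deg` sweep
#' axes; adjacent steps overlap by `overlap_deg`, so the step size is
#' `bar_width_deg - overlap_deg` and the steps tile the full diameter exactly.
#'
#' @param design `"spatiotemporal"` (9 steps, 0.375 deg overlap, 5 s per bar
#'   location) or `"toonotopy"` (12 steps, 0.27 deg overlap, 2 s per step with
#'   8 Hz image refresh). Individual fields can be overridden for reduced toy
#'   geometries in tests.
#' @param field_radius_deg,bar_width_deg,overlap_deg,n_steps,angles_deg,grid_px,slot_ms
#'   Optional overrides of the named design's parameters.
#' @return An object of class `bar_geometry`.
#' @export
bar_geometry <- function(design = c("spatiotemporal", "toonotopy"),
                         field_radius_deg = NULL, bar_width_deg = NULL,
                         overlap_deg = NULL, n_steps = NULL,
                         angles_deg = NULL, grid_px = NULL, slot_ms = NULL) {
  design <- match.arg(design)
  geom <- if (design == "spatiotemporal") {
    list(design = design, field_radius_deg = 12, bar_width_deg = 3,
         overlap_deg = 0.375, n_steps = 9L,
         angles_deg = c(0, 45, 90, 135), grid_px = 61L, slot_ms = 5000)
  } else {
    # 12 steps tile the 24 deg diameter with 0.27 deg overlap; the implied bar
    # width solves (n-1)(w - overlap) + w = diameter.
    w <- (24 + 11 * 0.27) / 12
    list(design = design, field_radius_deg = 12, bar_width_deg = w,
         overlap_deg = 0.27, n_steps = 12L,
         angles_deg = c(0, 45, 90, 135), grid_px = 61L, slot_ms = 2000)
  }
  ovr <- list(field_radius_deg = field_radius_deg,
              bar_width_deg = bar_width_deg, overlap_deg = overlap_deg,
              n_steps = n_steps, angles_deg = angles_deg, grid_px = grid_px,
              slot_ms = slot_ms)
  for (nm in names(ovr)) if (!is.null(ovr[[nm]])) geom[[nm]] <- ovr[[nm]]
  geom$n_steps <- as.integer(geom$n_steps)
  geom$grid_px <- as.integer(geom$grid_px)
  validate_geometry(geom)
  class(geom) <- "bar_geometry"
  geom
}

validate_geometry <- function(geom) {
  d <- 2 * geom$field_radius_deg
  span <- (geom$n_steps - 1) * (geom$bar_width_deg - geom$overlap_deg) +
    geom$bar_width_deg
  if (abs(span - d) > 1e-8) {
    stop("invalid-design: ", geom$n_steps, " steps of width ",
         geom$bar_width_deg, " with overlap ", geom$overlap_deg,
         " span ", span, " deg, not the field diameter ", d, " deg")
  }
  if (geom$grid_px < 3L) stop("invalid-design: grid_px must be >= 3")
  invisible(geom)
}

#' Pixel-center coordinates of the stimulus grid
#'
#' @param geom A [bar_geometry()].
#' @return List with vectors `x`, `y` (pixel centers, degrees) and the
#'   flattened meshes `X`, `Y` (column-major, length `grid_px^2`) plus
#'   `px_deg`, the pixel size in degrees.
#' @export
pixel_grid <- function(geom) {
  r <- geom$field_radius_deg
  n <- geom$grid_px
  px <- 2 * r / n
  centers <- -r + (seq_len(n) - 0.5) * px
  list(x = centers, y = centers,
       X = rep(centers, times = n), Y = rep(centers, each = n),
       px_deg = px)
}

#' Binary bar aperture for one sweep step
#'
#' The bar is a band of width `bar_width_deg` orthogonal to the sweep axis
#' `angle_deg` (measured from the positive x axis), intersected with the
#' circular stimulus field. Step 1 starts at the field edge; the band center
#' advances by `bar_width_deg - overlap_deg` per step so that adjacent bars
#' overlap by `overlap_deg`.
#'
#' @param geom A [bar_geometry()].
#' @param angle_deg Sweep-axis angle; must be one of `geom$angles_deg`.
#' @param step Step index in `1:geom$n_steps`.
#' @return A `grid_px` x `grid_px` binary (0/1) matrix; rows index x, columns
#'   index y.
#' @export
build_bar_aperture <- function(geom, angle_deg, step) {
  if (!angle_deg %in% geom$angles_deg) {
    stop("invalid-design: angle ", angle_deg, " not in design angles")
  }
  if (step < 1 || step > geom$n_steps || step != round(step)) {
    stop("invalid-design: step must be an integer in 1..", geom$n_steps)
  }
  g <- pixel_grid(geom)
  th <- angle_deg * pi / 180
  u <- g$X * cos(th) + g$Y * sin(th)
  ctr <- -geom$field_radius_deg + geom$bar_width_deg / 2 +
    (step - 1) * (geom$bar_width_deg - geom$overlap_deg)
  inside <- abs(u - ctr) <= geom$bar_width_deg / 2 &
    (g$X^2 + g$Y^2) <= geom$field_radius_deg^2
  matrix(as.numeric(inside), geom$grid_px, geom$grid_px)
}

#' Temporal presentation conditions
#'
#' Nine within-slot presentation schedules: each 5 s bar location shows
#' `n_images` image epochs of `on_ms` separated by `isi_ms`. Conditions 1-3
#' fix the on-duration (133 ms) and vary the ISI; conditions 4-6 fix the ISI
#' (133 ms) and vary the on-duration; conditions 1, 7 and 8 share a 4 s total
#' on-time with 30, 15 and 5 images; condition 9 is a single uninterrupted 5 s
#' presentation.
#'
#' @return A data frame with columns `id`, `on_ms`, `isi_ms`, `n_images`,
#'   `slot_ms`.
#' @export
temporal_conditions <- function() {
  data.frame(
    id = 1:9,
    on_ms = c(133, 133, 133, 33, 200, 867, 4000 / 15, 800, 5000),
    isi_ms = c(33, 200, 867, 133, 133, 133, 1000 / 15, 200, 0),
    n_images = c(30L, 15L, 5L, 30L, 15L, 5L, 15L, 5L, 1L),
    slot_ms = 5000
  )
}

#' Binary on/off profile of one temporal condition
#'
#' Image epochs are laid out at exact millisecond times (`i * (on + isi)` for
#' epoch `i`) and each on/off boundary is rounded to the nearest frame, so
#' rounding errors do not accumulate across epochs and the total on-time stays
#' within one frame of `n_images * on_ms`.
#'
#' @param cond A single-row data frame with `on_ms`, `isi_ms`, `n_images`,
#'   `slot_ms` (a row of [temporal_conditions()]), or a condition id `1:9`.
#' @param dt_ms Frame duration, default 10 ms.
#' @return Integer 0/1 vector of length `slot_ms / dt_ms`.
#' @export
build_temporal_profile <- function(cond, dt_ms = 10) {
  if (is.numeric(cond) && length(cond) == 1) {
    tab <- temporal_conditions()
    if (!cond %in% tab$id) stop("invalid-design: condition id must be 1..9")
    cond <- tab[tab$id == cond, ]
  }
  n_frames <- as.integer(round(cond$slot_ms / dt_ms))
  prof <- integer(n_frames)
  period <- cond$on_ms + cond$isi_ms
  last_end <- (cond$n_images - 1) * period + cond$on_ms
  if (last_end > cond$slot_ms + 1e-6) {
    stop("schedule-overflow: ", cond$n_images, " epochs of ", cond$on_ms,
         "/", cond$isi_ms, " ms exceed the ", cond$slot_ms, " ms slot")
  }
  for (i in seq_len(cond$n_images) - 1) {
    s <- round(i * period / dt_ms)
    e <- round((i * period + cond$on_ms) / dt_ms)
    e <- min(e, n_frames)
    if (e > s) prof[(s + 1):e] <- 1L
  }
  prof
}

#' Counterbalanced run schedule
#'
#' Assigns one temporal condition to each bar location (angle x step) in each
#' run such that, across `n_runs = 9` runs, every condition occurs exactly
#' once at every location. The assignment is a seeded cyclic design: each
#' location gets a random phase offset and condition `((run + offset) mod 9) +
#' 1`; each run then contains every condition exactly four times.
#'
#' @param geom A [bar_geometry()].
#' @param n_runs Number of runs (9 for the full counterbalance).
#' @param seed Integer seed for the per-location phase offsets.
#' @param angles_order Sweep order of the angles within a run.
#' @return Data frame with one row per (run, angle, step) slot in presentation
#'   order, columns `run`, `angle`, `step`, `cond`.
#' @export
run_schedule <- function(geom, n_runs = 9L, seed = 1L,
                         angles_order = geom$angles_deg) {
  stopifnot(all(angles_order %in% geom$angles_deg))
  n_cond <- 9L
  locs <- expand.grid(step = seq_len(geom$n_steps), angle = angles_order)
  # balanced phase offsets: each residue equally often across locations, so
  # within a run every condition also appears equally often (exactly four
  # times for the 36-location design)
  offsets <- withr::with_seed(seed,
    sample(rep_len(seq_len(n_cond) - 1L, nrow(locs))))
  out <- do.call(rbind, lapply(seq_len(n_runs), function(r) {
    data.frame(run = r, angle = locs$angle, step = locs$step,
               cond = ((r - 1 + offsets) %% n_cond) + 1L)
  }))
  # presentation order: angle sweeps in order, steps in order within sweep
  out <- out[order(out$run, match(out$angle, angles_order), out$step), ]
  rownames(out) <- NULL
  out
}

# Shared builder: renders a stimulus sequence from a geometry, a slot table
# (run/angle/step/cond) and a per-slot temporal profile function.
build_stimulus <- function(geom, slots, profiles, design_label, seed = NA) {
  dt_ms <- 10
  frames_per_slot <- as.integer(round(geom$slot_ms / dt_ms))
  n_runs <- length(unique(slots$run))
  slots_per_run <- nrow(slots) / n_runs
  frames_per_run <- as.integer(slots_per_run * frames_per_slot)

  # unique apertures, flattened as grid_px^2 x K
  key <- paste(slots$angle, slots$step)
  ukey <- unique(key)
  ap_of_slot <- match(key, ukey)
  parts <- strsplit(ukey, " ")
  ap_angle <- as.numeric(vapply(parts, `[`, "", 1))
  ap_step <- as.integer(vapply(parts, `[`, "", 2))
  A <- vapply(seq_along(ukey), function(k) {
    as.vector(build_bar_aperture(geom, ap_angle[k], ap_step[k]))
  }, numeric(geom$grid_px^2))

  frame_ap <- integer(n_runs * frames_per_run)
  iv <- vector("list", nrow(slots))
  for (i in seq_len(nrow(slots))) {
    prof <- profiles[[i]]
    r <- slots$run[i]
    slot_in_run <- (i - 1) %% slots_per_run
    t0 <- slot_in_run * frames_per_slot  # 0-based within run
    rl <- rle(prof)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths
    on <- rl$values == 1L
    if (any(on)) {
      iv[[i]] <- data.frame(run = r, start0 = t0 + starts[on],
                            end0 = t0 + ends[on], ap = ap_of_slot[i])
      idx <- (r - 1) * frames_per_run + t0 + which(prof == 1L)
      frame_ap[idx] <- ap_of_slot[i]
    }
  }
  intervals <- do.call(rbind, iv)
  intervals <- intervals[order(intervals$run, intervals$start0), ]
  rownames(intervals) <- NULL

  slots$ap <- ap_of_slot
  slots$t0_frame <- ((seq_len(nrow(slots)) - 1) %% slots_per_run) *
    frames_per_slot
  pkey <- vapply(profiles, paste, "", collapse = "")
  upk <- unique(pkey)
  slots$prof_id <- match(pkey, upk)
  uprofiles <- profiles[match(upk, pkey)]

  structure(list(
    design_label = design_label, geometry = geom, dt_ms = dt_ms,
    grid = pixel_grid(geom), apertures = A, ap_angle = ap_angle,
    ap_step = ap_step, n_runs = n_runs, frames_per_run = frames_per_run,
    frames_per_slot = frames_per_slot, frame_ap = frame_ap,
    intervals = intervals, slots = slots, profiles = uprofiles, seed = seed
  ), class = "stim_sequence")
}

#' Assemble a stimulus sequence from a schedule
#'
#' Renders the binarized space-time movie `I(X, Y, t)` implied by a run
#' schedule: at every 10 ms frame the image is the bar aperture of the current
#' slot gated by the slot's temporal on/off profile.
#'
#' @param geom A [bar_geometry()].
#' @param schedule A schedule data frame from [run_schedule()] (any subset of
#'   runs; every slot must carry a condition).
#' @return A `stim_sequence` object (compact representation: unique apertures
#'   plus a per-frame aperture index; use [stim_frames()] to materialize
#'   frames).
#' @export
assemble_run <- function(geom, schedule) {
  need <- c("run", "angle", "step", "cond")
  if (!all(need %in% names(schedule)) || anyNA(schedule[need])) {
    stop("invalid-schedule: schedule must provide run, angle, step, cond")
  }
  per_run <- table(schedule$run)
  if (length(unique(per_run)) != 1) {
    stop("invalid-schedule: all runs must contain the same number of slots")
  }
  tab <- temporal_conditions()
  tab$slot_ms <- geom$slot_ms
  profiles <- lapply(schedule$cond, function(cid) {
    build_temporal_profile(tab[tab$id == cid, ])
  })
  build_stimulus(geom, schedule, profiles, geom$design)
}

#' Spatiotemporal mapping stimulus (9 counterbalanced runs)
#'
#' @param n_runs Number of runs (default 9).
#' @param seed Seed for the condition counterbalance.
#' @return A `stim_sequence`.
#' @export
stim_spatiotemporal <- function(n_runs = 9L, seed = 1L) {
  geom <- bar_geometry("spatiotemporal")
  sched <- run_schedule(geom, n_runs = n_runs, seed = seed)
  out <- assemble_run(geom, sched)
  out$seed <- seed
  out
}

#' Toonotopy stimulus (8 Hz traveling bar)
#'
#' Conventional traveling-bar retinotopy: 12 bar steps per sweep, 2 s per
#' step, four sweep angles per run. The bar content refreshes at 8 Hz; by
#' default each 125 ms image epoch is rendered with a one-frame off gap at
#' the refresh, so image transitions drive transient channels at the
#' design's presentation rate. `refresh_gaps = FALSE` renders each 2 s step
#' as continuously on instead (a binarization with no temporal structure
#' within steps).
#'
#' @param n_runs Number of runs (default 4).
#' @param refresh_gaps Insert 10 ms off gaps at 8 Hz refreshes?
#' @return A `stim_sequence`.
#' @export
stim_toonotopy <- function(n_runs = 4L, refresh_gaps = TRUE) {
  geom <- bar_geometry("toonotopy")
  slots <- do.call(rbind, lapply(seq_len(n_runs), function(r) {
    expand.grid(step = seq_len(geom$n_steps), angle = geom$angles_deg,
                run = r)[, c("run", "angle", "step")]
  }))
  slots$cond <- NA_integer_
  n_frames <- as.integer(geom$slot_ms / 10)
  prof <- rep(1L, n_frames)
  if (refresh_gaps) {
    # one-frame off gap at each interior 125 ms refresh boundary (15 gaps,
    # 16 image epochs per 2 s step); built directly since 12.5-frame epochs
    # do not survive per-epoch rounding
    gap_at <- floor(125 * seq_len(16 * geom$slot_ms / 2000 - 1) / 10) + 1L
    prof[gap_at] <- 0L
  }
  profiles <- rep(list(prof), nrow(slots))
  build_stimulus(geom, slots, profiles, "toonotopy")
}

#' Materialize stimulus frames
#'
#' @param stim A `stim_sequence`.
#' @param t Frame indices (1-based, over the concatenated runs).
#' @return Binary array `grid_px` x `grid_px` x `length(t)`.
#' @export
stim_frames <- function(stim, t) {
  n <- stim$geometry$grid_px
  out <- array(0, c(n, n, length(t)))
  for (i in seq_along(t)) {
    k <- stim$frame_ap[t[i]]
    if (k > 0) out[, , i] <- matrix(stim$apertures[, k], n, n)
  }
  out
}

#' Subset runs of a stimulus sequence
#'
#' @param stim A `stim_sequence`.
#' @param runs Run numbers to keep (renumbered 1..length(runs)).
#' @return A `stim_sequence` containing only those runs.
#' @export
stim_subset_runs <- function(stim, runs) {
  stopifnot(all(runs %in% seq_len(stim$n_runs)))
  fpr <- stim$frames_per_run
  keep_frames <- unlist(lapply(runs, function(r) (r - 1) * fpr + seq_len(fpr)))
  iv <- stim$intervals[stim$intervals$run %in% runs, ]
  iv$run <- match(iv$run, runs)
  iv <- iv[order(iv$run, iv$start0), ]
  rownames(iv) <- NULL
  out <- stim
  out$n_runs <- length(runs)
  out$frame_ap <- stim$frame_ap[keep_frames]
  out$intervals <- iv
  out$slots <- stim$slots[stim$slots$run %in% runs, ]
  out$slots$run <- match(out$slots$run, runs)
  out
}

#' @export
print.stim_sequence <- function(x, ...) {
  cat("<stim_sequence>", x$design_label, "\n",
      " runs:", x$n_runs, "x", x$frames_per_run, "frames @", x$dt_ms, "ms (",
      x$frames_per_run / 100, "s per run)\n",
      " grid:", x$geometry$grid_px, "x", x$geometry$grid_px, "px over [-",
      x$geometry$field_radius_deg, ",", x$geometry$field_radius_deg, "] deg\n",
      " apertures:", ncol(x$apertures), "\n")
  invisible(x)
}
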