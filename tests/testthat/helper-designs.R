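# Reduced designs used by the unit tests: a 12-deg-diameter field with 5 bar
# steps on a 25 px grid keeps forward models fast while exercising the same
# code paths as the full design.

toy_geom <- function() {
  bar_geometry("spatiotemporal", field_radius_deg = 6, bar_width_deg = 3,
               overlap_deg = 0.75, n_steps = 5L, grid_px = 25L)
}

toy_stim <- function(n_runs = 1L, seed = 1L) {
  geom <- toy_geom()
  assemble_run(geom, run_schedule(geom, n_runs = n_runs, seed = seed))
}

# an all-off toy sequence (every slot uses a custom blank profile)
toy_stim_blank <- function() {
  geom <- toy_geom()
  sched <- run_schedule(geom, n_runs = 1L, seed = 1L)
  st <- assemble_run(geom, sched)
  st$frame_ap[] <- 0L
  st$intervals <- st$intervals[0, ]
  st
}

# small solver grid for the toy field (full coarse tau grid: even toy
# problems need it to localize sluggish pRFs)
toy_grid <- function() {
  grid_spec(xy_step = 1, sigma_range = c(0.4, 4), sigma_steps = 10L)
}

fast_fine <- function() fine_spec(maxiter = c(30L, 12L, 12L))
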