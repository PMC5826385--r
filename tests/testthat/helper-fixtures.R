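# Shared fixtures, computed once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

fix_pulse <- function() {
  cached("pulse", generate_pulse(52, 9600, 6800, total_angle = 1.134))
}

fix_mesh <- function() cached("mesh", build_geometry("sagittal", target_edge = 6))

fix_material <- function() ogden_prony_material()

# six experiments with the published per-experiment peak kinematics
fix_experiments <- function() {
  cached("experiments", {
    tab <- sagittal_experiment_table()
    purrr::map(seq_len(nrow(tab)), function(i) {
      list(id = i,
           pulse = generate_pulse(tab$peak_velocity[i],
                                  tab$peak_accel[i] * 1000,
                                  tab$peak_decel[i] * 1000,
                                  total_angle = 65 * pi / 180))
    })
  })
}

fix_recovery_grid <- function() c(138.4, 346, 692, 1730)

# simulated per-pair maxima over the recovery grid (the expensive part,
# shared by the sweep/recovery/acceptance tests)
fix_sweep_dfem <- function() {
  cached("sweep_dfem", suppressWarnings(
    sweep_displacements(fix_recovery_grid(), fix_experiments(), fix_mesh(),
                        fix_material(), sim_config(seed = 1),
                        vein_variant = "post_cyclic")))
}

# a small tracked synthetic experiment (video pipeline end-to-end)
fix_tracked_experiment <- function(peak_rel_disp = 1.0, noise_sd = 0,
                                   seed = 4) {
  key <- sprintf("tracked_%g_%g_%d", peak_rel_disp, noise_sd, seed)
  cached(key, {
    pulse <- generate_pulse(52, 9600, 6800, total_angle = 0.7, dt = 1e-4)
    layout <- generate_layout(16, 8, "sagittal", seed = seed,
                              base_radius = 15, rigid_offset = 5)
    traj <- synthesize_trajectories(layout, pulse,
                                    lag_model(peak_rel_disp),
                                    noise_sd = noise_sd, seed = seed + 1,
                                    rotation_center = c(0, -25),
                                    lead_in = 0.02, hold = 0.01)
    stack <- rasterize_frames(traj, shape = c(240, 320))
    det <- segment_stack(stack)
    tracks <- filter_tracks(link_tracks(det, radius = 10), 0.9)
    center_px <- mm_to_px(matrix(c(0, 0), 1), stack)
    tracks <- label_tracks(tracks, center_px,
                           (attr(layout, "rigid_radius") - 2.5) * stack$px_per_mm)
    list(pulse = pulse, layout = layout, traj = traj, stack = stack,
         tracks = tracks)
  })
}
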