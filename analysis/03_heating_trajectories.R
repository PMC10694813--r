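#!/usr/bin/env Rscript
# Generate synthetic heating trajectories for a 50/50 binary crystal with an
# 80-molecule crack void, compute the NNO order parameter along the
# 248-348 K ramp and write the total-NNO-vs-temperature curves.
#
# The generator stands in for the MD engine: each molecule vibrates about
# its lattice site below its (staggered) personal onset and diffuses above
# it, so the curves show the crystalline baseline followed by the gradual
# NNO collapse that real heating runs show.

suppressPackageStartupMessages(library(tagmelt))

out_dir <- "results/trajectories"      # curves and config
traj_dir <- "scratch/trajectories"     # bulky per-frame coordinates
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
dir.create(traj_dir, showWarnings = FALSE, recursive = TRUE)
cfg <- run_config(seed = 60L)
write_run_config(cfg, file.path(out_dir, "config.json"))
ramp <- temperature_ramp(cfg$ramp[1], cfg$ramp[2], cfg$ramp[3])

# desk-scale system: 5 x 2 x 5 cells (200 molecules) with a 16-molecule void
crystal <- build_crystal(default_unit_cell(), c(5L, 2L, 5L))
mix <- substitute_random(crystal, default_species_set()$POST, 0.5,
                         seed = cfg$seed)
cracked <- carve_crack_void(mix, 16L, tolerance = cfg$tolerance,
                            seed = cfg$seed + 1L)
message("system: ", n_molecules(cracked), " molecules after void")

n_reps <- 5L
for (rep in seq_len(n_reps)) {
  sc <- melt_scenario(onset_temperature = 30, seed = cfg$seed + 10L * rep)
  traj <- gen_crystal_trajectory(cracked, ramp, sc, n_frames = cfg$n_frames)
  write_trajectory_txt(traj, file.path(traj_dir, sprintf("run%02d.traj", rep)),
                       config = cfg)
  series <- compute_nno(traj, cutoff = cfg$cutoff)
  curve <- total_nno_curve(series, ramp)
  write_curve_csv(curve, file.path(out_dir, sprintf("run%02d_curve.csv", rep)),
                  config = cfg)
  message(sprintf("run %d: baseline total NNO %d, final %d", rep,
                  curve$total_nno[2], curve$total_nno[nrow(curve)]))
}
message("wrote ", n_reps, " trajectories and total-NNO curves to ", out_dir)
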