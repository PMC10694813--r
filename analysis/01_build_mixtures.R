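#!/usr/bin/env Rscript
# Build the canonical 800-molecule supercell and the binary mixtures.
#
# Starting from a perfect single-TAG crystal of the larger molecule
# (sn-StOSt), molecules are replaced at random to reach 10-90% of the
# replacing TAG in steps of 10%; each mixture gets its own seed so no two
# binary crystals are identical.  Writes the mixtures as GRO files plus a
# composition table.

suppressPackageStartupMessages(library(tagmelt))

out_dir <- "results/mixtures"          # tables and config
gro_dir <- "scratch/mixtures"          # bulky coordinate files
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
dir.create(gro_dir, showWarnings = FALSE, recursive = TRUE)
cfg <- run_config(seed = 20L)
write_run_config(cfg, file.path(out_dir, "config.json"))

crystal <- build_crystal(default_unit_cell(), c(10L, 2L, 10L))
message("built ", n_molecules(crystal), " molecule sn-StOSt supercell, box ",
        paste(sprintf("%.1f", crystal$box), collapse = " x "), " nm")
write_gro(crystal, file.path(gro_dir, "stost_pure.gro"),
          title = paste("sn-StOSt 10x2x10 supercell | config", config_hash(cfg)))

post <- default_species_set()$POST
rows <- lapply(seq_along(cfg$ratio_grid), function(i) {
  frac <- cfg$ratio_grid[i]
  mix <- substitute_random(crystal, post, frac, seed = cfg$seed + i)
  comp <- composition(mix)
  file <- sprintf("post_stost_%02d_%02d.gro", round(100 * frac),
                  round(100 * (1 - frac)))
  write_gro(mix, file.path(gro_dir, file),
            title = sprintf("sn-POSt/sn-StOSt %d/%d | seed %d | config %s",
                            round(100 * frac), round(100 * (1 - frac)),
                            cfg$seed + i, config_hash(cfg)))
  data.frame(file = file, fraction_post = frac,
             n_post = unname(comp["POST"]), n_stost = unname(comp["STOST"]),
             seed = cfg$seed + i)
})
tab <- do.call(rbind, rows)
write.csv(tab, file.path(out_dir, "compositions.csv"), row.names = FALSE)
message("wrote ", nrow(tab), " binary mixtures; POST counts: ",
        paste(tab$n_post, collapse = ", "))
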