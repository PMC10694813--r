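test_that("trajectory generation is bit-reproducible and respects its preconditions", {
  cracked <- carve_crack_void(small_binary(0.5), 20, seed = 3)
  ramp <- temperature_ramp()
  sc <- melt_scenario(onset_temperature = 30, seed = 11)
  t1 <- gen_crystal_trajectory(cracked, ramp, sc, n_frames = 40)
  t2 <- gen_crystal_trajectory(cracked, ramp, sc, n_frames = 40)
  expect_identical(t1, t2)
  expect_equal(t1$metadata$true_onset_C, 30)
  expect_equal(length(t1$metadata$molecule_onsets_C), n_molecules(cracked))

  expect_error(melt_scenario(vibration_sigma = 0.4, melt_diffusion = 0.3),
               class = "tagmelt_invalid_argument")
  expect_error(gen_crystal_trajectory(cracked, ramp, sc, n_frames = 5),
               class = "tagmelt_invalid_argument")
})

test_that("a never-melting rigid scenario yields identical frames and constant NNO", {
  crys <- small_crystal(c(3, 2, 3))
  ramp <- temperature_ramp()
  sc <- melt_scenario(onset_temperature = 500, vibration_sigma = 0,
                      melt_diffusion = 0.3, stagger_width = 0, seed = 2)
  traj <- gen_crystal_trajectory(crys, ramp, sc, n_frames = 15)
  for (f in 2:15) expect_equal(traj$positions[[f]], traj$positions[[1]])
  series <- compute_nno(traj)
  expect_true(all(series == series[, 1]))
})

test_that("the default melt scenario is recovered by onset detection within 2 degrees", {
  cracked <- carve_crack_void(small_binary(0.5), 20, seed = 3)
  ramp <- temperature_ramp()
  traj <- gen_crystal_trajectory(cracked, ramp, melt_scenario(seed = 11),
                                 n_frames = 200)
  res <- detect_onset(total_nno_curve(compute_nno(traj), ramp))
  expect_true(res$found)
  expect_lt(abs(res$onset_temperature_C - 30), 2)
})

test_that("molecules melt in order of their staggered personal onsets", {
  cracked <- carve_crack_void(small_binary(0.5), 20, seed = 3)
  ramp <- temperature_ramp()
  sc <- melt_scenario(onset_temperature = 25, stagger_width = 10, seed = 4)
  traj <- gen_crystal_trajectory(cracked, ramp, sc, n_frames = 100)
  onsets <- traj$metadata$molecule_onsets_C
  expect_true(all(abs(onsets - 25) <= 5 + 1e-12))
  # at mid-melt, molecules past their onset have moved off their lattice site
  sites <- central_beads(cracked)
  f <- which.min(abs(ramp_temperature(ramp, traj$times) - 273.15 - 25))
  tempC <- ramp_temperature(ramp, traj$times[f]) - 273.15
  molten <- onsets <= tempC - 2
  frozen <- onsets > tempC + 2
  dd <- traj$positions[[f]] - sites
  dd <- dd - sweep(round(sweep(dd, 2, cracked$box, "/")), 2, cracked$box, "*")
  d <- sqrt(rowSums(dd^2))
  expect_gt(median(d[molten]), median(d[frozen]))
})

test_that("noiseless synthetic melting curves are recovered exactly by both rules", {
  for (pv in c(32L, 48L, 56L)) {
    for (cv in c(64L, 72L)) {
      if (cv <= pv) next
      crv <- gen_melting_curve(plateau_void = pv, plateau_T = 27,
                               collapse_void = cv, noise_sigma = 0, seed = 1)
      expect_equal(detect_plateau(crv)$chosen_void_size, pv)
      expect_equal(detect_plateau(crv)$melting_point, 27)
      expect_equal(detect_collapse(crv), match(cv, crv$void_size))
    }
  }
})

test_that("plateau recovery survives small curve noise", {
  hits <- vapply(1:20, function(seed) {
    crv <- gen_melting_curve(plateau_void = 48, collapse_void = 72,
                             noise_sigma = 0.02, seed = seed)
    detect_plateau(crv)$chosen_void_size == 48L
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("shifting the plateau temperature shifts the recovered melting point", {
  base <- gen_melting_curve(plateau_void = 48, plateau_T = 27,
                            collapse_void = 72, noise_sigma = 0, seed = 1)
  up <- gen_melting_curve(plateau_void = 48, plateau_T = 32,
                          collapse_void = 72, noise_sigma = 0, seed = 1)
  expect_equal(detect_plateau(up)$melting_point,
               detect_plateau(base)$melting_point + 5)
})

test_that("melting-curve generation enforces its void-grid preconditions", {
  expect_error(gen_melting_curve(plateau_void = 30, collapse_void = 72),
               class = "tagmelt_invalid_argument")
  expect_error(gen_melting_curve(plateau_void = 48, collapse_void = 48),
               class = "tagmelt_invalid_argument")
  expect_error(gen_melting_curve(plateau_void = 16, collapse_void = 72),
               class = "tagmelt_invalid_argument")
  expect_error(gen_melting_curve(plateau_void = 48, collapse_void = 80),
               class = "tagmelt_invalid_argument")
})
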