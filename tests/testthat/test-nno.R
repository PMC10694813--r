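test_that("the linear ramp maps time to temperature and reproduces the heating rate", {
  ramp <- temperature_ramp(248, 348, 200)
  expect_equal(ramp_temperature(ramp, 0), 248)
  expect_equal(ramp_temperature(ramp, 200), 348)
  expect_equal(ramp_temperature(ramp, 100), 298)
  expect_equal(heating_rate(ramp), 0.5)
  expect_error(temperature_ramp(348, 248, 200), class = "tagmelt_invalid_argument")
  expect_error(temperature_ramp(248, 348, 0), class = "tagmelt_invalid_argument")
})

test_that("neighbor sets respect the cutoff and the minimum-image convention", {
  box <- c(10, 10, 10)
  # two molecules 1.1 nm apart: neighbors at 1.2 nm cutoff; 1.3 nm: not
  pos <- rbind(c(1, 1, 1), c(2.1, 1, 1))
  expect_equal(neighbor_sets(pos, box, 1.2), list(2L, 1L))
  pos2 <- rbind(c(1, 1, 1), c(2.3, 1, 1))
  expect_equal(neighbor_sets(pos2, box, 1.2), list(integer(0), integer(0)))
  # across the periodic boundary: 0.2 + 0.3 nm through the wall
  pos3 <- rbind(c(0.2, 5, 5), c(9.7, 5, 5))
  expect_equal(neighbor_sets(pos3, box, 1.2), list(2L, 1L))
  # single molecule: empty set
  expect_equal(neighbor_sets(matrix(c(1, 1, 1), 1), box, 1.2),
               list(integer(0)))
  expect_error(neighbor_sets(pos, box, 5), class = "tagmelt_invalid_argument")
  expect_error(neighbor_sets(pos, box, 0), class = "tagmelt_invalid_argument")
})

test_that("cell-list and brute-force searches match an independent all-pairs oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    box <- c(4, 3.5, 5)
    pos <- cbind(runif(50, 0, box[1]), runif(50, 0, box[2]), runif(50, 0, box[3]))
    expected <- oracle_neighbor_sets(pos, box, 1.2)
    cell <- neighbor_sets(pos, box, 1.2, method = "cell")
    brute <- neighbor_sets(pos, box, 1.2, method = "brute")
    expect_identical(cell, expected)
    expect_identical(brute, expected)
    # symmetry: j in N(i) <=> i in N(j)
    for (i in seq_along(cell)) {
      for (j in cell[[i]]) expect_true(i %in% cell[[j]])
    }
  }
})

test_that("NNO equals the per-frame set-intersection oracle and stays in range", {
  crys <- small_binary(0.5)
  cracked <- carve_crack_void(crys, 20, seed = 3)
  ramp <- temperature_ramp()
  traj <- gen_crystal_trajectory(cracked, ramp,
                                 melt_scenario(onset_temperature = 20, seed = 7),
                                 n_frames = 12)
  for (mode in c("consecutive", "reference")) {
    series <- compute_nno(traj, cutoff = 1.2, mode = mode)
    expect_identical(unclass(series)[, ], oracle_nno(traj, 1.2, mode))
    expect_true(all(series >= 0 & series <= n_molecules(cracked) - 1L))
  }
})

test_that("identical frames give constant NNO equal to the full neighbor count", {
  crys <- small_crystal(c(3, 2, 3))
  pos <- central_beads(crys)
  traj <- tag_trajectory(times = 0:9 * 10, positions = rep(list(pos), 10),
                         box = crys$box, ramp = temperature_ramp())
  series <- compute_nno(traj)
  n0 <- lengths(neighbor_sets(pos, crys$box, 1.2))
  for (f in 1:10) expect_equal(series[, f], n0)
})

test_that("independently re-randomized sparse frames have near-zero mean NNO", {
  # 40 molecules in a 20^3 box: P(two within 1.2 nm) ~ 7.2e-4 per pair, so
  # the expected persistent-neighbor count per molecule is ~ 39 * 7.2e-4^2
  set.seed(99)
  box <- c(20, 20, 20)
  frames <- lapply(1:30, function(f) matrix(runif(120, 0, 20), ncol = 3))
  traj <- tag_trajectory(1:30, frames, box, temperature_ramp())
  series <- compute_nno(traj)
  expect_lt(mean(series[, -1]), 0.01)
})

test_that("rigid translation of a frame (mod box) leaves neighbor sets unchanged", {
  crys <- small_binary(0.5)
  pos <- central_beads(crys)
  base <- neighbor_sets(pos, crys$box, 1.2)
  for (shift in list(c(0.37, 0, 0), c(1.4, -2.2, 0.9), crys$box * 0.5)) {
    moved <- sweep(pos, 2, shift, "+")
    expect_identical(neighbor_sets(moved, crys$box, 1.2), base)
  }
})

test_that("NNO never increases when neighbor pairs are deleted from a frame", {
  # moving one molecule far away can only remove pairs involving it
  crys <- small_crystal(c(3, 2, 3))
  pos <- central_beads(crys)
  pos2 <- pos
  pos2[5, ] <- pos[5, ] + c(0, 0, 1.9)       # exits every 1.2 nm neighborhood
  traj <- tag_trajectory(c(0, 1), list(pos, pos2), crys$box, temperature_ramp())
  series <- compute_nno(traj)
  expect_true(all(series[, 2] <= series[, 1]))
})

test_that("the total-NNO curve sums molecules per frame and converts the ramp to Celsius", {
  crys <- small_binary(0.5)
  ramp <- temperature_ramp()
  traj <- gen_crystal_trajectory(crys, ramp, melt_scenario(seed = 5),
                                 n_frames = 11)
  series <- compute_nno(traj)
  curve <- total_nno_curve(series, ramp)
  expect_equal(nrow(curve), 11L)
  expect_equal(curve$total_nno, unname(colSums(series)))
  expect_equal(curve$temperature_K[1], 248)
  expect_equal(curve$temperature_K[11], 348)
  expect_equal(curve$temperature_C, curve$temperature_K - 273.15)
})

test_that("trajectory containers reject inconsistent input", {
  pos <- matrix(runif(30), ncol = 3)
  ramp <- temperature_ramp()
  expect_error(tag_trajectory(c(0, 0), list(pos, pos), c(5, 5, 5), ramp),
               class = "tagmelt_format_error")
  expect_error(tag_trajectory(c(0, 1), list(pos, pos[1:5, ]), c(5, 5, 5), ramp),
               class = "tagmelt_format_error")
  traj <- tag_trajectory(0, list(pos), c(5, 5, 5), ramp)
  expect_error(compute_nno(traj), class = "tagmelt_invalid_argument")
})
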