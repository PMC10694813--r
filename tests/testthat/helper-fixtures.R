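# Shared fixtures: small crystals and trajectories so individual tests stay
# fast; the full-scale grids live in test-acceptance.R.

small_crystal <- function(reps = c(5L, 2L, 5L),
                          species = default_species_set()$STOST) {
  build_crystal(default_unit_cell(species), reps)
}

small_binary <- function(fraction = 0.5, seed = 2L, reps = c(5L, 2L, 5L)) {
  substitute_random(small_crystal(reps), default_species_set()$POST,
                    fraction, seed = seed)
}

# Brute-force neighbor oracle, independent of the package's search paths:
# plain double loop over all pairs with explicit minimum-image arithmetic.
oracle_neighbor_sets <- function(pos, box, cutoff) {
  n <- nrow(pos)
  adj <- rep(list(integer(0L)), n)
  if (n < 2L) return(adj)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- pos[i, ] - pos[j, ]
      d <- d - box * round(d / box)
      if (sum(d^2) <= cutoff^2) {
        adj[[i]] <- c(adj[[i]], j)
        adj[[j]] <- c(adj[[j]], i)
      }
    }
  }
  lapply(adj, sort)
}

# Independent NNO oracle on top of the neighbor oracle.
oracle_nno <- function(traj, cutoff, mode = "consecutive") {
  nf <- length(traj$times)
  n <- nrow(traj$positions[[1L]])
  adj <- lapply(seq_len(nf), function(f) {
    oracle_neighbor_sets(traj$positions[[f]], traj$box[[f]], cutoff)
  })
  out <- matrix(0L, n, nf)
  out[, 1L] <- lengths(adj[[1L]])
  for (f in 2:nf) {
    base <- if (mode == "consecutive") adj[[f - 1L]] else adj[[1L]]
    out[, f] <- vapply(seq_len(n), function(i) {
      length(intersect(adj[[f]][[i]], base[[i]]))
    }, integer(1L))
  }
  out
}

# A quick synthetic total-NNO curve: flat baseline then linear decline.
step_curve <- function(n = 200L, t_star = 30, base = 4000, sigma = 30,
                       slope = 50, t_range = c(0, 60), seed = 1L) {
  tc <- seq(t_range[1L], t_range[2L], length.out = n)
  set.seed(seed)
  data.frame(temperature_C = tc,
             total_nno = base + rnorm(n, 0, sigma) - slope * pmax(tc - t_star, 0))
}

extdata <- function(file) {
  system.file("extdata", file, package = "tagmelt", mustWork = TRUE)
}
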