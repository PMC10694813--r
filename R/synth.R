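#' Synthetic melting scenario
#'
#' Parameters of the synthetic heating trajectory generator.  Below its
#' personal onset a molecule vibrates about its lattice site with Gaussian
#' amplitude `vibration_sigma`; above it, it abandons the site and performs
#' a random walk with per-frame step `melt_diffusion`.  Personal onsets are
#' staggered uniformly over `stagger_width` around `onset_temperature`,
#' reproducing the gradual, molecule-by-molecule melting seen in heating
#' trajectories (a width of 0 gives a sharp transition).
#'
#' @param onset_temperature System melting onset (degrees C).
#' @param vibration_sigma Crystalline positional noise (nm), >= 0.  Default
#'   0.05 nm, small against the 0.8 nm lattice spacing.
#' @param melt_diffusion Per-frame random-walk step in the melt (nm); must
#'   exceed `vibration_sigma`, otherwise melting would be indistinguishable
#'   from vibration.  Default 0.3 nm.
#' @param stagger_width Spread of per-molecule onsets (degrees C, default 2).
#' @param seed Integer seed; one generator drives all randomness of a run.
#' @return A `melt_scenario` list.
#' @export
melt_scenario <- function(onset_temperature = 30, vibration_sigma = 0.05,
                          melt_diffusion = 0.3, stagger_width = 2,
                          seed = 11L) {
  if (!is.finite(onset_temperature) || vibration_sigma < 0 || stagger_width < 0) {
    stop_invalid("onset must be finite; vibration_sigma and stagger_width >= 0")
  }
  if (melt_diffusion <= vibration_sigma) {
    stop_invalid("`melt_diffusion` must exceed `vibration_sigma` ",
                 "(melting would be indistinguishable from vibration)")
  }
  structure(list(onset_temperature = onset_temperature,
                 vibration_sigma = vibration_sigma,
                 melt_diffusion = melt_diffusion,
                 stagger_width = stagger_width,
                 seed = as.integer(seed)),
            class = "melt_scenario")
}

#' Generate a synthetic heating trajectory for a crystal
#'
#' Emulates the central-bead trajectory of a crystal under a linear
#' temperature ramp, with known ground truth in place of a molecular
#' dynamics engine.  Each molecule draws a personal onset uniformly from
#' `onset_temperature +/- stagger_width / 2`; while the ramp temperature is
#' below it the molecule's central bead is its lattice position plus fresh
#' Gaussian jitter (`vibration_sigma`), and above it the bead performs a
#' Gaussian random walk (`melt_diffusion` per frame and axis) with periodic
#' wrapping, so its neighbor set decorrelates and the NNO collapses.  The
#' run is bit-reproducible from the scenario seed; the true onset is stored
#' in the trajectory metadata.
#'
#' @param crystal A `crystal_system` (typically after [carve_crack_void()]).
#' @param ramp A [temperature_ramp].
#' @param scenario A [melt_scenario].
#' @param n_frames Number of evenly spaced frames (>= 10; default 200).
#' @return A [tag_trajectory]; `metadata$true_onset_C` holds the scenario
#'   onset and `metadata$molecule_onsets_C` the per-molecule onsets.
#' @examples
#' crys <- build_crystal(default_unit_cell(), c(5, 2, 5))
#' traj <- gen_crystal_trajectory(crys, temperature_ramp(),
#'                                melt_scenario(seed = 11), n_frames = 50)
#' @export
gen_crystal_trajectory <- function(crystal, ramp, scenario,
                                   n_frames = 200L) {
  stopifnot(inherits(crystal, "crystal_system"),
            inherits(ramp, "temperature_ramp"),
            inherits(scenario, "melt_scenario"))
  n_frames <- as.integer(n_frames)
  if (is.na(n_frames) || n_frames < 10L) stop_invalid("`n_frames` must be >= 10")
  sites <- central_beads(crystal)
  n <- nrow(sites)
  box <- crystal$box
  times <- seq(0, ramp$duration, length.out = n_frames)
  temps_C <- kelvin_to_celsius(ramp_temperature(ramp, times))

  with_seed(scenario$seed, {
    onsets <- scenario$onset_temperature +
      stats::runif(n, -0.5, 0.5) * scenario$stagger_width
    pos <- sites
    frames <- vector("list", n_frames)
    for (f in seq_len(n_frames)) {
      molten <- temps_C[f] >= onsets
      cur <- pos
      if (any(!molten)) {
        k <- sum(!molten)
        cur[!molten, ] <- sites[!molten, , drop = FALSE] +
          matrix(stats::rnorm(3L * k, sd = scenario$vibration_sigma), k, 3L)
      }
      if (any(molten)) {
        k <- sum(molten)
        cur[molten, ] <- pos[molten, , drop = FALSE] +
          matrix(stats::rnorm(3L * k, sd = scenario$melt_diffusion), k, 3L)
      }
      cur <- wrap_coords(cur, box)
      frames[[f]] <- cur
      # molten molecules continue their walk from the current position;
      # crystalline ones keep referencing the lattice site
      pos[molten, ] <- cur[molten, , drop = FALSE]
    }
    tag_trajectory(times, frames, box, ramp, ids = crystal$id,
                   metadata = list(true_onset_C = scenario$onset_temperature,
                                   molecule_onsets_C = onsets,
                                   scenario = scenario))
  })
}

#' Generate a synthetic melting-vs-void-size curve
#'
#' Constructs a curve with the shape the void-size scan produces: onsets
#' fall with increasing void size in steps of geometrically decreasing
#' magnitude until the plateau void, drift down gently across the plateau
#' (default 0.2 degrees C per step), then drop sharply after the collapse
#' void.  The pre-plateau differences decay to half the plateau drift, so
#' the first *increase* in successive differences — the plateau rule's
#' trigger — lands exactly on `plateau_void`, and the terminal drop is the
#' collapse signature.  Gaussian noise is added on top; the noiseless curve
#' and the true plateau/collapse voids are stored as attributes.
#'
#' @param plateau_void Void size where the curve plateaus; on the
#'   `{16..80 step 8}` grid, at least the second grid point.
#' @param plateau_T Onset at the plateau (degrees C).
#' @param pre_slope Initial drop per void step before the plateau
#'   (degrees C, default 1.5).
#' @param collapse_void Void size after which the collapse drop occurs; on
#'   the grid, greater than `plateau_void` and before the last grid point.
#' @param collapse_drop Collapse magnitude (degrees C, default 5).
#' @param noise_sigma Gaussian noise per point (degrees C, default 0.3).
#' @param seed Integer seed.
#' @param void_grid Void-size grid (default `seq(16, 80, 8)`).
#' @param plateau_drift Downward drift per step across the plateau
#'   (degrees C, default 0.2).
#' @return A [melting_curve]; attributes `truth` (plateau/collapse voids,
#'   plateau temperature) and `noiseless` (the clean curve).
#' @examples
#' crv <- gen_melting_curve(plateau_void = 56, plateau_T = 27,
#'                          collapse_void = 72, noise_sigma = 0, seed = 1)
#' detect_plateau(crv)$chosen_void_size   # 56
#' @export
gen_melting_curve <- function(plateau_void, plateau_T = 27, pre_slope = 1.5,
                              collapse_void = 72, collapse_drop = 5,
                              noise_sigma = 0.3, seed = 1L,
                              void_grid = seq(16L, 80L, by = 8L),
                              plateau_drift = 0.2) {
  void_grid <- as.integer(void_grid)
  plateau_void <- as.integer(plateau_void)
  collapse_void <- as.integer(collapse_void)
  ip <- match(plateau_void, void_grid)
  ic <- match(collapse_void, void_grid)
  if (is.na(ip) || is.na(ic)) {
    stop_invalid("plateau_void and collapse_void must lie on the void grid {",
                 paste(void_grid, collapse = ", "), "}")
  }
  if (ip < 2L) stop_invalid("plateau_void must leave at least one pre-plateau step")
  if (ic <= ip || ic >= length(void_grid)) {
    stop_invalid("need plateau_void < collapse_void < ", void_grid[length(void_grid)])
  }
  if (pre_slope <= plateau_drift / 2 || plateau_drift <= 0 || collapse_drop <= 0) {
    stop_invalid("need pre_slope > plateau_drift/2 and positive drift/drop")
  }
  p <- length(void_grid)
  # successive drops d_j (from point j to j+1)
  n_pre <- ip - 1L
  d_pre <- if (n_pre == 1L) plateau_drift / 2 else {
    pre_slope * (plateau_drift / (2 * pre_slope))^((seq_len(n_pre) - 1L) / (n_pre - 1L))
  }
  d <- c(d_pre,                                   # approach, decaying drops
         rep(plateau_drift, ic - ip),             # plateau drift
         collapse_drop + plateau_drift,           # collapse step
         rep(plateau_drift, p - ic - 1L))
  clean <- plateau_T + sum(d_pre) - cumsum(c(0, d))
  noisy <- if (noise_sigma > 0) {
    clean + with_seed(seed, stats::rnorm(p, sd = noise_sigma))
  } else clean
  out <- melting_curve(void_grid, noisy)
  attr(out, "truth") <- list(plateau_void = plateau_void,
                             plateau_T = plateau_T,
                             collapse_void = collapse_void)
  attr(out, "noiseless") <- clean
  out
}
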