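#' Carve a planar "crack" void from a crystal
#'
#' Removes `void_size` molecules lying nearest to a randomly positioned,
#' randomly oriented plane through the crystal, producing the planar crack
#' defect that lowers the melting nucleation barrier and prevents
#' superheating in direct-heating simulations.  For binary crystals the TAG
#' ratio of the survivors is kept within an absolute tolerance of the
#' pre-void ratio (default +/-1.5 percentage points): after the initial
#' nearest-to-plane selection, molecules at the slab boundary are swapped
#' between the removed and kept sets until the constraint holds.  If no
#' removal of `void_size` molecules can satisfy the tolerance, a
#' constraint-failure error is signalled rather than silently clipping.
#'
#' @param crystal A single-species or binary `crystal_system`.
#' @param void_size Number of molecules to remove (0 <= void_size < N).
#' @param tolerance Absolute tolerance on the surviving species percentage,
#'   in percentage points (default 1.5).
#' @param seed Integer seed controlling plane position and orientation; the
#'   same seed reproduces the same void.
#' @return A `crystal_system` with `N - void_size` molecules; survivors keep
#'   their ids and coordinates bit-exactly.  The carve geometry (plane point,
#'   normal, removed ids) is recorded in the `"void"` attribute.
#' @examples
#' crys <- build_crystal(default_unit_cell(), c(10, 2, 10))
#' mix <- substitute_random(crys, default_species_set()$POST, 0.1, seed = 1)
#' cracked <- carve_crack_void(mix, void_size = 56, seed = 3)
#' n_molecules(cracked)   # 744
#' @export
carve_crack_void <- function(crystal, void_size, tolerance = 1.5, seed = 1L) {
  stopifnot(inherits(crystal, "crystal_system"))
  void_size <- as.integer(void_size)
  n <- n_molecules(crystal)
  if (length(void_size) != 1L || is.na(void_size) || void_size < 0L ||
      void_size >= n) {
    stop_invalid("`void_size` must satisfy 0 <= void_size < ", n)
  }
  if (!is.numeric(tolerance) || length(tolerance) != 1L || tolerance < 0) {
    stop_invalid("`tolerance` must be >= 0")
  }
  if (void_size == 0L) return(crystal)
  species <- unique(crystal$species)
  if (length(species) > 2L) {
    stop_invalid("crack voids are defined for single-species or binary crystals")
  }

  pos <- central_beads(crystal)
  plane <- with_seed(seed, {
    point <- runif(3L) * crystal$box
    v <- stats::rnorm(3L)
    list(point = point, normal = v / sqrt(sum(v^2)))
  })
  # distance of each central bead to the (periodically wrapped) crack plane
  disp <- minimum_image(sweep(pos, 2L, plane$point, "-"), crystal$box)
  dist_plane <- abs(drop(disp %*% plane$normal))

  removed <- order(dist_plane)[seq_len(void_size)]

  if (length(species) == 2L) {
    # repair the ratio of species B among survivors, if needed
    comp <- composition(crystal)
    sp_b <- names(comp)[2L]
    is_b <- crystal$species == sp_b
    n_b <- sum(is_b)
    surv <- n - void_size
    p0 <- 100 * n_b / n
    k_lo <- max(ceiling(surv * (p0 - tolerance) / 100 - 1e-9), n_b - void_size, 0)
    k_hi <- min(floor(surv * (p0 + tolerance) / 100 + 1e-9), n_b)
    if (k_lo > k_hi) {
      stop_constraint("void of ", void_size, " molecules cannot keep the ",
                      sp_b, " percentage within +/-", tolerance,
                      " points of ", round(p0, 2), "%")
    }
    in_removed <- rep(FALSE, n); in_removed[removed] <- TRUE
    k <- n_b - sum(is_b & in_removed)      # surviving B count
    while (k < k_lo || k > k_hi) {
      if (k < k_lo) {
        # too many B removed: return the outermost removed B,
        # take the innermost kept A instead
        back <- which(in_removed & is_b)
        out  <- which(!in_removed & !is_b)
      } else {
        back <- which(in_removed & !is_b)
        out  <- which(!in_removed & is_b)
      }
      back <- back[which.max(dist_plane[back])]
      out  <- out[which.min(dist_plane[out])]
      in_removed[back] <- FALSE
      in_removed[out] <- TRUE
      k <- n_b - sum(is_b & in_removed)
    }
    removed <- which(in_removed)
  }

  keep <- setdiff(seq_len(n), removed)
  out <- crystal
  out$id <- crystal$id[keep]
  out$species <- crystal$species[keep]
  out$anchor <- crystal$anchor[keep, , drop = FALSE]
  attr(out, "void") <- list(void_size = void_size, seed = seed,
                            plane_point = plane$point,
                            plane_normal = plane$normal,
                            removed_ids = crystal$id[removed])
  out
}

#' Minor-species percentage of a crystal
#'
#' Percentage of the less abundant species among all molecules.  For a
#' single-species crystal this is 0; for an exactly 50/50 binary it is 50.
#'
#' @param crystal A `crystal_system`.
#' @return Percentage in `[0, 50]`.
#' @export
minor_species_percentage <- function(crystal) {
  comp <- composition(crystal)
  comp <- comp[comp > 0]
  if (length(comp) == 1L) return(0)
  100 * min(comp) / sum(comp)
}
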