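#' Unit-cell template for supercell construction
#'
#' A unit cell is described by three lattice vectors (nm) and a list of
#' molecule placements, each an anchor offset (nm) inside the cell plus the
#' TAG species occupying that slot.  Supercells are built by stacking copies
#' of the cell along the three lattice directions.
#'
#' @param lattice_vectors 3 x 3 numeric matrix; rows are the a, b, c lattice
#'   vectors in nm.  Must be linearly independent.
#' @param placements List of placements, each a list with elements `species`
#'   (a [tag_species]) and `offset` (length-3 numeric, nm).
#' @return An object of class `unit_cell_template`.
#' @seealso [default_unit_cell()], [build_crystal()]
#' @export
unit_cell_template <- function(lattice_vectors, placements) {
  lattice_vectors <- as.matrix(lattice_vectors)
  if (!identical(dim(lattice_vectors), c(3L, 3L)) ||
      !all(is.finite(lattice_vectors))) {
    stop_invalid("`lattice_vectors` must be a finite 3x3 matrix (rows a, b, c in nm)")
  }
  if (abs(det(lattice_vectors)) < 1e-12) {
    stop_invalid("lattice vectors must be linearly independent")
  }
  if (!is.list(placements) || length(placements) < 1L) {
    stop_invalid("`placements` must be a non-empty list")
  }
  for (p in placements) {
    if (!is.list(p) || !inherits(p$species, "tag_species") ||
        length(p$offset) != 3L || !all(is.finite(p$offset))) {
      stop_invalid("each placement needs a `species` (tag_species) and a length-3 `offset`")
    }
  }
  structure(list(lattice_vectors = lattice_vectors, placements = placements),
            class = "unit_cell_template")
}

#' Idealized TAG unit cell
#'
#' An idealized rectangular cell holding four TAG molecules per cell, chains
#' running along c.  Molecules sit on a square 0.8 nm grid in the a-b plane,
#' so nearest central-bead spacings (0.8 and 1.13 nm) fall inside the 1.2 nm
#' neighbor cutoff and every interior molecule has eight in-plane neighbors.
#' The geometry is a stand-in for the experimentally refined beta-2 packing,
#' chosen to preserve the topology that the analysis depends on (a dense,
#' persistent neighbor graph below melting) rather than crystallographic
#' accuracy.
#'
#' @param species [tag_species] occupying all four slots (default sn-StOSt,
#'   the largest of the three cocoa-butter TAGs, matching the convention of
#'   starting every binary mixture from a perfect crystal of the larger
#'   molecule).
#' @return A [unit_cell_template] with 4 placements.
#' @examples
#' cell <- default_unit_cell()
#' crystal <- build_crystal(cell, c(10, 2, 10))  # 800 molecules
#' @export
default_unit_cell <- function(species = default_species_set()$STOST) {
  lv <- diag(c(1.6, 1.6, 4.0))
  offs <- list(c(0, 0, 0), c(0.8, 0, 0), c(0, 0.8, 0), c(0.8, 0.8, 0))
  unit_cell_template(lv, lapply(offs, function(o) list(species = species, offset = o)))
}

#' Build a single-TAG supercell
#'
#' Stacks `reps[1] * reps[2] * reps[3]` copies of the unit cell along its
#' lattice vectors.  The canonical system is an 800-molecule crystal obtained
#' by stacking 10, 2 and 10 cells of the 4-molecule default cell in the a, b
#' and c directions.
#'
#' @param template A [unit_cell_template].
#' @param reps Integer vector of length 3: repetitions along a, b, c (all
#'   >= 1).
#' @return A `crystal_system`: molecule ids, species labels, lattice anchors
#'   (wrapped into the periodic box) and box vectors.
#' @examples
#' crystal <- build_crystal(default_unit_cell(), c(10, 2, 10))
#' n_molecules(crystal)   # 800
#' @export
build_crystal <- function(template, reps) {
  stopifnot(inherits(template, "unit_cell_template"))
  reps <- as.integer(reps)
  if (length(reps) != 3L || any(is.na(reps)) || any(reps < 1L)) {
    stop_invalid("`reps` must be three integers >= 1")
  }
  lv <- template$lattice_vectors
  if (any(abs(lv[upper.tri(lv) | lower.tri(lv)]) > 1e-12)) {
    stop_invalid("only rectangular (diagonal) lattice vectors are supported")
  }
  box <- diag(lv) * reps
  cells <- as.matrix(expand.grid(a = seq_len(reps[1L]) - 1L,
                                 b = seq_len(reps[2L]) - 1L,
                                 c = seq_len(reps[3L]) - 1L))
  shifts <- cells %*% lv                       # one row per cell copy
  n_pl <- length(template$placements)
  anchors <- matrix(0, nrow = nrow(shifts) * n_pl, ncol = 3L)
  species <- character(nrow(anchors))
  species_set <- list()
  for (p in seq_len(n_pl)) {
    pl <- template$placements[[p]]
    rows <- seq(p, nrow(anchors), by = n_pl)
    anchors[rows, ] <- sweep(shifts, 2L, pl$offset, "+")
    species[rows] <- pl$species$name
    species_set[[pl$species$name]] <- pl$species
  }
  new_crystal(species = species, anchor = wrap_coords(anchors, box),
              box = box, species_set = species_set)
}

new_crystal <- function(species, anchor, box, species_set) {
  structure(
    list(id = seq_along(species) - 1L,    # 0-based internal ids
         species = species,
         anchor = anchor,
         box = box,
         species_set = species_set),
    class = "crystal_system"
  )
}

#' @export
print.crystal_system <- function(x, ...) {
  comp <- composition(x)
  cat(sprintf("<crystal_system> %d molecules, box %.2f x %.2f x %.2f nm\n",
              n_molecules(x), x$box[1L], x$box[2L], x$box[3L]))
  cat("  composition:",
      paste(sprintf("%s=%d (%.1f%%)", names(comp), comp,
                    100 * comp / sum(comp)), collapse = ", "), "\n")
  invisible(x)
}

#' Number of molecules in a crystal
#' @param crystal A `crystal_system`.
#' @return Integer count.
#' @export
n_molecules <- function(crystal) {
  stopifnot(inherits(crystal, "crystal_system"))
  length(crystal$species)
}

#' Composition tally of a crystal
#' @param crystal A `crystal_system`.
#' @return Named integer vector of molecule counts per species.
#' @export
composition <- function(crystal) {
  stopifnot(inherits(crystal, "crystal_system"))
  counts <- table(factor(crystal$species, levels = names(crystal$species_set)))
  out <- as.integer(counts)
  names(out) <- names(counts)
  out
}

#' Central-bead coordinates of every molecule
#'
#' The central oleic bead (bead 5 of the sn-2 chain by default) is the
#' reference site for all distance calculations.  Positions are the lattice
#' anchors plus the species' central-bead offset, wrapped into the box.
#'
#' @param crystal A `crystal_system`.
#' @return n x 3 matrix of coordinates (nm) in `[0, box)`.
#' @export
central_beads <- function(crystal) {
  stopifnot(inherits(crystal, "crystal_system"))
  pos <- crystal$anchor
  for (sp in names(crystal$species_set)) {
    rows <- crystal$species == sp
    if (any(rows)) {
      off <- species_central_offset(crystal$species_set[[sp]])
      pos[rows, ] <- sweep(pos[rows, , drop = FALSE], 2L, off, "+")
    }
  }
  wrap_coords(pos, crystal$box)
}

#' Convert a single-TAG crystal to a binary mixture by random substitution
#'
#' Relabels `round(target_fraction * N)` randomly chosen molecules to a
#' second TAG species at their existing lattice sites.  A shorter replacing
#' chain simply occupies fewer bead sites along the same chain axis, leaving
#' terminal sites empty (the packing "mini-voids" of mixed-chain-length
#' crystals).  The selection is a seeded uniform draw without replacement, so
#' the same seed reproduces the same mixture and different seeds give
#' independent mixtures.
#'
#' @param crystal A single-species `crystal_system`.
#' @param new_species [tag_species] to substitute in (distinct name).
#' @param target_fraction Fraction of molecules to replace, in (0, 1).
#' @param seed Integer seed for the selection.
#' @return A `crystal_system` with updated species labels and composition.
#' @examples
#' crys <- build_crystal(default_unit_cell(), c(10, 2, 10))
#' mix <- substitute_random(crys, default_species_set()$POST, 0.3, seed = 7)
#' composition(mix)   # 240 POST, 560 STOST
#' @export
substitute_random <- function(crystal, new_species, target_fraction, seed) {
  stopifnot(inherits(crystal, "crystal_system"),
            inherits(new_species, "tag_species"))
  if (length(unique(crystal$species)) != 1L) {
    stop_invalid("`crystal` must be single-species before substitution")
  }
  if (!is.numeric(target_fraction) || length(target_fraction) != 1L ||
      is.na(target_fraction) || target_fraction <= 0 || target_fraction >= 1) {
    stop_invalid("`target_fraction` must lie strictly in (0, 1)")
  }
  if (new_species$name %in% crystal$species) {
    stop_invalid("`new_species` must differ from the resident species")
  }
  n <- n_molecules(crystal)
  n_rep <- round(target_fraction * n)
  if (n_rep == 0L) return(crystal)
  picked <- with_seed(seed, sample.int(n, n_rep))
  out <- crystal
  out$species[picked] <- new_species$name
  out$species_set[[new_species$name]] <- new_species
  out
}
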