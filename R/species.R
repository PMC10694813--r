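#' Define a coarse-grained TAG species
#'
#' A triacylglyceride (TAG) is described by the bead counts of its three
#' fatty-acid chains in sn-1/sn-2/sn-3 order and by the index of the central
#' bead of the sn-2 oleic chain.  That central bead is the reference site for
#' every distance-based calculation in the package (neighbor searches, void
#' carving, trajectory generation): in the cocoa-butter TAGs modelled here the
#' sn-2 chain is oleic and its middle bead tracks the molecule's lattice site.
#'
#' @param name Species label (used as the GRO residue name; at most 5
#'   characters).
#' @param chain_bead_counts Integer vector of length 3: beads per chain for
#'   sn-1, sn-2 (oleic) and sn-3.  All must be >= 1.
#' @param central_oleic_bead_index 1-based index of the central bead within
#'   the sn-2 oleic chain.  Defaults to bead 5.
#' @return An object of class `tag_species`.
#' @examples
#' tag_species("POP", c(5L, 9L, 5L))
#' @export
tag_species <- function(name, chain_bead_counts, central_oleic_bead_index = 5L) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name) || nchar(name) > 5L) {
    stop_invalid("`name` must be a single non-empty string of at most 5 characters")
  }
  chain_bead_counts <- as.integer(chain_bead_counts)
  if (length(chain_bead_counts) != 3L || any(is.na(chain_bead_counts)) ||
      any(chain_bead_counts < 1L)) {
    stop_invalid("`chain_bead_counts` must be three integers >= 1 (sn-1, sn-2, sn-3)")
  }
  central_oleic_bead_index <- as.integer(central_oleic_bead_index)
  if (length(central_oleic_bead_index) != 1L || is.na(central_oleic_bead_index) ||
      central_oleic_bead_index < 1L ||
      central_oleic_bead_index > chain_bead_counts[2L]) {
    stop_invalid("`central_oleic_bead_index` must lie within the sn-2 chain ",
                 "(1..", chain_bead_counts[2L], ")")
  }
  structure(
    list(name = name,
         chain_bead_counts = chain_bead_counts,
         central_oleic_bead_index = central_oleic_bead_index),
    class = "tag_species"
  )
}

#' Default cocoa-butter TAG species set
#'
#' The three main cocoa-butter TAGs in an idealized coarse-grained mapping:
#' sn-POP (palmitic-oleic-palmitic), sn-POSt (palmitic-oleic-stearic) and
#' sn-StOSt (stearic-oleic-stearic).  The palmitic chain carries one bead
#' fewer than the stearic chain, so substituting a shorter TAG into a longer
#' TAG's lattice leaves empty terminal bead sites ("mini-voids").  The oleic
#' sn-2 chain has 9 beads with bead 5 as the central reference bead.
#'
#' @return Named list of [tag_species] objects (`POP`, `POST`, `STOST`).
#' @examples
#' default_species_set()$POP
#' @export
default_species_set <- function() {
  list(
    POP   = tag_species("POP",   c(5L, 9L, 5L)),
    POST  = tag_species("POST",  c(5L, 9L, 6L)),
    STOST = tag_species("STOST", c(6L, 9L, 6L))
  )
}

#' @export
print.tag_species <- function(x, ...) {
  cat(sprintf("<tag_species> %s: chains %s beads (sn-1/sn-2/sn-3), central oleic bead %d\n",
              x$name, paste(x$chain_bead_counts, collapse = "/"),
              x$central_oleic_bead_index))
  invisible(x)
}

# Per-bead offsets (nm) of a species relative to its lattice anchor.
# Chains run along +z from the glycerol anchor; the three chains sit at small
# x offsets so the molecule has a realistic elongated footprint.  Returns a
# matrix with rownames giving bead names: A<i> (sn-1), O<i> (sn-2 oleic),
# B<i> (sn-3).
species_bead_offsets <- function(species) {
  stopifnot(inherits(species, "tag_species"))
  spacing <- 0.25            # nm between consecutive beads along the chain
  chain_x <- c(-0.25, 0, 0.25)
  prefix <- c("A", "O", "B")
  out <- list()
  for (ch in 1:3) {
    n <- species$chain_bead_counts[ch]
    off <- cbind(rep(chain_x[ch], n), 0, spacing * (seq_len(n) - 1L))
    rownames(off) <- paste0(prefix[ch], seq_len(n))
    out[[ch]] <- off
  }
  do.call(rbind, out)
}

# Offset (nm) of the central oleic bead relative to the lattice anchor.
species_central_offset <- function(species) {
  off <- species_bead_offsets(species)
  off[paste0("O", species$central_oleic_bead_index), , drop = TRUE]
}
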