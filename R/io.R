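# GRO coordinate files, the central-bead trajectory text format, curve CSVs
# and run configuration.  GRO is the only coordinate format; everything
# derived is CSV or JSON.

gro_atom_fmt <- "%5d%-5s%5s%5d%8.3f%8.3f%8.3f"

#' Write a crystal to a GRO coordinate file
#'
#' One residue per molecule (residue name = species, so the composition
#' survives the round trip), beads named `A<i>`/`O<i>`/`B<i>` for the
#' sn-1/sn-2/sn-3 chains.  Coordinates are in nm with the fixed-column GRO
#' precision of three decimals.
#'
#' @param crystal A `crystal_system`.
#' @param path Output path.
#' @param title Title line (first line of the file).
#' @return `path`, invisibly.
#' @export
write_gro <- function(crystal, path, title = "tagmelt crystal") {
  stopifnot(inherits(crystal, "crystal_system"))
  n <- n_molecules(crystal)
  offsets <- lapply(crystal$species_set, species_bead_offsets)
  lines <- character(0L)
  atom <- 0L
  blocks <- vector("list", n)
  for (m in seq_len(n)) {
    off <- offsets[[crystal$species[m]]]
    beads <- wrap_coords(sweep(off, 2L, crystal$anchor[m, ], "+"), crystal$box)
    rows <- sprintf(gro_atom_fmt,
                    m %% 100000L, crystal$species[m], rownames(off),
                    (atom + seq_len(nrow(off))) %% 100000L,
                    beads[, 1L], beads[, 2L], beads[, 3L])
    atom <- atom + nrow(off)
    blocks[[m]] <- rows
  }
  lines <- c(title, sprintf("%5d", atom), unlist(blocks),
             sprintf("%10.5f%10.5f%10.5f", crystal$box[1L], crystal$box[2L],
                     crystal$box[3L]))
  writeLines(lines, path)
  invisible(path)
}

parse_gro_frame <- function(lines, offset) {
  # returns list(title, atoms data.frame, box, next_offset); offset is the
  # 0-based index of the title line
  if (length(lines) < offset + 3L) {
    stop_format("truncated GRO content at line ", offset + 1L)
  }
  title <- lines[offset + 1L]
  natoms <- suppressWarnings(as.integer(trimws(lines[offset + 2L])))
  if (is.na(natoms) || natoms < 1L) {
    stop_format("line ", offset + 2L, ": expected a positive atom count")
  }
  if (length(lines) < offset + 2L + natoms + 1L) {
    stop_format("truncated GRO frame: expected ", natoms, " atom lines after line ",
                offset + 2L)
  }
  at <- lines[offset + 2L + seq_len(natoms)]
  bad <- which(nchar(at) < 44L)
  if (length(bad)) {
    stop_format("line ", offset + 2L + bad[1L], ": GRO atom line too short")
  }
  resnum <- suppressWarnings(as.integer(substr(at, 1L, 5L)))
  resname <- trimws(substr(at, 6L, 10L))
  atomname <- trimws(substr(at, 11L, 15L))
  xyz <- suppressWarnings(cbind(as.numeric(substr(at, 21L, 28L)),
                                as.numeric(substr(at, 29L, 36L)),
                                as.numeric(substr(at, 37L, 44L))))
  bad <- which(is.na(resnum) | !nzchar(resname) | rowSums(is.na(xyz)) > 0)
  if (length(bad)) {
    stop_format("line ", offset + 2L + bad[1L], ": malformed GRO atom line")
  }
  boxline <- suppressWarnings(as.numeric(strsplit(trimws(
    lines[offset + 2L + natoms + 1L]), "\\s+")[[1L]]))
  if (length(boxline) < 3L || any(is.na(boxline[1:3])) || any(boxline[1:3] <= 0)) {
    stop_format("line ", offset + 2L + natoms + 1L, ": malformed GRO box line")
  }
  list(title = title,
       atoms = data.frame(resnum = resnum, resname = resname,
                          atomname = atomname, x = xyz[, 1L], y = xyz[, 2L],
                          z = xyz[, 3L], stringsAsFactors = FALSE),
       box = boxline[1:3],
       next_offset = offset + 2L + natoms + 1L)
}

#' Read a GRO coordinate file
#'
#' Strict fixed-column parsing; malformed lines are reported with their line
#' number.  A single-frame file with full bead detail is returned as a
#' `crystal_system` (molecules grouped by residue number, species looked up
#' by residue name, lattice anchors recovered from the `O1` bead).  A
#' multi-frame file is returned as a [tag_trajectory] of central beads: per
#' residue, the bead named `O<central>` when present, otherwise the
#' residue's single atom.
#'
#' @param path GRO file path.
#' @param species_set Named list of [tag_species] used to resolve residue
#'   names (default [default_species_set()]).
#' @param ramp A [temperature_ramp]; required for multi-frame files.
#' @return A `crystal_system` or a [tag_trajectory].
#' @export
read_gro <- function(path, species_set = default_species_set(), ramp = NULL) {
  if (!file.exists(path)) stop_format("no such file: ", path)
  lines <- readLines(path)
  if (!length(lines) || !any(nzchar(lines))) stop_format("empty GRO file: ", path)
  frames <- list()
  offset <- 0L
  while (offset < length(lines) && any(nzchar(lines[(offset + 1L):length(lines)]))) {
    fr <- parse_gro_frame(lines, offset)
    frames[[length(frames) + 1L]] <- fr
    offset <- fr$next_offset
  }
  if (length(frames) == 1L) {
    gro_frame_to_crystal(frames[[1L]], species_set)
  } else {
    gro_frames_to_trajectory(frames, species_set, ramp)
  }
}

gro_frame_to_crystal <- function(frame, species_set) {
  at <- frame$atoms
  mols <- split(seq_len(nrow(at)), cumsum(c(1L, diff(at$resnum) != 0L)))
  species <- character(length(mols))
  anchor <- matrix(0, length(mols), 3L)
  used <- list()
  for (m in seq_along(mols)) {
    rows <- mols[[m]]
    sp <- at$resname[rows[1L]]
    if (is.null(species_set[[sp]])) {
      stop_format("unknown species in GRO file: ", sp)
    }
    o1 <- rows[at$atomname[rows] == "O1"]
    if (length(o1) != 1L) {
      stop_format("molecule ", m, " has no unique O1 anchor bead")
    }
    species[m] <- sp
    anchor[m, ] <- c(at$x[o1], at$y[o1], at$z[o1])
    used[[sp]] <- species_set[[sp]]
  }
  new_crystal(species = species, anchor = wrap_coords(anchor, frame$box),
              box = frame$box, species_set = used)
}

gro_frames_to_trajectory <- function(frames, species_set, ramp) {
  if (is.null(ramp)) {
    stop_format("multi-frame GRO files need a `ramp` to become a trajectory")
  }
  counts <- vapply(frames, function(f) nrow(f$atoms), integer(1L))
  if (length(unique(counts)) != 1L) {
    stop_format("inconsistent atom counts across frames: ",
                paste(unique(counts), collapse = ", "))
  }
  positions <- vector("list", length(frames))
  times <- numeric(length(frames))
  for (f in seq_along(frames)) {
    at <- frames[[f]]$atoms
    mols <- split(seq_len(nrow(at)), cumsum(c(1L, diff(at$resnum) != 0L)))
    pos <- t(vapply(mols, function(rows) {
      sp <- species_set[[at$resname[rows[1L]]]]
      pick <- if (length(rows) == 1L) rows else {
        target <- if (!is.null(sp)) paste0("O", sp$central_oleic_bead_index) else ""
        hit <- rows[at$atomname[rows] == target]
        if (length(hit) != 1L) {
          stop_format("cannot identify the central bead of a multi-bead residue")
        }
        hit
      }
      c(at$x[pick], at$y[pick], at$z[pick])
    }, numeric(3L)))
    positions[[f]] <- unname(pos)
    tm <- regmatches(frames[[f]]$title,
                     regexpr("t=\\s*-?[0-9.]+", frames[[f]]$title))
    times[f] <- if (length(tm)) as.numeric(sub("t=\\s*", "", tm)) else NA_real_
  }
  if (any(is.na(times))) times <- seq(0, ramp$duration, length.out = length(frames))
  tag_trajectory(times, positions, lapply(frames, `[[`, "box"), ramp)
}

#' Write / read a central-bead trajectory in plain text
#'
#' A simple whitespace-delimited per-frame format: a header line
#' `time_ns box_x box_y box_z` followed by one `id x y z` row per molecule,
#' frames concatenated.  Lines starting with `#` are comments (the writer
#' records the seed/config hash there when given).
#'
#' @param trajectory A [tag_trajectory].
#' @param path File path.
#' @param config Optional [run_config()]; when given, its hash and seed are
#'   embedded in a comment header.
#' @return `path`, invisibly.
#' @export
write_trajectory_txt <- function(trajectory, path, config = NULL) {
  stopifnot(inherits(trajectory, "tag_trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config)) {
    writeLines(sprintf("# tagmelt config=%s seed=%s", config_hash(config),
                       config$seed %||% "NA"), con)
  }
  for (f in seq_along(trajectory$times)) {
    # header times/boxes always carry a decimal point; id rows never do,
    # which is what lets the reader tell the two apart
    writeLines(sprintf("%.6f %.6f %.6f %.6f", trajectory$times[f],
                       trajectory$box[[f]][1L], trajectory$box[[f]][2L],
                       trajectory$box[[f]][3L]), con)
    p <- trajectory$positions[[f]]
    writeLines(sprintf("%d %.6f %.6f %.6f", trajectory$ids, p[, 1L], p[, 2L],
                       p[, 3L]), con)
  }
  invisible(path)
}

#' @rdname write_trajectory_txt
#' @param ramp A [temperature_ramp] for the resulting trajectory.
#' @export
read_trajectory_txt <- function(path, ramp) {
  if (!file.exists(path)) stop_format("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop_format("empty trajectory file: ", path)
  toks <- strsplit(trimws(lines), "\\s+")
  # id rows start with a bare integer; frame headers start with a time that
  # always carries a decimal point (see write_trajectory_txt)
  is_id_row <- vapply(toks, function(t) grepl("^-?[0-9]+$", t[1L]), logical(1L))
  times <- c(); positions <- list(); box <- list(); ids <- NULL
  i <- 1L
  while (i <= length(lines)) {
    h <- suppressWarnings(as.numeric(toks[[i]]))
    if (is_id_row[i] || length(h) != 4L || any(is.na(h))) {
      stop_format("line ", i, ": expected `time_ns box_x box_y box_z` header")
    }
    j <- i + 1L
    rows <- list()
    while (j <= length(lines) && is_id_row[j]) {
      v <- suppressWarnings(as.numeric(toks[[j]]))
      if (length(v) != 4L || any(is.na(v))) {
        stop_format("line ", j, ": malformed `id x y z` row")
      }
      rows[[length(rows) + 1L]] <- v
      j <- j + 1L
    }
    if (!length(rows)) stop_format("frame at line ", i, " has no molecules")
    m <- do.call(rbind, rows)
    if (is.null(ids)) ids <- as.integer(m[, 1L])
    times <- c(times, h[1L])
    box[[length(box) + 1L]] <- h[2:4]
    positions[[length(positions) + 1L]] <- unname(m[, 2:4, drop = FALSE])
    i <- j
  }
  tag_trajectory(times, positions, box, ramp, ids = ids)
}

#' Write / read a total-NNO curve as CSV
#'
#' Columns `temperature_C,total_nno` (plus any others present); an optional
#' comment header embeds the config hash and seed.
#'
#' @param curve A `total_nno_curve` (or compatible data frame).
#' @param path CSV path.
#' @param config Optional [run_config()] for the comment header.
#' @return `path` (writer, invisibly) or the curve (reader).
#' @export
write_curve_csv <- function(curve, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config)) {
    writeLines(sprintf("# tagmelt config=%s seed=%s", config_hash(config),
                       config$seed %||% "NA"), con)
  }
  utils::write.csv(as.data.frame(curve), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_curve_csv
#' @export
read_curve_csv <- function(path) {
  if (!file.exists(path)) stop_format("no such file: ", path)
  out <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if ("total_nno" %in% names(out)) class(out) <- c("total_nno_curve", "data.frame")
  out
}

#' Analysis run configuration
#'
#' Bundles every tunable of the pipeline with its default: the 1.2 nm NNO
#' cutoff, the 248-348 K / 200 ns ramp, the 16-80 step 8 void grid, the
#' 10-90% step 10 ratio grid, 50 replicates, the 0.95/0.95
#' prediction-interval rule and the 1.5 percentage-point ratio tolerance.
#' Configurations serialize to JSON and hash stably, so every output file
#' can embed the exact configuration that produced it.
#'
#' @param cutoff NNO cutoff (nm).
#' @param ramp Length-3 numeric: T_start (K), T_end (K), duration (ns).
#' @param void_grid Void sizes (molecules).
#' @param ratio_grid Replacing-TAG fractions.
#' @param replicates Replicates per combination.
#' @param pi_confidence,below_fraction_threshold Onset-rule fractions.
#' @param tolerance Void ratio tolerance (absolute percentage points).
#' @param n_frames Frames sampled per trajectory.
#' @param seed Base seed.
#' @return A `run_config` list.
#' @export
run_config <- function(cutoff = 1.2, ramp = c(248, 348, 200),
                       void_grid = seq(16L, 80L, by = 8L),
                       ratio_grid = seq(0.1, 0.9, by = 0.1),
                       replicates = 50L, pi_confidence = 0.95,
                       below_fraction_threshold = 0.95, tolerance = 1.5,
                       n_frames = 200L, seed = 1L) {
  structure(list(cutoff = cutoff, ramp = as.numeric(ramp),
                 void_grid = as.integer(void_grid),
                 ratio_grid = as.numeric(ratio_grid),
                 replicates = as.integer(replicates),
                 pi_confidence = pi_confidence,
                 below_fraction_threshold = below_fraction_threshold,
                 tolerance = tolerance, n_frames = as.integer(n_frames),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path JSON path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_format("no such file: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, raw)
}

#' @rdname run_config
#' @return `config_hash()`: a 32-character MD5 hex digest of the serialized
#'   configuration.
#' @export
config_hash <- function(config) {
  stopifnot(inherits(config, "run_config"))
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}
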