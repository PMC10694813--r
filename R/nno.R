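#' Linear temperature ramp
#'
#' Direct-heating runs raise the thermostat temperature linearly, so frame
#' time converts to temperature as
#' `T(t) = T_start + (T_end - T_start) * t / duration`.  The canonical
#' protocol heats from 248 to 348 K over 200 ns (0.5 K/ns).
#'
#' @param T_start,T_end Start and end temperatures (K), `T_end > T_start`.
#' @param duration Ramp duration (ns), > 0.
#' @return An object of class `temperature_ramp`.
#' @examples
#' ramp <- temperature_ramp()
#' ramp_temperature(ramp, 100)   # 298 K at mid-ramp
#' heating_rate(ramp)            # 0.5 K/ns
#' @export
temperature_ramp <- function(T_start = 248, T_end = 348, duration = 200) {
  if (!is.numeric(T_start) || !is.numeric(T_end) || !is.numeric(duration) ||
      T_end <= T_start || duration <= 0) {
    stop_invalid("need T_end > T_start and duration > 0")
  }
  structure(list(T_start = T_start, T_end = T_end, duration = duration),
            class = "temperature_ramp")
}

#' @rdname temperature_ramp
#' @param ramp A `temperature_ramp`.
#' @param t Time(s) in ns.
#' @return `ramp_temperature()`: temperature(s) in K.
#' @export
ramp_temperature <- function(ramp, t) {
  stopifnot(inherits(ramp, "temperature_ramp"))
  ramp$T_start + (ramp$T_end - ramp$T_start) * t / ramp$duration
}

#' @rdname temperature_ramp
#' @return `heating_rate()`: the ramp slope in K/ns.
#' @export
heating_rate <- function(ramp) {
  stopifnot(inherits(ramp, "temperature_ramp"))
  (ramp$T_end - ramp$T_start) / ramp$duration
}

#' Central-bead trajectory container
#'
#' Holds the per-frame central-bead coordinates of every molecule together
#' with the temperature ramp.  Frame times must be strictly increasing and
#' the molecule count constant across frames.
#'
#' @param times Numeric vector of frame times (ns), strictly increasing.
#' @param positions List of n x 3 coordinate matrices (nm), one per frame.
#' @param box Length-3 box vector (nm), or a list of one per frame.
#' @param ramp A [temperature_ramp].
#' @param ids Optional molecule ids (default `0:(n-1)`).
#' @param metadata Optional list (e.g. generator ground truth).
#' @return An object of class `tag_trajectory`.
#' @export
tag_trajectory <- function(times, positions, box, ramp, ids = NULL,
                           metadata = list()) {
  stopifnot(inherits(ramp, "temperature_ramp"))
  if (length(times) != length(positions)) {
    stop_format("`times` and `positions` must have one entry per frame")
  }
  if (length(times) < 1L || any(diff(times) <= 0)) {
    stop_format("frame times must be strictly increasing")
  }
  counts <- vapply(positions, nrow, integer(1L))
  if (length(unique(counts)) != 1L) {
    stop_format("molecule count differs across frames: ",
                paste(unique(counts), collapse = ", "))
  }
  if (!all(vapply(positions, function(p) all(is.finite(p)), logical(1L)))) {
    stop_format("non-finite coordinates in trajectory")
  }
  if (!is.list(box)) box <- rep(list(as.numeric(box)), length(times))
  if (any(vapply(box, function(b) length(b) != 3L || any(b <= 0), logical(1L)))) {
    stop_format("each frame box must be three positive edge lengths")
  }
  structure(
    list(times = as.numeric(times), positions = positions, box = box,
         ramp = ramp, ids = ids %||% (seq_len(counts[1L]) - 1L),
         metadata = metadata),
    class = "tag_trajectory"
  )
}

#' @export
print.tag_trajectory <- function(x, ...) {
  cat(sprintf(
    "<tag_trajectory> %d molecules, %d frames, t = %.1f..%.1f ns (%.0f..%.0f K)\n",
    nrow(x$positions[[1L]]), length(x$times), min(x$times), max(x$times),
    ramp_temperature(x$ramp, min(x$times)), ramp_temperature(x$ramp, max(x$times))))
  invisible(x)
}

n_frames <- function(traj) length(traj$times)

#' Neighbor sets of a frame under periodic minimum image
#'
#' Finds, for every molecule, the set of molecules whose central beads lie
#' within `cutoff` of its own (minimum-image convention, rectangular box).
#' The default method bins molecules into cells of at least the cutoff width
#' and only examines adjacent cells; `method = "brute"` checks all pairs.
#' Both return identical sets — the brute-force path exists as the
#' correctness reference.
#'
#' @param positions n x 3 coordinate matrix (nm).
#' @param box Length-3 box vector (nm).
#' @param cutoff Neighbor cutoff (nm); must be positive and less than half
#'   the smallest box dimension (else the minimum-image convention breaks).
#' @param method `"cell"` (default) or `"brute"`.
#' @return List of n sorted integer vectors of neighbor indices (1-based);
#'   the relation is symmetric and irreflexive.
#' @export
neighbor_sets <- function(positions, box, cutoff = 1.2,
                          method = c("cell", "brute")) {
  method <- match.arg(method)
  if (is.null(dim(positions))) positions <- matrix(positions, ncol = 3L)
  box <- as.numeric(box)
  stopifnot(ncol(positions) == 3L, length(box) == 3L, all(box > 0))
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0 ||
      cutoff >= min(box) / 2) {
    stop_invalid("`cutoff` must satisfy 0 < cutoff < min(box)/2 = ",
                 min(box) / 2)
  }
  n <- nrow(positions)
  adj <- rep(list(integer(0L)), n)
  if (n < 2L) return(adj)
  positions <- wrap_coords(positions, box)
  pairs <- if (method == "brute") {
    candidate_pairs_brute(n)
  } else {
    candidate_pairs_cell(positions, box, cutoff)
  }
  if (nrow(pairs) == 0L) return(adj)
  d <- minimum_image(positions[pairs[, 1L], , drop = FALSE] -
                       positions[pairs[, 2L], , drop = FALSE], box)
  keep <- rowSums(d * d) <= cutoff^2
  i <- pairs[keep, 1L]; j <- pairs[keep, 2L]
  hits <- split(c(j, i), c(i, j))
  for (nm in names(hits)) adj[[as.integer(nm)]] <- sort(hits[[nm]])
  adj
}

candidate_pairs_brute <- function(n) {
  i <- rep.int(seq_len(n - 1L), (n - 1L):1L)
  j <- sequence((n - 1L):1L) + i
  cbind(i, j)
}

# Cell-list candidate pairs: bin into cells of width >= cutoff, examine the
# 27-cell neighborhood of each occupied cell.  Wrapped duplicate cells (when
# a dimension has < 3 cells) are removed with unique(); each unordered cell
# pair is visited once via the id ordering.
candidate_pairs_cell <- function(positions, box, cutoff) {
  n <- nrow(positions)
  nc <- pmax(1L, as.integer(floor(box / cutoff)))
  idx <- floor(sweep(positions, 2L, box / nc, "/"))
  idx <- pmin(idx, matrix(nc - 1L, n, 3L, byrow = TRUE))   # guard edge rounding
  cid <- idx[, 1L] + nc[1L] * (idx[, 2L] + nc[2L] * idx[, 3L])
  members <- split(seq_len(n), cid)
  occupied <- as.integer(names(members))
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  pi <- vector("list", length(occupied)); pj <- pi
  for (k in seq_along(occupied)) {
    c0 <- occupied[k]
    cx <- c0 %% nc[1L]
    cy <- (c0 %/% nc[1L]) %% nc[2L]
    cz <- c0 %/% (nc[1L] * nc[2L])
    nb <- unique(((cx + offs[, 1L]) %% nc[1L]) +
                   nc[1L] * (((cy + offs[, 2L]) %% nc[2L]) +
                               nc[2L] * ((cz + offs[, 3L]) %% nc[3L])))
    nb <- nb[nb >= c0 & nb %in% occupied]
    m0 <- members[[as.character(c0)]]
    ii <- jj <- integer(0L)
    for (cb in nb) {
      if (cb == c0) {
        if (length(m0) > 1L) {
          w <- candidate_pairs_brute(length(m0))
          ii <- c(ii, m0[w[, 1L]]); jj <- c(jj, m0[w[, 2L]])
        }
      } else {
        mb <- members[[as.character(cb)]]
        ii <- c(ii, rep(m0, each = length(mb)))
        jj <- c(jj, rep(mb, times = length(m0)))
      }
    }
    pi[[k]] <- ii; pj[[k]] <- jj
  }
  cbind(unlist(pi) %||% integer(0L), unlist(pj) %||% integer(0L))
}

#' Near-neighbor occupancy series of a trajectory
#'
#' The near-neighbor occupancy (NNO) of a molecule counts how many of its
#' neighbors (central beads within `cutoff`) persist from one frame to the
#' next: `NNO(i, t) = |N_t(i) intersect N_{t-1}(i)|`, with the first frame
#' defined as the full neighbor count `|N_0(i)|`.  A molecule in a
#' crystalline environment keeps its neighbor set frame after frame, so its
#' NNO stays high; once it melts, neighbors are exchanged and the NNO
#' collapses.  `mode = "reference"` intersects with the first frame's sets
#' instead of the preceding frame's.
#'
#' @param trajectory A [tag_trajectory] with at least 2 frames.
#' @param cutoff Neighbor cutoff in nm (default 1.2, the central-oleic-bead
#'   cutoff).
#' @param mode `"consecutive"` (default) or `"reference"`.
#' @param method Neighbor-search method, see [neighbor_sets()].
#' @return An `nno_series`: integer matrix (molecules x frames) with frame
#'   times, cutoff and mode stored as attributes.
#' @export
compute_nno <- function(trajectory, cutoff = 1.2,
                        mode = c("consecutive", "reference"),
                        method = c("cell", "brute")) {
  stopifnot(inherits(trajectory, "tag_trajectory"))
  mode <- match.arg(mode)
  method <- match.arg(method)
  nf <- n_frames(trajectory)
  if (nf < 2L) stop_invalid("need at least 2 frames to compute persistence")
  n <- nrow(trajectory$positions[[1L]])
  values <- matrix(0L, nrow = n, ncol = nf)
  prev <- NULL
  ref <- NULL
  for (f in seq_len(nf)) {
    adj <- neighbor_sets(trajectory$positions[[f]], trajectory$box[[f]],
                         cutoff = cutoff, method = method)
    if (f == 1L) {
      values[, f] <- lengths(adj)
      ref <- adj
    } else {
      base <- if (mode == "consecutive") prev else ref
      values[, f] <- vapply(seq_len(n), function(i) {
        length(intersect(adj[[i]], base[[i]]))
      }, integer(1L))
    }
    prev <- adj
  }
  structure(values, class = "nno_series", times = trajectory$times,
            cutoff = cutoff, mode = mode)
}

#' Total-NNO-vs-temperature curve
#'
#' Sums the per-molecule NNO over the whole system at each frame and maps
#' frame times to temperature through the linear ramp, reducing the
#' trajectory to the 2-D curve on which melting onset is detected.
#'
#' @param series An `nno_series` from [compute_nno()].
#' @param ramp A [temperature_ramp].
#' @return A `total_nno_curve` data frame with columns `time_ns`,
#'   `temperature_K`, `temperature_C`, `total_nno`.
#' @export
total_nno_curve <- function(series, ramp) {
  stopifnot(inherits(series, "nno_series"), inherits(ramp, "temperature_ramp"))
  times <- attr(series, "times")
  tempK <- ramp_temperature(ramp, times)
  out <- data.frame(time_ns = times,
                    temperature_K = tempK,
                    temperature_C = kelvin_to_celsius(tempK),
                    total_nno = as.integer(colSums(series)))
  class(out) <- c("total_nno_curve", "data.frame")
  out
}
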