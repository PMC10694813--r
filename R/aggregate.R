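#' Aggregate replicate melting onsets
#'
#' The melting point of a TAG-ratio/void-size combination is the simple
#' arithmetic mean of the per-replicate onset temperatures; its uncertainty
#' is a seeded percentile bootstrap of the mean (95% interval, 2000 resamples
#' by default).
#'
#' @param onsets Numeric vector of onset temperatures (degrees C), length >= 2.
#' @param bootstrap_reps Number of bootstrap resamples (default 2000).
#' @param seed Integer seed for the resampling.
#' @param conf Confidence level of the percentile interval (default 0.95).
#' @return List with `mean`, `ci_lower`, `ci_upper`, `ci_half_width`, `n`.
#' @examples
#' aggregate_onsets(c(20, 22, 24), seed = 1)$mean   # 22
#' @export
aggregate_onsets <- function(onsets, bootstrap_reps = 2000L, seed = 1L,
                             conf = 0.95) {
  onsets <- as.numeric(onsets)
  if (length(onsets) < 2L || any(!is.finite(onsets))) {
    stop_invalid("need at least 2 finite onset values")
  }
  n <- length(onsets)
  boot_means <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * bootstrap_reps, replace = TRUE),
                  nrow = bootstrap_reps)
    rowMeans(matrix(onsets[idx], nrow = bootstrap_reps))
  })
  alpha <- 1 - conf
  q <- unname(stats::quantile(boot_means, c(alpha / 2, 1 - alpha / 2), type = 7))
  list(mean = mean(onsets), ci_lower = q[1L], ci_upper = q[2L],
       ci_half_width = (q[2L] - q[1L]) / 2, n = n)
}

#' Bootstrap convergence trace over replicate count
#'
#' Recomputes the running mean and bootstrap error over every prefix of the
#' replicate list, mirroring the convergence check used to justify the
#' replicate budget (the error and mean stabilise as runs accumulate).
#'
#' @param onsets Ordered numeric vector of onsets (degrees C), length >= 2.
#' @param seed Integer seed; prefix resamples are seeded deterministically
#'   from it.
#' @param bootstrap_reps Resamples per prefix (default 2000).
#' @return Data frame with one row per prefix length `n = 2..N`: `n`,
#'   `running_mean`, `running_error` (bootstrap CI half-width).
#' @export
convergence_trace <- function(onsets, seed = 1L, bootstrap_reps = 2000L) {
  onsets <- as.numeric(onsets)
  if (length(onsets) < 2L || any(!is.finite(onsets))) {
    stop_invalid("need at least 2 finite onset values")
  }
  ns <- 2:length(onsets)
  rows <- lapply(ns, function(n) {
    agg <- aggregate_onsets(onsets[seq_len(n)], bootstrap_reps = bootstrap_reps,
                            seed = seed + n)
    data.frame(n = n, running_mean = agg$mean, running_error = agg$ci_half_width)
  })
  do.call(rbind, rows)
}

#' Build a melting-vs-void-size curve
#'
#' @param void_size Strictly increasing integer void sizes.
#' @param mean_onset Mean onset per void size (degrees C).
#' @param ci95 Optional 95% CI half-widths (degrees C).
#' @param n Optional replicate counts.
#' @return A `melting_curve` data frame.
#' @export
melting_curve <- function(void_size, mean_onset, ci95 = NA_real_, n = NA_integer_) {
  void_size <- as.integer(void_size)
  if (any(diff(void_size) <= 0)) stop_invalid("void sizes must be strictly increasing")
  if (length(mean_onset) != length(void_size) || any(!is.finite(mean_onset))) {
    stop_invalid("`mean_onset` must be finite, one value per void size")
  }
  out <- data.frame(void_size = void_size, mean_onset = as.numeric(mean_onset),
                    ci95 = as.numeric(ci95), n = as.integer(n))
  class(out) <- c("melting_curve", "data.frame")
  out
}

#' Read the melting point off a melting-vs-void-size curve (plateau rule)
#'
#' Enlarging the crack void lowers the detected onset until the curve
#' plateaus.  The plateau — and with it the system's melting point — is the
#' first point at which the difference between melting points at subsequent
#' void sizes becomes larger than the previous difference: while the
#' successive drops `d_j = mean_onset(v_j) - mean_onset(v_{j+1})` decrease or
#' remain the same the curve is still converging; the first `d_j > d_{j-1}`
#' marks the plateau at `v_j`.  If no difference ever increases, the plateau
#' is taken at the last point before a mechanical collapse (see
#' [detect_collapse()]), or at the last point of the curve when no collapse
#' is present.  An explicit `override` void size supersedes the rule (curves
#' are occasionally resolved by inspection of the family of curves as a
#' whole); the override is recorded, never silent.
#'
#' @param curve A [melting_curve] with >= 3 points.
#' @param override Optional void size that supersedes the rule; must be a
#'   void size present in the curve.
#' @param collapse_factor Passed to [detect_collapse()] for the fallback.
#' @return A `plateau_result` list: `chosen_void_size`, `melting_point`,
#'   `rule_trace` (the successive differences), `manual_override` (NULL or
#'   the override with a note).
#' @examples
#' crv <- melting_curve(seq(16, 56, 8), c(30, 28.5, 27.5, 27, 26.8, 25.5))
#' detect_plateau(crv)   # void 48, melting point 26.8
#' @export
detect_plateau <- function(curve, override = NULL, collapse_factor = 2) {
  stopifnot(inherits(curve, "melting_curve"))
  p <- nrow(curve)
  if (p < 3L) stop_invalid("need at least 3 curve points")
  d <- curve$mean_onset[-p] - curve$mean_onset[-1L]   # d_j: drop from v_j to v_{j+1}

  if (!is.null(override)) {
    j <- match(as.integer(override), curve$void_size)
    if (is.na(j)) stop_invalid("override void size ", override, " not in curve")
    return(structure(
      list(chosen_void_size = curve$void_size[j],
           melting_point = curve$mean_onset[j],
           rule_trace = d,
           manual_override = list(void_size = curve$void_size[j],
                                  note = "manual override supersedes plateau rule")),
      class = "plateau_result"))
  }

  inc <- which(d[-1L] > d[-length(d)])         # j with d_j > d_{j-1}, offset by 1
  j <- if (length(inc)) inc[1L] + 1L else {
    coll <- detect_collapse(curve, factor = collapse_factor)
    if (is.null(coll)) p else coll
  }
  structure(
    list(chosen_void_size = curve$void_size[j],
         melting_point = curve$mean_onset[j],
         rule_trace = d,
         manual_override = NULL),
    class = "plateau_result")
}

#' @export
print.plateau_result <- function(x, ...) {
  cat(sprintf("<plateau_result> melting point %.2f C at void size %d%s\n",
              x$melting_point, x$chosen_void_size,
              if (is.null(x$manual_override)) "" else " (manual override)"))
  cat("  successive differences:", paste(sprintf("%.2f", x$rule_trace),
                                         collapse = ", "), "\n")
  invisible(x)
}

#' Detect mechanical collapse on a melting-vs-void-size curve
#'
#' Very large voids destabilise the crystal mechanically: the onset drops
#' sharply instead of plateauing.  The collapse is flagged at the first point
#' whose drop to the next point exceeds `factor` times the median of all
#' preceding drops.
#'
#' @param curve A [melting_curve] with >= 3 points.
#' @param factor Multiple of the median prior drop that qualifies as
#'   "sharp" (default 2).
#' @return Index (into the curve) of the point before the collapse drop, or
#'   `NULL` when no collapse is present.
#' @export
detect_collapse <- function(curve, factor = 2) {
  stopifnot(inherits(curve, "melting_curve"))
  p <- nrow(curve)
  if (p < 3L) stop_invalid("need at least 3 curve points")
  d <- curve$mean_onset[-p] - curve$mean_onset[-1L]
  for (j in 2:length(d)) {
    if (d[j] > factor * stats::median(d[seq_len(j - 1L)])) return(j)
  }
  NULL
}

#' Enumerate the full simulation design
#'
#' Cartesian product of binary TAG pairs, mixture ratios, void sizes and
#' replicates, with a distinct seed per run so that no two crystals or voids
#' are ever identical.  The full study design — 3 pairs x 9 ratios x 9 void
#' sizes x 50 replicates — enumerates 12,150 runs.
#'
#' @param pairs Character vector of pair labels (e.g. `"POP-POST"`).
#' @param ratios Numeric fractions of the replacing TAG.
#' @param void_sizes Integer void sizes.
#' @param replicates Number of replicates per combination.
#' @param base_seed Integer; run seeds are `base_seed + 1..n_runs`.
#' @return A `run_manifest` data frame: `run`, `pair`, `ratio`, `void_size`,
#'   `replicate`, `seed`.
#' @examples
#' nrow(enumerate_design(c("a", "b", "c"), 1:9 / 10, seq(16, 80, 8), 50))
#' @export
enumerate_design <- function(pairs, ratios, void_sizes, replicates,
                             base_seed = 1000L) {
  if (!length(pairs) || !length(ratios) || !length(void_sizes) ||
      length(replicates) != 1L || replicates < 1L) {
    stop_invalid("all design lists must be non-empty and replicates >= 1")
  }
  grid <- expand.grid(replicate = seq_len(replicates),
                      void_size = as.integer(void_sizes),
                      ratio = as.numeric(ratios),
                      pair = as.character(pairs),
                      stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, c("pair", "ratio", "void_size", "replicate")]
  out <- cbind(run = seq_len(nrow(grid)), grid,
               seed = as.integer(base_seed) + seq_len(nrow(grid)))
  class(out) <- c("run_manifest", "data.frame")
  out
}
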