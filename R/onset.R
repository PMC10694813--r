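#' Onset-detection configuration
#'
#' @param pi_confidence One-sided confidence of the lower prediction bound
#'   (default 0.95).
#' @param below_fraction_threshold Fraction of remaining points that must lie
#'   strictly below their bound (default 0.95; the rule requires *more than*
#'   this fraction).
#' @param min_fit_fraction Smallest fraction of the curve used for the
#'   baseline fit (default 0.2); prevents degenerate 2-3 point fits.
#' @return An `onset_config` list.
#' @export
onset_config <- function(pi_confidence = 0.95,
                         below_fraction_threshold = 0.95,
                         min_fit_fraction = 0.2) {
  vals <- c(pi_confidence, below_fraction_threshold, min_fit_fraction)
  if (any(!is.finite(vals)) || any(vals <= 0) || any(vals >= 1)) {
    stop_invalid("all onset_config fractions must lie strictly in (0, 1)")
  }
  structure(list(pi_confidence = pi_confidence,
                 below_fraction_threshold = below_fraction_threshold,
                 min_fit_fraction = min_fit_fraction),
            class = "onset_config")
}

#' Detect the melting onset from a total-NNO curve
#'
#' Iterates along the total-NNO-vs-temperature curve: for each candidate
#' split index k, an ordinary least-squares line is fitted to the head
#' (points 1..k, the crystalline baseline) and a one-sided lower prediction
#' bound at confidence `pi_confidence` is evaluated at every remaining
#' point.  The criterion is met at the smallest k for which the fraction of
#' remaining points falling strictly below their bound exceeds
#' `below_fraction_threshold` (more than 95% by default).  On a stable
#' crystalline baseline essentially no points fall below the bound; once the
#' system starts to melt the total NNO drops and the tail dives under it.
#'
#' The onset is reported at the departure point: the first remaining point
#' that falls below its bound and is immediately followed by another
#' below-bound point (a lone sub-bound point is the ~5% false-positive rate
#' of the one-sided bound, not melting).  The split temperature itself would
#' systematically precede the departure by a margin that grows with the
#' length of the remaining tail — the criterion tolerates up to 5% of the
#' tail being still crystalline — so it is kept in the result as
#' `split_index` but not used as the onset estimate.
#'
#' @param curve A `total_nno_curve`, or any data frame with strictly
#'   increasing `temperature_C` and a `total_nno` column; at least 10 points.
#' @param config An [onset_config].
#' @return An `onset_result` list: `onset_temperature_C`, `onset_index`,
#'   `split_index`, `below_fraction_at_onset`, `found`.
#' @examples
#' set.seed(1)
#' tc <- seq(0, 60, length.out = 120)
#' nno <- 4000 + rnorm(120, 0, 30) - 50 * pmax(tc - 30, 0)
#' detect_onset(data.frame(temperature_C = tc, total_nno = nno))
#' @export
detect_onset <- function(curve, config = onset_config()) {
  stopifnot(inherits(config, "onset_config"))
  if (!is.data.frame(curve) ||
      !all(c("temperature_C", "total_nno") %in% names(curve))) {
    stop_format("`curve` needs `temperature_C` and `total_nno` columns")
  }
  x <- as.numeric(curve$temperature_C)
  y <- as.numeric(curve$total_nno)
  n <- length(x)
  if (n < 10L) stop_invalid("need at least 10 curve points, got ", n)
  if (any(diff(x) <= 0)) stop_format("temperatures must be strictly increasing")

  not_found <- structure(
    list(onset_temperature_C = NA_real_, onset_index = NA_integer_,
         split_index = NA_integer_, below_fraction_at_onset = NA_real_,
         found = FALSE),
    class = "onset_result")

  k_min <- max(ceiling(config$min_fit_fraction * n), 3L)
  for (k in k_min:(n - 1L)) {
    head_idx <- seq_len(k)
    fit <- stats::lm(y ~ x, data = data.frame(x = x[head_idx], y = y[head_idx]))
    # one-sided lower bound at pi_confidence = lower limit of the two-sided
    # prediction interval at level 2*pi_confidence - 1
    lwr <- stats::predict(fit, newdata = data.frame(x = x[(k + 1L):n]),
                          interval = "prediction",
                          level = 2 * config$pi_confidence - 1)[, "lwr"]
    below <- y[(k + 1L):n] < lwr
    frac <- mean(below)
    if (frac > config$below_fraction_threshold) {
      # departure point: first below-bound point confirmed by its successor
      run2 <- below & c(below[-1L], TRUE)
      b <- k + which(run2)[1L]
      return(structure(
        list(onset_temperature_C = x[b], onset_index = b,
             split_index = k, below_fraction_at_onset = frac, found = TRUE),
        class = "onset_result"))
    }
  }
  not_found
}

#' @export
print.onset_result <- function(x, ...) {
  if (x$found) {
    cat(sprintf("<onset_result> onset %.2f C at index %d (%.1f%% of tail below PI)\n",
                x$onset_temperature_C, x$onset_index,
                100 * x$below_fraction_at_onset))
  } else {
    cat("<onset_result> no melting onset found\n")
  }
  invisible(x)
}
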