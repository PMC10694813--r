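#' Binary phase diagram container
#'
#' Melting temperature versus composition for one binary TAG pair.
#' Compositions are fractions of component A in `[0, 1]` (the endpoints are
#' the pure components) and must be unique.
#'
#' @param fraction Numeric fractions of component A in `[0, 1]`, unique.
#' @param melting_point Melting temperatures (degrees C).
#' @param pair Pair label, e.g. `"POP/POST"`.
#' @param source Optional per-point source tag (e.g. `"simulated"`,
#'   `"hildebrand"`).
#' @return A `phase_diagram` data frame sorted by fraction.
#' @export
phase_diagram <- function(fraction, melting_point, pair = "A/B",
                          source = "simulated") {
  fraction <- as.numeric(fraction)
  melting_point <- as.numeric(melting_point)
  if (length(fraction) != length(melting_point) ||
      any(!is.finite(fraction)) || any(!is.finite(melting_point)) ||
      any(fraction < 0) || any(fraction > 1)) {
    stop_invalid("`fraction` must lie in [0, 1] with one melting point each")
  }
  if (anyDuplicated(fraction)) stop_invalid("fractions must be unique")
  ord <- order(fraction)
  out <- data.frame(fraction = fraction[ord],
                    melting_point = melting_point[ord],
                    source = rep_len(source, length(fraction))[ord],
                    stringsAsFactors = FALSE)
  attr(out, "pair") <- pair
  class(out) <- c("phase_diagram", "data.frame")
  out
}

#' Locate the eutectic minimum of a phase diagram
#'
#' Finds the composition with the lowest melting temperature.  By default
#' the pure endpoints (fractions 0 and 1) are excluded so the result is a
#' genuine mixture minimum; eutectic behaviour is present when this interior
#' minimum lies strictly below both pure melting points.  Ties are broken
#' toward the composition closest to 0.5, and all tied compositions are
#' reported in the diagnostics.
#'
#' @param diagram A [phase_diagram] with >= 3 points.
#' @param include_endpoints Include fractions 0 and 1 in the search
#'   (default `FALSE`).
#' @return An `eutectic_point` list: `fraction`, `temperature`, and
#'   `tied_fractions` (all compositions attaining the minimum).
#' @export
find_minimum <- function(diagram, include_endpoints = FALSE) {
  stopifnot(inherits(diagram, "phase_diagram"))
  if (nrow(diagram) < 3L) stop_invalid("need at least 3 diagram points")
  cand <- diagram
  if (!include_endpoints) {
    cand <- cand[cand$fraction > 0 & cand$fraction < 1, , drop = FALSE]
    if (nrow(cand) == 0L) stop_invalid("no interior compositions in diagram")
  }
  tmin <- min(cand$melting_point)
  tied <- cand$fraction[cand$melting_point == tmin]
  best <- tied[which.min(abs(tied - 0.5))]
  structure(list(fraction = best, temperature = tmin, tied_fractions = tied),
            class = "eutectic_point")
}

#' @export
print.eutectic_point <- function(x, ...) {
  cat(sprintf("<eutectic_point> %.1f C at fraction %.2f", x$temperature, x$fraction))
  if (length(x$tied_fractions) > 1L) {
    cat(" (ties:", paste(x$tied_fractions, collapse = ", "), ")")
  }
  cat("\n")
  invisible(x)
}

#' Hildebrand (ideal-solubility) parameters for a binary pair
#'
#' The ideal-solubility model predicts the liquidus of each component from
#' its pure melting temperature and enthalpy of fusion alone.
#'
#' @param T_m Named numeric vector of length 2: pure melting temperatures
#'   (K) of components A and B.
#' @param dH_f Named numeric vector of length 2: enthalpies of fusion
#'   (J/mol), same order.
#' @param R Gas constant (J/(mol K)).
#' @return A `hildebrand_params` list.
#' @export
hildebrand_params <- function(T_m, dH_f, R = 8.314462618) {
  T_m <- as.numeric(T_m); dH_f <- as.numeric(dH_f)
  if (length(T_m) != 2L || length(dH_f) != 2L ||
      any(!is.finite(c(T_m, dH_f))) || any(T_m <= 0) || any(dH_f <= 0)) {
    stop_invalid("need two positive melting temperatures (K) and enthalpies (J/mol)")
  }
  structure(list(T_m = T_m, dH_f = dH_f, R = R), class = "hildebrand_params")
}

#' Ideal-solubility liquidus temperature of one component
#'
#' Solves the ideal-solubility relation
#' `ln x = (dH_f / R) * (1 / T_m - 1 / T)` for the temperature `T` at which
#' a liquid of mole fraction `x` of the component is in equilibrium with the
#' pure solid.  The closed form is
#' `T = 1 / (1 / T_m - R * ln(x) / dH_f)`; at `x = 1` it returns `T_m`
#' exactly and for `x < 1` it is strictly below `T_m`.
#'
#' @param params A [hildebrand_params].
#' @param component `1`/`"A"` or `2`/`"B"`.
#' @param x Mole fraction(s) of the component, in (0, 1].
#' @return Temperature(s) in K.
#' @examples
#' p <- hildebrand_params(T_m = c(310, 305), dH_f = c(1e5, 9e4))
#' hildebrand_temperature(p, 1, 1)     # 310, the pure melting point
#' @export
hildebrand_temperature <- function(params, component, x) {
  stopifnot(inherits(params, "hildebrand_params"))
  comp <- if (is.character(component)) match(toupper(component), c("A", "B"))
          else as.integer(component)
  if (is.na(comp) || !comp %in% 1:2) stop_invalid("`component` must be A/B or 1/2")
  x <- as.numeric(x)
  if (any(!is.finite(x)) || any(x <= 0) || any(x > 1)) {
    stop_invalid("mole fractions must lie in (0, 1]")
  }
  1 / (1 / params$T_m[comp] - params$R * log(x) / params$dH_f[comp])
}

#' Hildebrand liquidus over a composition grid
#'
#' Evaluates both components' ideal-solubility branches over the grid (the
#' fraction axis refers to component A, so component B enters at `1 - x`)
#' and takes the upper envelope `max(T_A(x), T_B(1 - x))` as the predicted
#' liquidus.  The branch crossing, where the stable solid switches from B to
#' A, is the model's eutectic composition and is reported alongside.
#'
#' @param params A [hildebrand_params].
#' @param grid Fractions of component A strictly inside (0, 1); the pure
#'   endpoints are added automatically.
#' @param pair Pair label for the resulting diagram.
#' @return A [phase_diagram] (temperatures in degrees C, source
#'   `"hildebrand"`) with the model eutectic (`fraction`, `temperature_C`)
#'   stored in the `"eutectic"` attribute.
#' @export
hildebrand_liquidus <- function(params, grid = seq(0.05, 0.95, by = 0.05),
                                pair = "A/B") {
  stopifnot(inherits(params, "hildebrand_params"))
  grid <- sort(unique(as.numeric(grid)))
  if (any(grid <= 0) || any(grid >= 1)) {
    stop_invalid("`grid` must lie strictly inside (0, 1)")
  }
  x <- c(0, grid, 1)
  TA <- c(NA_real_, hildebrand_temperature(params, 1L, grid), params$T_m[1L])
  TB <- c(params$T_m[2L], hildebrand_temperature(params, 2L, 1 - grid), NA_real_)
  liq <- pmax(TA, TB, na.rm = TRUE)
  # eutectic: crossing of the two branches, T_A(x) = T_B(1 - x)
  gap <- function(x) hildebrand_temperature(params, 1L, x) -
    hildebrand_temperature(params, 2L, 1 - x)
  root <- stats::uniroot(gap, interval = c(1e-9, 1 - 1e-9), tol = 1e-12)
  out <- phase_diagram(x, kelvin_to_celsius(liq), pair = pair,
                       source = "hildebrand")
  attr(out, "eutectic") <- list(
    fraction = root$root,
    temperature_C = kelvin_to_celsius(hildebrand_temperature(params, 1L, root$root)))
  out
}

#' Read a melting-point table into phase diagrams
#'
#' Parses a CSV laid out like the simulated melting-point table: a `ratio`
#' column of `"A/B"` percentage labels (`"0/100"` ... `"100/0"`) and one
#' column per binary system.  The packaged copy of that table is at
#' `system.file("extdata", "simulated_melting_points.csv", package = "tagmelt")`.
#'
#' @param path CSV path.
#' @return Named list of [phase_diagram] objects, one per system column.
#' @export
read_melting_table <- function(path) {
  if (!file.exists(path)) stop_format("no such file: ", path)
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"ratio" %in% names(tab) || ncol(tab) < 2L) {
    stop_format("expected a `ratio` column plus one column per binary system")
  }
  frac <- vapply(strsplit(tab$ratio, "/", fixed = TRUE), function(p) {
    if (length(p) != 2L) stop_format("malformed ratio label: ", paste(p, collapse = "/"))
    as.numeric(p[1L]) / 100
  }, numeric(1L))
  systems <- setdiff(names(tab), "ratio")
  out <- lapply(systems, function(s) {
    phase_diagram(frac, tab[[s]], pair = s, source = "simulated")
  })
  names(out) <- systems
  out
}
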