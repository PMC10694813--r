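# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards.  Keeps user-facing functions from
# clobbering the session RNG while staying dependency-free.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  env <- globalenv()
  had_seed <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Wrap coordinates into [0, box) per axis.  `x` is an n x 3 matrix (or a
# length-3 vector), `box` a length-3 vector of positive edge lengths.
wrap_coords <- function(x, box) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 3L)
  stopifnot(ncol(x) == 3L, length(box) == 3L, all(box > 0))
  x - sweep(floor(sweep(x, 2L, box, "/")), 2L, box, "*")
}

# Minimum-image displacement(s) for a rectangular periodic box.
minimum_image <- function(dx, box) {
  if (is.null(dim(dx))) dx <- matrix(dx, ncol = 3L)
  dx - sweep(round(sweep(dx, 2L, box, "/")), 2L, box, "*")
}

stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("tagmelt_invalid_argument", "error")))
}

stop_format <- function(...) {
  stop(errorCondition(paste0(...), class = c("tagmelt_format_error", "error")))
}

stop_constraint <- function(...) {
  stop(errorCondition(paste0(...), class = c("tagmelt_constraint_failure", "error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

kelvin_to_celsius <- function(K) K - 273.15
celsius_to_kelvin <- function(C) C + 273.15
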