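# Internal helpers shared across modules.

#' Derive a reproducible integer seed for a named substream
#'
#' All randomness in the package flows from a single user seed; each module
#' draws from its own named substream so that, e.g., re-simulating weather
#' does not perturb the marker draw. The substream seed is a deterministic
#' 31-bit hash of (seed, name).
#'
#' @param seed Integer master seed.
#' @param name Character substream label (e.g. `"markers"`, `"weather"`).
#' @return A single integer in `[0, 2^31 - 2]`.
#' @keywords internal
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  codes <- as.integer(charToRaw(paste0(name, ":", format(seed, scientific = FALSE))))
  h <- 0
  for (cc in codes) h <- (h * 131 + cc) %% 2147483647
  as.integer(h)
}

# Evaluate `expr` under a local RNG state seeded from (seed, name); restores
# the caller's RNG afterwards so package calls never disturb user code.
with_substream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, name))
  expr
}

# Stop with a message naming the offending field.
check_that <- function(ok, field, msg) {
  if (!isTRUE(ok)) {
    abort(sprintf("invalid `%s`: %s", field, msg), class = "phenocast_config_error")
  }
  invisible(TRUE)
}

# Nearest index of `x` in a sorted grid.
nearest_index <- function(grid, x) {
  vapply(x, function(v) which.min(abs(grid - v)), integer(1))
}

# Fisher-Yates style sample of indices that is stable across R versions.
shuffle <- function(n) sample.int(n, n, replace = FALSE)
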