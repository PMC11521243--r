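#' Round half away from zero
#'
#' Commercial ("half-up") rounding as used throughout SeDeM reporting, where
#' base R's `round()` rounds half to even. All chained computations in the
#' package use unrounded values; this is applied only at the reporting stage.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(c(0.125, 4.4998, 6.315), 2)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  # small guard against representation error just below a .5 boundary
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Truncate to a fixed number of decimals
#'
#' Drops (never rounds) decimals beyond `digits`, the display convention of
#' the bundled formulation-composition tables.
#'
#' @param x numeric vector.
#' @param digits decimals to keep.
#' @return truncated numeric vector.
#' @export
#' @examples
#' trunc_dec(c(56.24264, 219.78021), 3)
trunc_dec <- function(x, digits = 3) {
  p <- 10^digits
  trunc(x * p + sign(x) * 1e-9) / p
}

# Evaluate code under a fixed, named RNG state and restore the caller's state.
# One fixed generator (Mersenne-Twister / Inversion / Rejection) so synthetic
# fixtures are portable across platforms and sessions.
with_fixed_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("'seed' must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  code
}

stopifnot_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop(sprintf("'%s' must be a single finite number in [%s, %s]",
                 name, format(lower), format(upper)), call. = FALSE)
  }
  invisible(x)
}
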