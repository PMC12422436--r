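#' @keywords internal
"_PACKAGE"

#' Round half away from zero at a given number of decimals
#'
#' Display rounding used throughout the reporting surface: 95.675 rounds to
#' 95.68, matching conventional table formatting rather than base R's
#' round-half-even. A tiny epsilon guards against values such as 96.545
#' being stored as 96.54499999999999.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 2).
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

#' Derive a child seed from a base seed and a label
#'
#' Deterministically maps (seed, label parts) to an integer in [1, 2^31 - 2]
#' so that independent components (per-image rendering, per-fold selector
#' fits, dropout streams) draw from decorrelated but reproducible streams.
#'
#' @param seed base integer seed.
#' @param ... further integers or strings mixed into the derivation.
#' @return a single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  parts <- list(...)
  h <- as.numeric(seed) %% 2147483647
  for (p in parts) {
    if (is.character(p)) p <- sum(utf8ToInt(p) * seq_along(utf8ToInt(p)))
    for (v in as.numeric(p)) {
      h <- (h * 48271 + (v %% 2147483647) + 11) %% 2147483647
    }
  }
  as.integer(h %% 2147483645 + 1)
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

stop_mismatch <- function(what, expected, got) {
  stop(sprintf("%s: expected %s, got %s", what,
               paste(expected, collapse = "x"), paste(got, collapse = "x")),
       call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
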