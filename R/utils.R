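#' Run code with a temporary, restorable RNG seed
#'
#' Evaluates `code` after seeding the global RNG with `seed`, then restores
#' whatever RNG state existed before the call. With `seed = NULL` the code
#' runs on the current RNG stream.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Fisher-Pearson skewness coefficient
#'
#' Standardised third central moment g1 (uncorrected), the conventional
#' default for describing the asymmetry of selection-coefficient and
#' promoter-activity distributions.
#'
#' @param x numeric vector (length >= 2).
#' @return numeric skewness.
#' @export
sample_skewness <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 2)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 == 0) return(NaN)
  mean((x - m)^3) / s2^1.5
}

# argument checkers ---------------------------------------------------------

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0))
    stop(sprintf("`%s` must be finite and non-negative", name), call. = FALSE)
  invisible(x)
}

check_pos <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0))
    stop(sprintf("`%s` must be finite and positive", name), call. = FALSE)
  invisible(x)
}
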