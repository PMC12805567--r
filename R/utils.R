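#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom stats sd setNames runif rnorm
#' @importFrom utils head tail
NULL

vnorm <- function(x) sqrt(sum(x * x))

unit <- function(x) {
  n <- vnorm(x)
  if (n <= 0) abort("zero-length vector cannot be normalized")
  x / n
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Coulomb constant in kJ mol^-1 nm e^-2 (vacuum)
COULOMB_KE <- 138.935458

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort(sprintf("`%s` must be a finite numeric scalar", name))
  if (positive && x <= 0)
    abort(sprintf("`%s` must be > 0", name))
  invisible(x)
}
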