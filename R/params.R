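#' Division parameters: asymmetry fraction and quiescence threshold
#'
#' Validates the pair of dimensionless parameters that govern the model: the
#' asymmetry fraction `p` (fraction of the cell-cycle factor inherited by one
#' daughter, the other receiving `1 - p`) and the threshold `phi` (content, as
#' a fraction of the founder cell's content, below which a cell permanently
#' exits the cell cycle).
#'
#' Because the two daughters are interchangeable, `p` and `1 - p` describe the
#' same division; `p` is canonicalised into `(0, 0.5]`. A threshold of zero
#' would allow unbounded growth and is rejected.
#'
#' @param p Asymmetry fraction, strictly between 0 and 1.
#' @param phi Quiescence threshold, in `(0, 1]`.
#'
#' @return An object of class `division_params`: a list with elements `p`
#'   (canonicalised into `(0, 0.5]`) and `phi`.
#'
#' @examples
#' division_params(0.25, 0.5)
#' division_params(0.6, 0.5) # p canonicalised to 0.4
#' @export
division_params <- function(p, phi) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p <= 0 || p >= 1) {
    abort("asymmetry fraction `p` must be a single number strictly between 0 and 1")
  }
  if (!is.numeric(phi) || length(phi) != 1L || is.na(phi) || phi <= 0) {
    abort("threshold must be positive")
  }
  if (phi > 1) {
    abort("threshold `phi` must be at most 1 (it is a fraction of the founder content)")
  }
  if (p > 0.5) p <- 1 - p
  structure(list(p = as.numeric(p), phi = as.numeric(phi)), class = "division_params")
}

#' @export
print.division_params <- function(x, ...) {
  cat(sprintf("<division_params> p = %g, phi = %g\n", x$p, x$phi))
  invisible(x)
}

# Canonicalise a vector of p values (used by grid sweeps, where per-element
# division_params() calls would be wasteful).
canonicalize_p <- function(p) {
  if (any(!is.finite(p) | p <= 0 | p >= 1)) {
    abort("asymmetry fraction `p` must lie strictly between 0 and 1")
  }
  ifelse(p > 0.5, 1 - p, p)
}

check_phi <- function(phi) {
  if (any(!is.finite(phi) | phi <= 0)) abort("threshold must be positive")
  if (any(phi > 1)) abort("threshold `phi` must be at most 1")
  phi
}
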