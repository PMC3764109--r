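#' Classify a growth curve as linear or non-linear
#'
#' A lineage's topology is summarised by its growth curve, the population
#' size `N(t)` after each synchronous iteration. The *linear* topology is the
#' one in which exactly one cell divides per iteration, i.e. `N(t) = t + 1`
#' for every `t`; any curve that breaks this relation at even a single
#' iteration is *non-linear*.
#'
#' @param curve A growth curve (integer vector starting at 1, strictly
#'   increasing, at most doubling per step) or a [lineage_tree][grow_lineage].
#' @return `"linear"` or `"nonlinear"`.
#' @examples
#' classify_topology(c(1, 2, 3, 4)) # linear
#' classify_topology(c(1, 2, 4))    # nonlinear
#' @export
classify_topology <- function(curve) {
  curve <- validate_growth_curve(curve)
  if (all(curve == seq_along(curve))) "linear" else "nonlinear"
}

#' Completion duration of a growth curve
#'
#' The number of synchronous iterations `T` taken to reach the final
#' population size. A linear curve reaching `N_f` cells has `T = N_f - 1`;
#' every non-linear curve completes in fewer iterations.
#'
#' @inheritParams classify_topology
#' @return Non-negative integer `T`.
#' @examples
#' completion_duration(c(1, 2, 4)) # 2
#' @export
completion_duration <- function(curve) {
  curve <- validate_growth_curve(curve)
  length(curve) - 1L
}

validate_growth_curve <- function(curve) {
  if (inherits(curve, "lineage_tree")) curve <- curve$growth_curve
  if (length(curve) == 0L) abort("empty growth curve")
  if (!is.numeric(curve) || any(is.na(curve))) abort("growth curve must be numeric and complete")
  if (curve[1L] != 1L) abort("growth curve must start at N(0) = 1")
  if (length(curve) > 1L) {
    d <- diff(curve)
    if (any(d <= 0)) abort("growth curve must be strictly increasing")
    if (any(curve[-1L] > 2 * curve[-length(curve)])) {
      abort("growth curve may at most double per iteration")
    }
  }
  as.integer(curve)
}
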