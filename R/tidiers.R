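#' Tidy a lineage tree into its node table
#'
#' @param x A [lineage_tree][grow_lineage].
#' @param ... Unused.
#' @return A tibble with one row per cell (`node_id`, `parent_id`,
#'   `content`, `generation`, `divided`).
#' @export
tidy.lineage_tree <- function(x, ...) {
  x$nodes
}

#' One-row summary of a lineage tree
#'
#' @inheritParams tidy.lineage_tree
#' @return A one-row tibble: `engine`, `p`, `phi`, `n0`, `final_size`,
#'   `duration`, `topology`.
#' @export
glance.lineage_tree <- function(x, ...) {
  tibble(
    engine = x$engine, p = x$p, phi = x$phi, n0 = x$n0,
    final_size = x$final_size, duration = x$duration,
    topology = classify_topology(x$growth_curve)
  )
}

#' Tidy a replicate size distribution
#'
#' @param x A [size_distribution][simulate_size_distribution].
#' @param ... Unused.
#' @return A tibble with columns `nf`, `count`, `prop`.
#' @export
tidy.size_distribution <- function(x, ...) {
  x$counts
}

#' One-row summary of a replicate size distribution
#'
#' @inheritParams tidy.size_distribution
#' @return A one-row tibble: `p`, `phi`, `n0`, `reps`, `mode`, `confidence`,
#'   `prop_linear`.
#' @export
glance.size_distribution <- function(x, ...) {
  tibble(
    p = x$p, phi = x$phi, n0 = x$n0, reps = x$reps,
    mode = x$mode, confidence = x$confidence, prop_linear = x$prop_linear
  )
}

#' One-row summary of a deterministic map
#'
#' @param x A `det_map` from [sweep_deterministic()].
#' @param ... Unused.
#' @return A one-row tibble: grid size, mesh, size range, fraction linear,
#'   maximum topology variety and the size attaining it.
#' @export
glance.det_map <- function(x, ...) {
  tv <- topology_variety(x)
  tibble(
    n_pairs = nrow(x), mesh = attr(x, "mesh") %||% NA_real_,
    min_nf = min(x$nf), max_nf = max(x$nf),
    frac_linear = mean(x$topology == "linear"),
    max_variety = attr(tv, "max_variety"),
    argmax_variety_nf = attr(tv, "argmax_nf")[1L]
  )
}

#' One-row summary of a stochastic sweep
#'
#' @param x A `conf_map` from [sweep_stochastic()].
#' @param ... Unused.
#' @return A one-row tibble: grid size, `n0`, `reps`, fraction of usable
#'   pairs, mean confidence, fraction high-confidence (> 0.9), largest
#'   high-confidence mode.
#' @export
glance.conf_map <- function(x, ...) {
  cen <- high_confidence_census(x)
  ok <- x$ok
  tibble(
    n_pairs = nrow(x), n0 = attr(x, "n0"), reps = attr(x, "reps"),
    frac_ok = mean(ok),
    mean_confidence = mean(x$confidence[ok]),
    frac_high = mean(x$confidence[ok] > 0.9),
    max_high_conf_nf = attr(cen, "max_nf")
  )
}
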