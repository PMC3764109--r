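#' Regular grid over the division-parameter plane
#'
#' Builds the uniform mesh over `p` in `(0, 0.5]` and `phi` in `(0, 1]` used
#' by the parameter sweeps: `p` takes values `mesh, 2*mesh, ..., 0.5` and
#' `phi` takes `mesh, 2*mesh, ..., 1`. Zero is excluded (both parameters are
#' degenerate there), the upper bounds are included.
#'
#' @param mesh Mesh size in `(0, 0.5]`; must divide 0.5 evenly. The reference
#'   resolution for the full analyses is 0.0025 (80,000 pairs).
#' @return A tibble with columns `p` and `phi` (one row per pair, `phi`
#'   varying fastest) and attribute `mesh`.
#' @examples
#' param_grid(0.25)
#' nrow(param_grid(0.0025)) # 80,000
#' @export
param_grid <- function(mesh) {
  if (!is.numeric(mesh) || length(mesh) != 1L || is.na(mesh) || mesh <= 0 || mesh > 0.5) {
    abort("`mesh` must be a single value in (0, 0.5]")
  }
  k <- 0.5 / mesh
  if (abs(k - round(k)) > 1e-8) abort("`mesh` must divide 0.5 evenly to tile (0, 0.5]")
  k <- as.integer(round(k))
  grid <- tidyr::expand_grid(p = mesh * seq_len(k), phi = mesh * seq_len(2L * k))
  attr(grid, "mesh") <- mesh
  grid
}

as_param_grid <- function(grid) {
  if (is.numeric(grid) && length(grid) == 1L) grid <- param_grid(grid)
  if (!is.data.frame(grid) || !all(c("p", "phi") %in% names(grid))) {
    abort("`grid` must be a mesh size or a data frame with columns `p` and `phi`")
  }
  grid
}

#' Deterministic parameter-plane sweep
#'
#' Runs the deterministic engine at every grid pair and records the final
#' population size, the completion duration and the growth-curve topology
#' class. Small final sizes occupy large regions of the plane (a quarter of
#' it yields `N_f = 2`); arbitrarily large sizes exist but in vanishingly
#' small regions at low `p` and/or low `phi`.
#'
#' @param grid A mesh size (passed to [param_grid()]) or a data frame with
#'   columns `p`, `phi`.
#' @inheritParams grow_lineage
#' @return A tibble of class `det_map` with columns `p`, `phi`, `nf`,
#'   `duration`, `topology` (`"linear"`/`"nonlinear"`).
#' @examples
#' dm <- sweep_deterministic(0.05)
#' dplyr::filter(dm, p == 0.5, phi == 0.3) # N_f = 4 in 2 iterations
#' @export
sweep_deterministic <- function(grid, max_iter = 1e5, max_cells = 1e6) {
  grid <- as_param_grid(grid)
  p <- canonicalize_p(grid$p)
  phi <- check_phi(grid$phi)
  res <- cpp_sweep_det(p, phi, as.integer(max_iter), as.double(max_cells))
  out <- tibble(
    p = p, phi = phi,
    nf = res$nf, duration = res$duration,
    topology = ifelse(res$linear, "linear", "nonlinear")
  )
  structure(out,
    mesh = attr(grid, "mesh"), max_iter = max_iter, max_cells = max_cells,
    class = c("det_map", class(out))
  )
}

#' Histogram of final sizes over a deterministic map
#'
#' Counts, for each distinct final population size, how many grid pairs
#' produce it — the likelihood of hitting a size when drawing parameters
#' uniformly. Counts sum to the grid size and drop rapidly with `N_f`.
#'
#' @param map A `det_map` from [sweep_deterministic()].
#' @return A tibble with columns `nf` and `n_pairs`, ascending in `nf`.
#' @export
size_histogram <- function(map) {
  stopifnot(inherits(map, "det_map"))
  dplyr::count(as_tibble(map), .data$nf, name = "n_pairs")
}

#' Topology variety per final size
#'
#' For each final population size, counts the number of distinct completion
#' durations among the grid pairs producing it — the number of distinct
#' growth-curve lengths, a coarse census of tree topologies. Variety grows
#' with `N_f` (bigger trees admit more shapes) while the number of parameter
#' pairs shrinks, so the variety peaks at an intermediate size.
#'
#' @inheritParams size_histogram
#' @return A tibble with columns `nf` and `variety`, with attributes
#'   `max_variety` and `argmax_nf` (the size(s) attaining the maximum).
#' @export
topology_variety <- function(map) {
  stopifnot(inherits(map, "det_map"))
  out <- dplyr::summarise(
    dplyr::group_by(as_tibble(map), .data$nf),
    variety = dplyr::n_distinct(.data$duration),
    .groups = "drop"
  )
  mx <- max(out$variety)
  structure(out, max_variety = mx, argmax_nf = out$nf[out$variety == mx],
            class = class(out))
}

#' Parameter region producing a given final size, grouped by growth curve
#'
#' Returns every grid pair of a deterministic map whose final size equals
#' `nf`, re-deriving each pair's full growth curve and grouping pairs that
#' share the exact curve (the curve uniquely identifies the tree topology
#' under synchronous growth). Separate groups correspond to disconnected
#' regions of parameter space producing the same size by different growth
#' mechanisms.
#'
#' @inheritParams size_histogram
#' @param nf Target final population size.
#' @return A tibble with columns `p`, `phi`, `duration`, `curve_id` (integer,
#'   1 = most populous curve group), `curve_key` (curve as a string) and
#'   `curve` (list column of integer vectors). Zero rows if no grid pair
#'   produces `nf`.
#' @examples
#' dm <- sweep_deterministic(0.05)
#' rg <- size_region(dm, 2) # the triangle phi > 1 - p
#' @export
size_region <- function(map, nf) {
  stopifnot(inherits(map, "det_map"))
  sub <- dplyr::filter(as_tibble(map), .data$nf == !!nf)
  max_iter <- attr(map, "max_iter") %||% 1e5
  max_cells <- attr(map, "max_cells") %||% 1e6
  if (nrow(sub) == 0L) {
    return(tibble(p = double(), phi = double(), duration = integer(),
                  curve_id = integer(), curve_key = character(), curve = list()))
  }
  curves <- purrr::map2(sub$p, sub$phi, function(p, phi) {
    cpp_curve_det(p, phi, as.integer(max_iter), as.double(max_cells))
  })
  key <- vapply(curves, paste, character(1), collapse = ",")
  sizes <- sort(table(key), decreasing = TRUE)
  id <- match(key, names(sizes))
  out <- tibble(
    p = sub$p, phi = sub$phi, duration = sub$duration,
    curve_id = id, curve_key = key, curve = curves
  )
  dplyr::arrange(out, .data$curve_id, .data$p, .data$phi)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
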