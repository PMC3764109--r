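#' Stochastic parameter-plane sweep (mode and confidence of the final size)
#'
#' Runs the binomial-partitioning engine `reps` times at every grid pair and
#' records the modal final population size and its confidence (fraction of
#' replicates attaining the mode). The topology class of a pair is the
#' majority class over its replicate growth curves. Grid pairs where a
#' replicate hits a growth cap (e.g. `phi * n0 <= 1`, where a lone molecule
#' re-divides forever) are recorded as missing with a reason rather than
#' aborting the sweep.
#'
#' Each grid pair receives its own RNG substream, derived once from the
#' current RNG state (or from `seed` when supplied), so any single pair can
#' be reproduced in isolation.
#'
#' @inheritParams sweep_deterministic
#' @param n0 Founder molecule count (default 10,000, the reference value for
#'   the main stochastic analyses).
#' @param reps Replicates per grid pair (default 100).
#' @param seed Optional master seed.
#' @return A tibble of class `conf_map` with columns `p`, `phi`, `mode`,
#'   `confidence`, `topology`, `ok`, `reason`, and attributes `n0`, `reps`,
#'   `mesh`.
#' @examples
#' cm <- sweep_stochastic(param_grid(0.1), n0 = 1000, reps = 25, seed = 1)
#' @export
sweep_stochastic <- function(grid, n0 = 10000L, reps = 100L, seed = NULL,
                             max_iter = 1e5, max_cells = 1e6) {
  grid <- as_param_grid(grid)
  p <- canonicalize_p(grid$p)
  phi <- check_phi(grid$phi)
  n0 <- as.integer(n0)
  reps <- as.integer(reps)
  stopifnot(n0 >= 1L, reps >= 1L)
  n <- length(p)
  seeds <- derive_seeds(n, seed)
  mode_v <- integer(n)
  conf_v <- double(n)
  topo_v <- character(n)
  ok_v <- logical(n)
  reason_v <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    set.seed(seeds[i])
    raw <- cpp_stoch_reps(p[i], phi[i], n0, reps, as.integer(max_iter), as.double(max_cells))
    if (any(raw$cap)) {
      mode_v[i] <- NA_integer_
      conf_v[i] <- NA_real_
      topo_v[i] <- NA_character_
      ok_v[i] <- FALSE
      reason_v[i] <- sprintf("growth cap hit in replicate %d", which(raw$cap)[1L])
    } else {
      tab <- tabulate_mode(raw$nf)
      mode_v[i] <- tab$mode
      conf_v[i] <- tab$count / reps
      topo_v[i] <- if (sum(raw$linear) > reps / 2) "linear" else "nonlinear"
      ok_v[i] <- TRUE
    }
  }
  out <- tibble(
    p = p, phi = phi, mode = mode_v, confidence = conf_v,
    topology = topo_v, ok = ok_v, reason = reason_v
  )
  structure(out,
    n0 = n0, reps = reps, mesh = attr(grid, "mesh"), seed = seed,
    class = c("conf_map", class(out))
  )
}

# modal value with ties broken toward the smallest nf
tabulate_mode <- function(nf) {
  tab <- table(nf)
  vals <- as.integer(names(tab))
  cnt <- as.integer(tab)
  best <- which.max(cnt) # table() sorts values ascending; first max = smallest
  list(mode = vals[best], count = cnt[best])
}

#' Census of high-confidence final sizes
#'
#' Counts, per final population size, the grid pairs of a stochastic sweep
#' whose modal size equals it with confidence strictly above `threshold`.
#' These are the sizes a noisy lineage can hit reliably; the largest of them
#' is attached as attribute `max_nf`.
#'
#' @param cmap A `conf_map` from [sweep_stochastic()].
#' @param threshold Confidence cut-off (strict inequality), default 0.9.
#' @return A tibble with columns `nf` and `n_pairs` (ascending `nf`),
#'   attribute `max_nf` (`NA` if the census is empty).
#' @export
high_confidence_census <- function(cmap, threshold = 0.9) {
  stopifnot(inherits(cmap, "conf_map"))
  hi <- dplyr::filter(as_tibble(cmap), .data$ok, .data$confidence > threshold)
  out <- dplyr::count(hi, nf = .data$mode, name = "n_pairs")
  structure(out,
    max_nf = if (nrow(out)) max(out$nf) else NA_integer_,
    threshold = threshold, n0 = attr(cmap, "n0"),
    class = class(out)
  )
}

#' High-confidence census across founder molecule counts
#'
#' Repeats [sweep_stochastic()] + [high_confidence_census()] for each founder
#' count in `n0_list`. Because `n0` sets the magnitude of segregation noise,
#' the census expands with `n0`; *special* sizes (e.g. 41) acquire
#' high-confidence parameter pairs at founder counts where their neighbours
#' (40, 42) have none, and their emergence is sporadic rather than monotone.
#'
#' @inheritParams sweep_stochastic
#' @param n0_list Ascending vector of founder molecule counts.
#' @param threshold Confidence cut-off (strict), default 0.9.
#' @return A tibble with columns `n0`, `nf`, `n_pairs`.
#' @export
census_vs_n0 <- function(grid, n0_list, reps = 100L, threshold = 0.9,
                         seed = NULL, max_iter = 1e5, max_cells = 1e6) {
  grid <- as_param_grid(grid)
  if (is.unsorted(n0_list)) abort("`n0_list` must be sorted ascending")
  seeds <- derive_seeds(length(n0_list), seed)
  purrr::list_rbind(purrr::imap(as.list(as.integer(n0_list)), function(n0, i) {
    cm <- sweep_stochastic(grid, n0 = n0, reps = reps, seed = seeds[i],
                           max_iter = max_iter, max_cells = max_cells)
    cen <- high_confidence_census(cm, threshold = threshold)
    if (nrow(cen) == 0L) {
      tibble(n0 = integer(), nf = integer(), n_pairs = integer())
    } else {
      tibble(n0 = n0, nf = cen$nf, n_pairs = cen$n_pairs)
    }
  }))
}

#' Confidence summary by growth-curve topology
#'
#' Summarises, separately for linear and non-linear grid pairs of a
#' stochastic sweep, the fraction achieving high confidence and the fraction
#' achieving perfect (100%) confidence. A topology class absent from the map
#' is absent from the output (undefined, not zero).
#'
#' @inheritParams high_confidence_census
#' @return A tibble with one row per topology class present: `topology`,
#'   `n_pairs`, `frac_high` (confidence strictly above `threshold`),
#'   `frac_perfect` (confidence exactly 1).
#' @export
topology_confidence_summary <- function(cmap, threshold = 0.9) {
  stopifnot(inherits(cmap, "conf_map"))
  ok <- dplyr::filter(as_tibble(cmap), .data$ok)
  dplyr::summarise(
    dplyr::group_by(ok, .data$topology),
    n_pairs = dplyr::n(),
    frac_high = mean(.data$confidence > threshold),
    frac_perfect = mean(.data$confidence == 1),
    .groups = "drop"
  )
}

#' Deterministic vs stochastic divergence
#'
#' Compares a deterministic map and a stochastic sweep over the same grid:
#' per pair, the absolute difference between the deterministic final size
#' and the stochastic modal size. The overall fraction of identical pairs is
#' attached as attribute `identity_fraction` (capped/missing stochastic
#' pairs count as non-identical). Divergence concentrates on borders between
#' deterministic size regions and near the origin where sizes are large.
#'
#' @param dmap A `det_map`.
#' @param cmap A `conf_map` over the identical grid.
#' @return A tibble `p`, `phi`, `nf_det`, `mode`, `abs_diff` with attribute
#'   `identity_fraction`.
#' @export
det_stoch_divergence <- function(dmap, cmap) {
  stopifnot(inherits(dmap, "det_map"), inherits(cmap, "conf_map"))
  if (nrow(dmap) != nrow(cmap) ||
      !isTRUE(all.equal(dmap$p, cmap$p)) || !isTRUE(all.equal(dmap$phi, cmap$phi))) {
    abort("`dmap` and `cmap` must be computed over the identical grid")
  }
  out <- tibble(
    p = dmap$p, phi = dmap$phi,
    nf_det = dmap$nf, mode = cmap$mode,
    abs_diff = abs(dmap$nf - cmap$mode)
  )
  structure(out,
    identity_fraction = mean(!is.na(out$mode) & out$nf_det == out$mode),
    class = c("divergence_map", class(out))
  )
}
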