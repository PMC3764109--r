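#' Binomial partitioning of molecules at division
#'
#' Draws the segregation of `m` molecules between the two daughters of a
#' division: each molecule independently goes to the `p`-side daughter with
#' probability `p`, so `a ~ Binomial(m, p)` and `b = m - a`. This is the
#' noise model behind the stochastic engine.
#'
#' @param m Non-negative integer molecule count of the parent cell.
#' @param p Success probability in `[0, 1]` (not canonicalised: the two
#'   daughters are distinguishable here).
#' @param n Number of independent partitions to draw.
#' @return A tibble with `n` rows and columns `a` (`p`-side daughter) and
#'   `b = m - a`.
#' @examples
#' partition_molecules(10, 0) # always (0, 10)
#' partition_molecules(100, 0.3, n = 5)
#' @export
partition_molecules <- function(m, p, n = 1L) {
  if (!is.numeric(m) || length(m) != 1L || is.na(m) || m < 0 || m != floor(m)) {
    abort("`m` must be a single non-negative integer")
  }
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    abort("`p` must be a probability in [0, 1]")
  }
  a <- rbinom(n, size = m, prob = p)
  tibble(a = a, b = as.integer(m) - a)
}

#' Replicate distribution of the stochastic final population size
#'
#' Runs the stochastic engine `reps` times at a single `(p, phi)` pair and
#' tabulates the final population sizes. The *mode* is the most frequent
#' `N_f` (ties broken toward the smallest size) and the *confidence* is the
#' fraction of replicates attaining it.
#'
#' @inheritParams grow_lineage
#' @param reps Number of replicates (default 100).
#' @return An object of class `size_distribution`: a list with elements
#'   `counts` (tibble `nf`, `count`, `prop`), `reps`, `mode`, `confidence`,
#'   `prop_linear` (fraction of replicates with a linear growth curve), and
#'   the run settings `p`, `phi`, `n0`, `seed`.
#' @examples
#' sd <- simulate_size_distribution(0.5, 0.6, n0 = 10000, reps = 20, seed = 1)
#' glance(sd) # mode 2 with confidence 1: a 6000-molecule daughter is essentially impossible
#' @export
simulate_size_distribution <- function(p, phi, n0 = 10000L, reps = 100L,
                                       seed = NULL, max_iter = 1e5, max_cells = 1e6) {
  par <- division_params(p, phi)
  reps <- as.integer(reps)
  if (is.na(reps) || reps < 1L) abort("`reps` must be a positive integer")
  n0 <- as.integer(n0)
  if (is.na(n0) || n0 < 1L) abort("`n0` must be a positive integer")
  if (!is.null(seed)) set.seed(seed)
  raw <- cpp_stoch_reps(par$p, par$phi, n0, reps, as.integer(max_iter), as.double(max_cells))
  if (any(raw$cap)) {
    abort(sprintf(
      "runaway growth: replicate %d exceeded a growth cap at p = %g, phi = %g, n0 = %d",
      which(raw$cap)[1L], par$p, par$phi, n0
    ))
  }
  new_size_distribution(raw, par, n0, reps, seed)
}

new_size_distribution <- function(raw, par, n0, reps, seed) {
  tab <- table(raw$nf)
  nf <- as.integer(names(tab))
  count <- as.integer(tab)
  ord <- order(nf)
  counts <- tibble(nf = nf[ord], count = count[ord], prop = count[ord] / reps)
  mode_nf <- counts$nf[which.max(counts$count)] # ties -> smallest nf (counts sorted)
  structure(
    list(
      counts = counts,
      reps = reps,
      mode = mode_nf,
      confidence = max(counts$count) / reps,
      prop_linear = mean(raw$linear),
      p = par$p, phi = par$phi, n0 = n0, seed = seed
    ),
    class = "size_distribution"
  )
}

#' @export
print.size_distribution <- function(x, ...) {
  cat(sprintf(
    "<size_distribution> p = %g, phi = %g, n0 = %d, %d replicates\n  mode N_f = %d with confidence %.3f\n",
    x$p, x$phi, x$n0, x$reps, x$mode, x$confidence
  ))
  print(x$counts, n = 10)
  invisible(x)
}
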