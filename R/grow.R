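#' Grow a single lineage tree
#'
#' Grows one rooted binary lineage tree under the hourglass dilution model.
#' The founder cell carries the full complement of a cell-cycle factor; at
#' each synchronous iteration every cell at or above the quiescence threshold
#' divides, passing a fraction `p` of its content to one daughter and `1 - p`
#' to the other. Cells below the threshold are permanently quiescent. Growth
#' stops when no cell can divide.
#'
#' Three engines are available:
#' \describe{
#'   \item{`"deterministic"`}{content is a real fraction of the founder's
#'     (taken as 1); daughters receive exactly `p * x` and `(1 - p) * x`.}
#'   \item{`"stochastic"`}{content is an integer molecule count out of `n0`
#'     founder molecules; each molecule independently goes to the `p`-side
#'     daughter with probability `p` (binomial partitioning). A cell divides
#'     iff its count `m` satisfies `m / n0 >= phi`.}
#'   \item{`"perturbed"`}{as `"stochastic"`, but at every division event the
#'     effective `p` and `phi` are fresh Gaussian draws centred on their
#'     nominal values with standard deviations `sigma_p * p` and
#'     `sigma_phi * phi` (`p` clipped to `[0, 1]`, `phi` clipped below at 0).
#'     A cell that fails its eligibility test is permanently quiescent.}
#' }
#'
#' @param p,phi Division parameters; see [division_params()]. `p` is
#'   canonicalised into `(0, 0.5]`.
#' @param engine Growth engine, one of `"deterministic"`, `"stochastic"`,
#'   `"perturbed"`.
#' @param n0 Founder molecule count (stochastic engines). Default 10000.
#' @param sigma_p,sigma_phi Per-division Gaussian perturbation widths, as
#'   fractions of the mean (engine `"perturbed"`; both in `[0, 0.10]` in
#'   typical use, 0 disables the corresponding draw).
#' @param seed Optional integer seed; when given, `set.seed(seed)` is applied
#'   before growth so the tree is reproducible in isolation.
#' @param max_iter,max_cells Safety caps on synchronous iterations and total
#'   cells created; exceeding either raises a "runaway growth" error naming
#'   the offending cap.
#'
#' @return An object of class `lineage_tree`: a list with elements
#'   \describe{
#'     \item{`nodes`}{tibble with one row per cell: `node_id`, `parent_id`
#'       (`NA` for the root), `content` (fraction or molecule count),
#'       `generation` (synchronous iteration of birth), `divided`.}
#'     \item{`growth_curve`}{integer vector `N(t)`, `t = 0..T`.}
#'     \item{`final_size`}{number of quiescent cells `N_f` at termination.}
#'     \item{`duration`}{number of synchronous iterations `T`.}
#'     \item{`p`, `phi`, `engine`, `n0`, `sigma_p`, `sigma_phi`, `seed`}{run
#'       settings.}
#'   }
#'
#' @examples
#' grow_lineage(0.3, 0.5) # N_f = 3, growth curve 1, 2, 3
#' tr <- grow_lineage(0.4, 0.25, engine = "stochastic", n0 = 1000, seed = 1)
#' glance(tr)
#' @seealso [final_size()] for the fast deterministic final-size path,
#'   [simulate_size_distribution()] for replicate ensembles.
#' @export
grow_lineage <- function(p, phi,
                         engine = c("deterministic", "stochastic", "perturbed"),
                         n0 = 10000L, sigma_p = 0, sigma_phi = 0, seed = NULL,
                         max_iter = 1e5, max_cells = 1e6) {
  engine <- match.arg(engine)
  par <- division_params(p, phi)
  if (!is.null(seed)) set.seed(seed)
  if (engine == "deterministic") {
    raw <- cpp_grow_det_tree(par$p, par$phi, as.integer(max_iter), as.double(max_cells))
    n0 <- 1L
  } else {
    n0 <- as.integer(n0)
    if (is.na(n0) || n0 < 1L) abort("`n0` must be a positive integer")
    if (engine == "stochastic") {
      raw <- cpp_grow_stoch_tree(par$p, par$phi, n0, as.integer(max_iter), as.double(max_cells))
    } else {
      stopifnot(sigma_p >= 0, sigma_phi >= 0)
      raw <- cpp_grow_perturbed_tree(par$p, par$phi, sigma_p, sigma_phi, n0,
                                     as.integer(max_iter), as.double(max_cells))
    }
  }
  nodes <- tibble(
    node_id = seq_along(raw$content),
    parent_id = raw$parent,
    content = raw$content,
    generation = raw$generation,
    divided = raw$divided
  )
  structure(
    list(
      nodes = nodes,
      growth_curve = raw$curve,
      final_size = sum(!nodes$divided),
      duration = raw$duration,
      p = par$p, phi = par$phi,
      engine = engine, n0 = n0,
      sigma_p = if (engine == "perturbed") sigma_p else 0,
      sigma_phi = if (engine == "perturbed") sigma_phi else 0,
      seed = seed
    ),
    class = "lineage_tree"
  )
}

#' @export
print.lineage_tree <- function(x, ...) {
  cat(sprintf(
    "<lineage_tree> %s engine, p = %g, phi = %g%s\n  N_f = %d quiescent cells after %d iterations; %d nodes\n",
    x$engine, x$p, x$phi,
    if (x$engine == "deterministic") "" else sprintf(", n0 = %d", x$n0),
    x$final_size, x$duration, nrow(x$nodes)
  ))
  cat("  growth curve:", paste(head(x$growth_curve, 12L), collapse = " "),
      if (length(x$growth_curve) > 12L) "...\n" else "\n")
  invisible(x)
}

#' Deterministic final population size
#'
#' Fast vectorised path to the deterministic final size `N_f(p, phi)` without
#' materialising lineage trees. Exactly equivalent to
#' `grow_lineage(p, phi)$final_size` at every parameter pair.
#'
#' @param p,phi Numeric vectors of division parameters (recycled to a common
#'   length); `p` is canonicalised into `(0, 0.5]`.
#' @inheritParams grow_lineage
#' @return Integer vector of final population sizes (each at least 2).
#' @examples
#' final_size(c(0.5, 0.3, 0.1), c(0.3, 0.5, 0.5)) # 4, 3, 8
#' @export
final_size <- function(p, phi, max_iter = 1e5, max_cells = 1e6) {
  n <- max(length(p), length(phi))
  p <- canonicalize_p(rep_len(p, n))
  phi <- check_phi(rep_len(phi, n))
  res <- cpp_sweep_det(p, phi, as.integer(max_iter), as.double(max_cells))
  res$nf
}

#' Extract the growth curve of a lineage tree
#'
#' @param tree A `lineage_tree`.
#' @return Integer vector of population sizes `N(t)` for `t = 0..T`.
#' @export
growth_curve <- function(tree) {
  stopifnot(inherits(tree, "lineage_tree"))
  tree$growth_curve
}
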