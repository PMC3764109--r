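#' Final size under symmetric division
#'
#' Closed form for the deterministic final size when division is symmetric
#' (`p = 0.5`): the factor is halved at every round, so after `n` rounds each
#' cell holds `2^-n` of the founder content and growth stops at the first `n`
#' with `2^-n < phi`, giving `N_f = 2^n`. The boundary follows the engine's
#' divide-iff-`content >= phi` rule, so e.g. `phi = 0.25` still divides at
#' content 0.25 and yields 8 cells.
#'
#' @param phi Threshold(s) in `(0, 1]`.
#' @return Integer vector of final sizes (powers of two).
#' @examples
#' symmetric_final_size(c(1, 0.3, 0.25)) # 2, 4, 8
#' @export
symmetric_final_size <- function(phi) {
  phi <- check_phi(phi)
  vapply(phi, function(ph) {
    x <- 1
    n <- 0L
    while (x >= ph) {
      x <- x / 2
      n <- n + 1L
    }
    if (n > 30L) abort("final size exceeds integer range; threshold too small")
    as.integer(2^n)
  }, integer(1))
}

#' Final size of a linear (chain) lineage
#'
#' Closed form for the deterministic final size in the linear regime
#' `p < phi`, where the small daughter (content `p * (1-p)^k < phi`) never
#' divides and growth is a chain of the large daughter: the chain ends at the
#' first `n` with `(1-p)^n < phi`, giving `N_f = n + 1`. The running product
#' is accumulated by repeated multiplication so its floating-point path
#' matches the simulation engine exactly.
#'
#' @param p,phi Numeric vectors (recycled); requires `p < phi` elementwise
#'   after canonicalising `p` into `(0, 0.5]`.
#' @return Integer vector of final sizes.
#' @examples
#' linear_chain_size(0.1, 0.5) # 8
#' linear_chain_size(0.3, 0.5) # 3
#' @export
linear_chain_size <- function(p, phi) {
  n <- max(length(p), length(phi))
  p <- canonicalize_p(rep_len(p, n))
  phi <- check_phi(rep_len(phi, n))
  if (any(p >= phi)) {
    abort("linear_chain_size() requires p < phi (linear regime); use grow_lineage() or final_size() elsewhere")
  }
  cpp_linear_chain_size(p, phi)
}

#' Exact final-size distribution of the stochastic model
#'
#' Computes the distribution of the final population size `N_f` under
#' binomial partitioning exactly (up to a reported truncation), serving as an
#' independent oracle for the Monte-Carlo engine at small founder counts.
#'
#' A cell with `m < ceiling(phi * n0)` molecules contributes one quiescent
#' leaf; otherwise its leaf count is the sum of the leaf counts of daughters
#' `a ~ Binomial(m, p)` and `m - a`. The fixed-point system over
#' `m = 0..n0` is solved by depth iteration (Jacobi sweeps correspond to
#' conditioning on lineage depth); convolutions are done by FFT. Because
#' splits such as `(m, 0)` recreate the parent count, `N_f` has an infinite
#' (geometrically decaying) tail: mass beyond `max_nf` or deeper than
#' `max_depth` is reported as `truncated_mass`, not redistributed.
#'
#' @param p,phi Division parameters (scalars); `p` canonicalised.
#' @param n0 Founder molecule count; must be small (`<= 64`) and satisfy
#'   `ceiling(phi * n0) >= 2`, otherwise the process cannot terminate.
#' @param max_nf Largest final size tracked explicitly.
#' @param max_depth Cap on depth iterations.
#' @param tol Stop once successive sweeps change no probability by more.
#' @return A tibble of class `exact_size_distribution` with columns `nf` and
#'   `prob` (positive entries only), and attributes `truncated_mass`, `p`,
#'   `phi`, `n0`, `threshold`.
#' @examples
#' d <- exact_size_distribution(0.5, 0.6, n0 = 10)
#' d$prob[d$nf == 2] # 252/1024: both daughters quiescent needs a 5/5 split
#' @export
exact_size_distribution <- function(p, phi, n0, max_nf = 250L, max_depth = 400L,
                                    tol = 1e-13) {
  par <- division_params(p, phi)
  n0 <- as.integer(n0)
  if (is.na(n0) || n0 < 1L) abort("`n0` must be a positive integer")
  if (n0 > 64L) abort("exact_size_distribution() is tractable only for n0 <= 64")
  thr <- cpp_int_threshold(par$phi, n0)
  if (thr <= 1L) {
    abort("phi * n0 <= 1: a single molecule always re-divides and the process never terminates")
  }
  max_nf <- as.integer(max_nf)
  L <- 2L * max_nf + 12L # pad so exponents up to 2*max_nf never wrap
  # column m+1 holds the distribution of N_f for a cell with m molecules;
  # row k+1 is the probability of exactly k leaves
  P <- matrix(0, nrow = L, ncol = n0 + 1L)
  P[2L, seq_len(thr)] <- 1 # m < thr: one quiescent leaf
  w <- lapply(thr:n0, function(m) dbinom(0:m, m, par$p))
  keep <- c(rep(TRUE, max_nf + 1L), rep(FALSE, L - max_nf - 1L))
  depth <- 0L
  repeat {
    FT <- mvfft(P)
    newP <- P
    for (m in thr:n0) {
      acc <- complex(L)
      wm <- w[[m - thr + 1L]]
      for (a in 0:m) {
        acc <- acc + wm[a + 1L] * (FT[, a + 1L] * FT[, m - a + 1L])
      }
      col <- Re(fft(acc, inverse = TRUE)) / L
      col[col < 0] <- 0
      col[!keep] <- 0 # beyond max_nf: accounted as truncated mass
      newP[, m + 1L] <- col
    }
    delta <- max(abs(newP - P))
    P <- newP
    depth <- depth + 1L
    if (delta < tol || depth >= max_depth) break
  }
  probs <- P[, n0 + 1L][seq_len(max_nf + 1L)][-1L] # nf = 1..max_nf
  out <- tibble(nf = seq_len(max_nf), prob = probs)
  out <- out[out$prob > 1e-12, ] # drop FFT floor noise
  structure(
    out,
    truncated_mass = max(0, 1 - sum(probs)),
    p = par$p, phi = par$phi, n0 = n0, threshold = thr, depth = depth,
    class = c("exact_size_distribution", class(out))
  )
}
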