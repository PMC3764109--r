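test_that("stochastic sweeps record mode, confidence and topology per grid pair", {
  g <- param_grid(0.1)
  cm <- sweep_stochastic(g, n0 = 1000, reps = 30, seed = 21)
  expect_identical(nrow(cm), nrow(g))
  ok <- cm$ok
  expect_true(all(cm$confidence[ok] > 0 & cm$confidence[ok] <= 1))
  expect_true(all(cm$mode[ok] >= 2L))
  expect_true(all(cm$topology[ok] %in% c("linear", "nonlinear")))
  # deep inside the two-cell region noise cannot matter
  pt <- cm$p == 0.5 & abs(cm$phi - 0.6) < 1e-9
  expect_identical(cm$mode[pt], 2L)
  expect_identical(cm$confidence[pt], 1)
})

test_that("grid pairs that cannot terminate are recorded as missing, not fatal", {
  # phi * n0 = 1: a lone molecule always re-divides
  g <- tibble::tibble(p = c(0.3, 0.5), phi = c(0.01, 0.5))
  cm <- sweep_stochastic(g, n0 = 100, reps = 3, seed = 2, max_iter = 300)
  expect_false(cm$ok[1])
  expect_match(cm$reason[1], "growth cap")
  expect_true(is.na(cm$mode[1]))
  expect_true(cm$ok[2])
})

test_that("sweeps are reproducible from the master seed alone", {
  g <- param_grid(0.25)
  cm1 <- sweep_stochastic(g, n0 = 500, reps = 20, seed = 33)
  cm2 <- sweep_stochastic(g, n0 = 500, reps = 20, seed = 33)
  expect_identical(as.data.frame(cm1), as.data.frame(cm2))
})

test_that("the high-confidence census shrinks as the threshold rises", {
  g <- param_grid(0.05)
  cm <- sweep_stochastic(g, n0 = 1000, reps = 50, seed = 8)
  c50 <- high_confidence_census(cm, threshold = 0.5)
  c90 <- high_confidence_census(cm, threshold = 0.9)
  c99 <- high_confidence_census(cm, threshold = 0.99)
  tot <- function(x) sum(x$n_pairs)
  expect_gte(tot(c50), tot(c90))
  expect_gte(tot(c90), tot(c99))
  # every censused size also appears as a mode in the map
  expect_true(all(c90$nf %in% cm$mode))
  expect_identical(attr(c90, "max_nf"), max(c90$nf))
})

test_that("at tiny founder counts only the smallest sizes are high-confidence", {
  g <- param_grid(0.05)
  cen <- census_vs_n0(g, n0_list = c(10L, 1000L), reps = 40, seed = 13)
  expect_true(all(c("n0", "nf", "n_pairs") %in% names(cen)))
  small <- cen[cen$n0 == 10L, ]
  large <- cen[cen$n0 == 1000L, ]
  expect_lte(max(small$nf), 4L)
  expect_gt(max(large$nf), max(small$nf))
})

test_that("topology summaries report only classes present in the map", {
  g <- param_grid(0.05)
  cm <- sweep_stochastic(g, n0 = 1000, reps = 40, seed = 17)
  ts <- topology_confidence_summary(cm)
  expect_true(all(ts$topology %in% c("linear", "nonlinear")))
  expect_true(all(ts$frac_perfect <= ts$frac_high | ts$frac_perfect <= 1))
  expect_identical(sum(ts$n_pairs), sum(cm$ok))

  # a map reduced to one class yields one row, not a zero for the other
  one <- cm[cm$topology == "linear" & cm$ok, ]
  class(one) <- class(cm)
  attr(one, "n0") <- attr(cm, "n0")
  ts1 <- topology_confidence_summary(one)
  expect_identical(ts1$topology, "linear")
})

test_that("with minimal noise, linear lineages hit their size more reliably", {
  cm <- sweep_stochastic(param_grid(0.02), n0 = 10000, reps = 50, seed = 29)
  ts <- topology_confidence_summary(cm)
  expect_gt(ts$frac_high[ts$topology == "linear"],
            ts$frac_high[ts$topology == "nonlinear"])
})

test_that("deterministic-stochastic divergence is zero against a perfect map", {
  g <- param_grid(0.1)
  dm <- sweep_deterministic(g)
  cm <- sweep_stochastic(g, n0 = 2000, reps = 25, seed = 3)
  dv <- det_stoch_divergence(dm, cm)
  expect_identical(nrow(dv), nrow(g))
  expect_true(all(dv$abs_diff[!is.na(dv$abs_diff)] >= 0L))
  fr <- attr(dv, "identity_fraction")
  expect_true(fr >= 0 && fr <= 1)

  # divergence of a map against itself is identically zero
  self <- cm
  self$mode <- dm$nf
  dv0 <- det_stoch_divergence(dm, self)
  expect_true(all(dv0$abs_diff == 0L))
  expect_identical(attr(dv0, "identity_fraction"), 1)

  expect_error(det_stoch_divergence(dm, sweep_stochastic(param_grid(0.25), n0 = 100, reps = 5, seed = 1)),
               "identical grid")
})
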