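test_that("binomial partitioning conserves molecules and has the right moments", {
  set.seed(5)
  expect_identical(partition_molecules(10, 0, n = 5)$a, rep(0L, 5))
  expect_identical(partition_molecules(10, 0, n = 5)$b, rep(10L, 5))

  draws <- partition_molecules(500, 0.3, n = 2000)
  expect_true(all(draws$a + draws$b == 500L))

  big <- partition_molecules(10000, 0.5, n = 20000)
  # Binomial(10000, 0.5): mean 5000, variance 2500
  expect_lt(abs(mean(big$a) - 5000), 4 * sqrt(2500 / 20000))
  expect_lt(abs(var(big$a) / 2500 - 1), 0.05)

  expect_error(partition_molecules(-1, 0.5), "non-negative")
  expect_error(partition_molecules(10, 1.5), "probability")
})

test_that("a 60% threshold at n0 = 10000 collapses to two cells in every replicate", {
  # a daughter would need 6000 of Binomial(10000, 0.5): probability < 1e-80
  sd <- simulate_size_distribution(0.5, 0.6, n0 = 10000, reps = 50, seed = 1)
  expect_identical(sd$mode, 2L)
  expect_identical(sd$confidence, 1)
  expect_identical(sd$counts$nf, 2L)
})

test_that("stochastic trees conserve molecules exactly and obey the threshold rule", {
  set.seed(9)
  for (i in 1:10) {
    n0 <- sample(c(50L, 500L, 5000L), 1)
    tr <- grow_lineage(runif(1, 0.05, 0.5), runif(1, 0.05, 0.9),
                       engine = "stochastic", n0 = n0)
    expect_identical(max(abs(division_residuals(tr))), 0)
    expect_equal(sum(tr$nodes$content[!tr$nodes$divided]), as.numeric(n0))
    thr <- hourglass:::cpp_int_threshold(tr$phi, n0)
    expect_true(all(tr$nodes$content[tr$nodes$divided] >= thr))
    expect_true(all(tr$nodes$content[!tr$nodes$divided] < thr))
  }
})

test_that("a single founder molecule cycles forever and trips the iteration cap", {
  expect_error(grow_lineage(0.3, 0.5, engine = "stochastic", n0 = 1, max_iter = 500),
               "runaway growth")
  expect_error(
    simulate_size_distribution(0.3, 0.5, n0 = 1, reps = 3, max_iter = 500),
    "replicate 1"
  )
})

test_that("replicate distributions tabulate correctly and break mode ties downward", {
  sd1 <- simulate_size_distribution(0.4, 0.3, n0 = 1000, reps = 1, seed = 3)
  expect_identical(sd1$confidence, 1)
  expect_identical(sum(sd1$counts$count), 1L)

  sd <- simulate_size_distribution(0.45, 0.15, n0 = 200, reps = 200, seed = 4)
  expect_identical(sum(sd$counts$count), 200L)
  expect_equal(sd$confidence, max(sd$counts$count) / 200)

  # documented tie rule: the smallest N_f wins
  tie <- hourglass:::tabulate_mode(c(5L, 5L, 3L, 3L, 9L))
  expect_identical(tie$mode, 3L)
})

test_that("zero-molecule daughters are quiescent cells counted in the final size", {
  # p = 0.02 at small n0 throws many empty daughters
  tr <- grow_lineage(0.02, 0.4, engine = "stochastic", n0 = 20, seed = 11)
  expect_true(any(tr$nodes$content == 0))
  expect_true(all(!tr$nodes$divided[tr$nodes$content == 0]))
  expect_identical(sum(!tr$nodes$divided), tr$final_size)
})
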