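test_that("the symmetric closed form matches halving with the >= boundary rule", {
  expect_identical(symmetric_final_size(c(1, 0.3, 0.25)), c(2L, 4L, 8L))
  # grid thresholds: closed form vs engine at p = 0.5
  phis <- param_grid(0.025)$phi
  expect_identical(symmetric_final_size(phis), final_size(0.5, phis))
  expect_error(symmetric_final_size(0), "positive")
})

test_that("the linear-chain closed form matches the engine in its regime", {
  expect_identical(linear_chain_size(0.1, 0.5), 8L)  # 0.9^7 ~ 0.478 first below 0.5
  expect_identical(linear_chain_size(0.3, 0.5), 3L)  # 0.7^2 = 0.49
  expect_identical(linear_chain_size(0.25, 0.8), 2L) # 0.75 < 0.8 immediately
  g <- param_grid(0.025)
  lin <- g[g$p < g$phi, ]
  expect_identical(linear_chain_size(lin$p, lin$phi), final_size(lin$p, lin$phi))
  expect_error(linear_chain_size(0.4, 0.3), "linear regime")
})

test_that("any final size is reachable by a linear lineage at a suitable asymmetry", {
  for (target in 2:40) {
    if (target == 2L) {
      p <- 0.4 # any p with 1 - p < phi
      expect_identical(linear_chain_size(p, 0.8), 2L)
    } else {
      # choose p so that (1-p)^(target-2) >= 0.5 > (1-p)^(target-1)
      p <- 1 - 0.5^(1 / (target - 1.5))
      expect_identical(linear_chain_size(p, 0.5), as.integer(target))
    }
  }
})

test_that("the exact size distribution reproduces closed-form probabilities", {
  d <- exact_size_distribution(0.5, 0.6, n0 = 10)
  # N_f = 2 requires the unique 5/5 split: C(10,5) / 2^10
  expect_equal(d$prob[d$nf == 2], 252 / 1024, tolerance = 1e-10)
  expect_lte(sum(d$prob), 1 + 1e-9)
  expect_lt(attr(d, "truncated_mass"), 1e-9)

  # p = 0: all molecules follow one daughter; the lineage is a fixed chain
  d0 <- exact_size_distribution(0.001, 0.5, n0 = 8)
  # with phi*n0 = 4 and p ~ 0 the chain 8 -> (8,0) -> ... does not shorten:
  # mass concentrates on long chains; distribution must still be proper
  expect_lte(sum(d0$prob) + attr(d0, "truncated_mass"), 1 + 1e-9)
})

test_that("exact oracle agrees with an independent direct enumeration at tiny n0", {
  # independent oracle: enumerate the Markov chain over multisets by direct
  # dynamic programming on total probability of population states
  p <- 0.4; phi <- 0.55; n0 <- 6L
  thr <- hourglass:::cpp_int_threshold(phi, n0) # 4
  # states: population of active cells (counts >= thr) plus accumulated leaves;
  # enumerate breadth-first with pruning of negligible mass
  states <- list(list(active = c(n0), leaves = 0L, prob = 1)) # root
  dist <- numeric(64)
  for (step in 1:60) {
    nxt <- list()
    for (st in states) {
      if (length(st$active) == 0L) {
        dist[st$leaves] <- dist[st$leaves] + st$prob
        next
      }
      m <- st$active[1]
      rest <- st$active[-1]
      for (a in 0:m) {
        w <- dbinom(a, m, p)
        if (w < 1e-14) next
        kids <- c(a, m - a)
        act <- c(rest, kids[kids >= thr])
        lvs <- st$leaves + sum(kids < thr)
        nxt[[length(nxt) + 1L]] <- list(active = act, leaves = lvs, prob = st$prob * w)
      }
    }
    # merge identical states to keep the enumeration tractable
    if (length(nxt) == 0L) break
    key <- vapply(nxt, function(s) paste(c(sort(s$active), "|", s$leaves), collapse = ","), "")
    merged <- lapply(split(seq_along(nxt), key), function(ix) {
      s <- nxt[[ix[1]]]
      s$prob <- sum(vapply(ix, function(i) nxt[[i]]$prob, 0))
      s
    })
    states <- unname(merged)
  }
  resolved <- sum(dist)
  expect_gt(resolved, 0.999)
  d <- exact_size_distribution(p, phi, n0)
  for (k in which(dist > 1e-6)) {
    expect_equal(d$prob[d$nf == k], dist[k], tolerance = 1e-4)
  }
})

test_that("intractable or non-terminating oracle inputs are refused", {
  expect_error(exact_size_distribution(0.3, 0.5, n0 = 1000), "n0 <= 64")
  expect_error(exact_size_distribution(0.3, 0.1, n0 = 10), "never terminates")
})
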