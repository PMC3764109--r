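test_that("parameter grids tile (0, 0.5] x (0, 1] with zero excluded", {
  g <- param_grid(0.25)
  expect_equal(sort(unique(g$p)), c(0.25, 0.5))
  expect_equal(sort(unique(g$phi)), c(0.25, 0.5, 0.75, 1))
  expect_identical(nrow(g), 8L)

  fine <- param_grid(0.0025)
  expect_identical(nrow(fine), 80000L)
  expect_identical(length(unique(fine$p)), 200L)
  expect_identical(length(unique(fine$phi)), 400L)
  expect_equal(max(fine$p), 0.5)
  expect_equal(max(fine$phi), 1)
  expect_true(min(fine$p) > 0 && min(fine$phi) > 0)

  expect_error(param_grid(0.3), "divide 0.5 evenly")
  expect_error(param_grid(0), "\\(0, 0.5\\]")
  expect_error(param_grid(0.7), "\\(0, 0.5\\]")
})

test_that("the deterministic map records known sizes and the two-cell quarter", {
  dm <- coarse_det_map()
  expect_identical(dm$nf[dm$p == 0.5 & abs(dm$phi - 0.3) < 1e-9], 4L)
  # both daughters quiescent immediately: the triangle phi > 1 - p
  expect_true(all(dm$nf[dm$phi > 1 - dm$p] == 2L))
  # its grid area is about a quarter of the plane (coarse meshes overshoot
  # because the boundary column is included)
  frac2 <- sum(dm$nf == 2L) / nrow(dm)
  expect_gt(frac2, 0.2)
  expect_lt(frac2, 0.35)
})

test_that("the size histogram partitions the grid and favours small sizes", {
  dm <- coarse_det_map()
  h <- size_histogram(dm)
  expect_identical(sum(h$n_pairs), nrow(dm))
  expect_identical(h$n_pairs[h$nf == 2L], max(h$n_pairs))
})

test_that("topology variety counts distinct completion durations per size", {
  dm <- coarse_det_map()
  tv <- topology_variety(dm)
  expect_identical(tv$variety[tv$nf == 2L], 1L)       # only the curve c(1, 2)
  if (4L %in% tv$nf) expect_lte(tv$variety[tv$nf == 4L], 2L)  # 4 leaves: T = 2 or 3
  expect_identical(attr(tv, "max_variety"), max(tv$variety))
  expect_true(all(tv$variety[match(attr(tv, "argmax_nf"), tv$nf)] == max(tv$variety)))
})

test_that("size regions partition the grid and group pairs by exact growth curve", {
  dm <- coarse_det_map()
  expect_identical(nrow(size_region(dm, 1L)), 0L)     # N_f >= 2 always
  r2 <- size_region(dm, 2L)
  expect_identical(nrow(r2), sum(dm$nf == 2L))
  expect_true(all(vapply(r2$curve, identical, logical(1), c(1L, 2L))))
  expect_identical(unique(r2$curve_id), 1L)
  # regions across all sizes cover every grid pair exactly once
  counts <- vapply(unique(dm$nf), function(s) nrow(size_region(dm, s)), integer(1))
  expect_identical(sum(counts), nrow(dm))
})

test_that("a mid-sized target is reachable through several distinct growth curves", {
  dm <- sweep_deterministic(0.0025)
  r41 <- size_region(dm, 41L)
  expect_gt(nrow(r41), 0L)
  expect_gte(length(unique(r41$curve_key)), 2L)
  # linear and non-linear mechanisms coexist for the same final size
  topo <- vapply(r41$curve, classify_topology, character(1))
  expect_setequal(unique(topo), c("linear", "nonlinear"))
})
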