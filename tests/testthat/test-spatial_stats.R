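test_that("Moran's I on the 1..9 lattice equals 0.5 and matches the oracle", {
  g <- matrix(1:9, 3, 3, byrow = TRUE)
  expect_equal(morans_i(g, adjacency = "rook"), 0.5, tolerance = 1e-15)
  expect_equal(brute_morans_i(g, adjacency = "rook"), 0.5, tolerance = 1e-15)
})

test_that("Moran's I matches the brute-force double sum on random grids", {
  set.seed(101)
  for (rep in 1:25) {
    g <- matrix(rnorm(64), 8, 8)
    valid <- if (rep %% 3 == 0) matrix(runif(64) > 0.2, 8, 8) else NULL
    for (adj in c("rook", "queen")) {
      if (!is.null(valid) && sum(valid) < 2) next
      expect_equal(morans_i(g, valid, adj), brute_morans_i(g, valid, adj),
                   tolerance = 1e-12)
    }
  }
})

test_that("Moran's I agrees with an independent weight-matrix implementation", {
  skip_if_not_installed("ape")
  # ape::Moran.I row-normalizes its weights, so exact agreement with
  # binary contiguity weights holds on configurations of constant degree:
  # isolated rook dominoes, every valid cell with exactly one neighbour
  set.seed(102)
  g <- matrix(rnorm(36), 6, 6)
  valid <- matrix(FALSE, 6, 6)
  dominoes <- rbind(c(1, 1), c(1, 4), c(3, 1), c(3, 4), c(5, 1), c(5, 4))
  for (i in seq_len(nrow(dominoes))) {
    valid[dominoes[i, 1], dominoes[i, 2] + 0:1] <- TRUE
  }
  cells <- which(valid, arr.ind = TRUE)
  w <- 1 * (abs(outer(cells[, 1], cells[, 1], "-")) +
            abs(outer(cells[, 2], cells[, 2], "-")) == 1)
  ref <- ape::Moran.I(g[cells], w)
  expect_equal(morans_i(g, valid, adjacency = "rook"), ref$observed,
               tolerance = 1e-12)
})

test_that("a checkerboard is perfectly dispersed: I = -1", {
  cb <- outer(1:4, 1:4, function(r, c) ifelse((r + c) %% 2 == 0, 1, -1))
  expect_equal(morans_i(cb, adjacency = "rook"), -1, tolerance = 1e-15)
})

test_that("Moran's I rejects degenerate inputs", {
  expect_error(morans_i(matrix(5, 3, 3)), "zero variance")
  expect_error(morans_i(matrix(1:4, 2, 2), valid = matrix(c(1, 0, 0, 0), 2, 2)),
               "at least 2")
  expect_error(morans_i(matrix(1:4, 2, 2),
                        valid = matrix(c(1, 0, 0, 1), 2, 2),
                        adjacency = "rook"), "adjacent")
})

test_that("entropy has its closed forms at equal and degenerate occupancy", {
  for (k in c(2, 4, 8)) {
    edges <- seq(0.05, 0.95, length.out = k)  # k bins, lower-edge inclusive
    vals <- rep(edges, each = 6)              # equal occupancy
    expect_equal(shannon_entropy(matrix(vals, ncol = 1), edges), log(k),
                 tolerance = 1e-12)
  }
  expect_equal(shannon_entropy(matrix(0.5, 4, 4), c(0.1, 0.9)), 0)
  expect_error(shannon_entropy(numeric(0), c(0.5)), "no tissue-covered")
})

test_that("entropy is permutation invariant and maximal at equal occupancy", {
  set.seed(103)
  edges <- log_bin_edges(6, 1e-3, 1)
  vals <- runif(60)
  e1 <- shannon_entropy(matrix(vals, 6, 10), edges)
  e2 <- shannon_entropy(matrix(sample(vals), 10, 6), edges)
  expect_equal(e1, e2, tolerance = 1e-12)
  expect_lte(e1, log(7) + 1e-12)   # 6 edges -> at most 7 occupied bins
})

test_that("mean NND matches the all-pairs oracle on point sets", {
  expect_equal(mean_nnd(rbind(c(0, 0), c(0, 5))), 5.0)
  expect_error(mean_nnd(rbind(c(1, 2))), "at least 2")
  set.seed(104)
  for (rep in 1:10) {
    n <- sample(5:200, 1)
    pts <- matrix(runif(2 * n, 0, 50), n, 2)
    expect_equal(mean_nnd(pts), brute_mean_nnd(pts), tolerance = 1e-12)
  }
})

test_that("mask NND matches the oracle, including sparse masks", {
  # fully-filled 2x2 block: every pixel's nearest neighbour at distance 1
  m <- matrix(0L, 5, 5); m[2:3, 2:3] <- 1L
  expect_equal(mean_nnd(m), 1.0)
  set.seed(105)
  for (p in c(0.02, 0.15, 0.5)) {
    mk <- matrix(as.integer(runif(900) < p), 30, 30)
    if (sum(mk) < 2) next
    pts <- which(mk > 0, arr.ind = TRUE)
    expect_equal(mean_nnd(mk), brute_mean_nnd(pts), tolerance = 1e-12)
  }
  expect_error(mean_nnd(matrix(c(1, 0, 0, 0), 2, 2)), "at least 2")
})

test_that("hotspot volume counts strict exceedances times window area", {
  m <- matrix(0L, 20, 20)
  m[1:10, 1:10] <- as.integer(matrix(runif(100) < 0.6, 10, 10))  # dense
  m[11:20, 1:10] <- as.integer(matrix(runif(100) < 0.4, 10, 10))
  dm <- compute_density_map(fiber_mask(m, 1), window_mm2 = 1e-4)  # 10px windows
  d <- dm$density
  expect_equal(hotspot_volume(dm, 0.5), 100 * sum(d > 0.5))
  expect_equal(hotspot_volume(dm, 1.0), 0)             # strict inequality
  expect_equal(hotspot_volume(dm, 0), sum(dm$areas[d > 0]))
  # monotone non-increasing in the threshold
  ths <- seq(0, 1, by = 0.1)
  hv <- vapply(ths, function(t) hotspot_volume(dm, t), 0)
  expect_true(all(diff(hv) <= 0))
})

test_that("all four metrics are invariant under a 90-degree grid rotation", {
  set.seed(106)
  m <- matrix(as.integer(runif(1600) < 0.2), 40, 40)
  rot <- function(x) t(x)[, nrow(x):1]
  dm <- compute_density_map(fiber_mask(m, 1), window_mm2 = 2.5e-5)   # 5px
  dmr <- compute_density_map(fiber_mask(rot(m), 1), window_mm2 = 2.5e-5)
  edges <- log_bin_edges(6, 1e-3, 1)
  expect_equal(shannon_entropy(dm, edges), shannon_entropy(dmr, edges),
               tolerance = 1e-12)
  expect_equal(morans_i(dm$density, adjacency = "queen"),
               morans_i(dmr$density, adjacency = "queen"), tolerance = 1e-12)
  expect_equal(mean_nnd(m), mean_nnd(rot(m)), tolerance = 1e-12)
  expect_equal(hotspot_volume(dm, 0.2), hotspot_volume(dmr, 0.2))
})

test_that("profile tables summarize regions with t confidence intervals", {
  set.seed(107)
  mk <- function(p) {
    m <- matrix(as.integer(runif(400) < p), 20, 20)
    compute_density_map(fiber_mask(m, 1), window_mm2 = 2.5e-5)
  }
  dms <- lapply(c(0.05, 0.1, 0.2, 0.4), mk)
  pt <- innervation_profile(dms, regions = list(low = 1:2, high = 3:4),
                            threshold = 0.02)
  expect_equal(nrow(pt$metrics), 4L)
  expect_equal(pt$metrics$slice_index, 1:4)
  s <- pt$summaries
  expect_true(all(s$ci_lo[s$n >= 2] <= s$mean[s$n >= 2] + 1e-12))
  expect_true(all(s$ci_hi[s$n >= 2] >= s$mean[s$n >= 2] - 1e-12))
  # identical slices give a zero-width interval at the common value
  pt2 <- innervation_profile(list(dms[[1]], dms[[1]]),
                             regions = list(all = 1:2), threshold = 0.02)
  hs <- pt2$summaries[pt2$summaries$metric == "hotspot_volume_px", ]
  expect_equal(hs$ci_lo, hs$mean)
  expect_equal(hs$ci_hi, hs$mean)
  # single-slice regions report the value with an undefined interval
  pt1 <- innervation_profile(dms[1], regions = list(only = 1), threshold = 0.02)
  expect_true(all(is.na(pt1$summaries$ci_lo)))
  expect_error(innervation_profile(dms, regions = list(bad = 1:9)),
               "absent slices")
})
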