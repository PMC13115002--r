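make_pairs <- function(src, tgt) landmark_pairs(src, tgt)

test_that("rigid fit recovers identity and exact rotations", {
  set.seed(31)
  src <- matrix(runif(10, 0, 100), 5, 2)
  # identity
  tr <- fit_rigid(make_pairs(src, src))
  expect_equal(tr$A, diag(2), tolerance = 1e-12)
  expect_equal(tr$t, c(0, 0), tolerance = 1e-12)
  # 90 degrees about the centroid
  ctr <- colMeans(src)
  R <- matrix(c(0, 1, -1, 0), 2, 2)
  tgt <- t(R %*% (t(src) - ctr) + ctr)
  tr90 <- fit_rigid(make_pairs(src, tgt))
  ang <- atan2(tr90$A[2, 1], tr90$A[1, 1])
  expect_equal(ang, pi / 2, tolerance = 1e-9)
  expect_lt(max(abs(transform_points(tr90, src) - tgt)), 1e-9)
  expect_error(fit_rigid(landmark_pairs(src[1, , drop = FALSE],
                                        tgt[1, , drop = FALSE])), "at least 2")
  expect_error(fit_rigid(make_pairs(matrix(5, 4, 2), tgt[1:4, ])), "coincide")
})

test_that("similarity fit recovers a known uniform scale", {
  set.seed(32)
  src <- matrix(runif(12, 0, 50), 6, 2)
  th <- 0.4; s <- 1.7
  R <- s * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  tgt <- t(R %*% t(src)) + rep(c(3, -2), each = 6)
  tr <- fit_rigid(make_pairs(src, tgt), allow_scale = TRUE)
  expect_equal(sqrt(det(tr$A)), s, tolerance = 1e-9)
  expect_lt(max(abs(transform_points(tr, src) - tgt)), 1e-9)
})

test_that("reflections are rejected by default and permitted by flag", {
  set.seed(33)
  src <- matrix(runif(12, 0, 50), 6, 2)
  tgt <- src %*% diag(c(-1, 1))   # mirrored
  tr_no <- fit_rigid(make_pairs(src, tgt))
  expect_equal(det(tr_no$A), 1, tolerance = 1e-9)
  tr_yes <- fit_rigid(make_pairs(src, tgt), allow_reflection = TRUE)
  expect_equal(det(tr_yes$A), -1, tolerance = 1e-9)
  expect_lt(max(abs(transform_points(tr_yes, src) - tgt)), 1e-9)
})

test_that("rigid fit is least-squares optimal vs random rigid transforms", {
  set.seed(34)
  resid <- function(A, t, src, tgt) mean(rowSums((src %*% t(A) +
    rep(t, each = nrow(src)) - tgt)^2))
  for (rep in 1:5) {
    src <- matrix(runif(10, 0, 100), 5, 2)
    tgt <- src + matrix(rnorm(10, 0, 4), 5, 2)
    tr <- fit_rigid(make_pairs(src, tgt))
    best <- resid(tr$A, tr$t, src, tgt)
    for (k in 1:200) {
      th <- runif(1, 0, 2 * pi)
      A <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
      tt <- colMeans(tgt) - A %*% colMeans(src) + rnorm(2, 0, 0.5)
      expect_gte(resid(A, tt, src, tgt), best - 1e-9)
    }
  }
})

test_that("similarity fit agrees with an independent Procrustes solver", {
  skip_if_not_installed("vegan")
  set.seed(55)
  src <- matrix(runif(16, 0, 100), 8, 2)
  tgt <- src %*% matrix(c(cos(0.6), -sin(0.6), sin(0.6), cos(0.6)), 2, 2) * 1.3 +
    rep(c(4, -6), each = 8) + matrix(rnorm(16, 0, 2), 8, 2)
  tr <- fit_rigid(landmark_pairs(src, tgt), allow_scale = TRUE)
  vp <- vegan::procrustes(tgt, src)   # vegan maps Y (src) onto X (tgt)
  mine <- transform_points(tr, src)
  expect_equal(mean(rowSums((mine - tgt)^2)),
               mean(stats::residuals(vp)^2), tolerance = 1e-8)
})

test_that("forward and inverse rigid transforms compose to the identity", {
  set.seed(35)
  A <- matrix(runif(8, 0, 100), 4, 2)
  B <- t(matrix(c(cos(1), sin(1), -sin(1), cos(1)), 2, 2) %*% t(A)) + 5
  f <- fit_rigid(make_pairs(A, B))
  g <- fit_rigid(make_pairs(B, A))
  back <- transform_points(g, transform_points(f, A))
  expect_lt(max(abs(back - A)), 1e-6)
})

test_that("affine fit reproduces a known affine map and rejects degeneracy", {
  src <- rbind(c(0, 0), c(10, 0), c(0, 10), c(7, 3))
  M <- matrix(c(1.2, 0.3, -0.4, 0.9), 2, 2)
  tgt <- src %*% t(M) + rep(c(5, -1), each = 4)
  tr <- fit_affine(make_pairs(src, tgt))
  expect_equal(tr$A, M, tolerance = 1e-9)
  coll <- cbind(1:4, 2 * (1:4))
  expect_error(fit_affine(make_pairs(coll, coll)), "collinear")
  expect_error(fit_tps(make_pairs(coll, coll)), "collinear")
})

test_that("unregularized TPS interpolates landmarks exactly", {
  set.seed(36)
  src <- matrix(runif(16, 0, 100), 8, 2)
  tgt <- src + matrix(rnorm(16, 0, 6), 8, 2)
  tr <- fit_tps(make_pairs(src, tgt), lambda = 0)
  expect_lt(max(abs(transform_points(tr, src) - tgt)), 1e-6)
})

test_that("TPS of affine-related landmarks has zero bending energy", {
  set.seed(37)
  src <- matrix(runif(14, 0, 100), 7, 2)
  M <- matrix(c(0.9, -0.2, 0.3, 1.1), 2, 2)
  tgt <- src %*% t(M) + rep(c(2, 7), each = 7)
  tr <- fit_tps(make_pairs(src, tgt), lambda = 0)
  expect_lt(tps_bending_energy(tr), 1e-8)
  # equals the affine map on a dense test grid
  gx <- seq(0, 100, by = 10)
  grid <- as.matrix(expand.grid(gx, gx))
  expect_lt(max(abs(transform_points(tr, grid) -
                    (grid %*% t(M) + rep(c(2, 7), each = nrow(grid))))), 1e-6)
})

test_that("strong regularization drives TPS toward the best affine fit", {
  set.seed(38)
  src <- matrix(runif(20, 0, 100), 10, 2)
  tgt <- src + matrix(rnorm(20, 0, 8), 10, 2)
  aff <- fit_affine(make_pairs(src, tgt))
  r_aff <- mean(rowSums((transform_points(aff, src) - tgt)^2))
  tr <- fit_tps(make_pairs(src, tgt), lambda = 1e8)
  r_tps <- mean(rowSums((transform_points(tr, src) - tgt)^2))
  expect_equal(r_tps, r_aff, tolerance = 1e-4)
})

test_that("TPS recovers a known 8-control-point warp on a dense grid", {
  set.seed(39)
  ctrl <- matrix(runif(16, 10, 90), 8, 2)
  truth <- fit_tps(make_pairs(ctrl, ctrl + matrix(rnorm(16, 0, 5), 8, 2)),
                   lambda = 0)
  # noiseless landmark observations of the true warp at its own knots
  fitted <- fit_tps(make_pairs(ctrl, transform_points(truth, ctrl)), lambda = 0)
  gx <- seq(5, 95, by = 5)
  grid <- as.matrix(expand.grid(gx, gx))
  err <- sqrt(rowSums((transform_points(fitted, grid) -
                       transform_points(truth, grid))^2))
  expect_lt(max(err), 1e-4)
})

test_that("grid resampling honours the row/col convention and value ranges", {
  m <- matrix(0, 20, 20); m[11, 11] <- 1   # bright pixel at (row 10, col 10) 0-based
  shift <- fit_rigid(make_pairs(rbind(c(0, 0), c(1, 0), c(0, 1)),
                                rbind(c(5, 0), c(6, 0), c(5, 1))))
  out <- apply_transform(m, shift, c(20, 20), "nearest")
  expect_equal(out[11, 16], 1)   # moved to (row 10, col 15)
  expect_equal(sum(out), 1)
  # identity returns the grid unchanged
  idt <- fit_rigid(make_pairs(rbind(c(0, 0), c(3, 4)), rbind(c(0, 0), c(3, 4))))
  expect_equal(apply_transform(m, idt, c(20, 20), "nearest"), m)
  # binary input stays binary (plus fill) under nearest for any transform
  set.seed(40)
  b <- matrix(as.integer(runif(400) < 0.4), 20, 20)
  rot <- fit_rigid(make_pairs(rbind(c(0, 0), c(1, 0), c(0, 1)),
                              rbind(c(10, 3), c(10, 3 + cos(0.7)),
                                    c(10 - sin(0.7), 3)) ))
  vals <- unique(as.vector(apply_transform(b, rot, c(20, 20), "nearest",
                                           fill = -7)))
  expect_true(all(vals %in% c(0, 1, -7)))
})

test_that("transforms survive a JSON round trip", {
  set.seed(41)
  src <- matrix(runif(12, 0, 50), 6, 2)
  tgt <- src + matrix(rnorm(12), 6, 2)
  for (tr in list(fit_rigid(make_pairs(src, tgt)),
                  fit_tps(make_pairs(src, tgt), lambda = 0.5))) {
    f <- withr::local_tempfile(fileext = ".json")
    write_transform(tr, f)
    re <- read_transform(f)
    pts <- matrix(runif(10, 0, 50), 5, 2)
    expect_equal(transform_points(re, pts), transform_points(tr, pts),
                 tolerance = 1e-12)
  }
})
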