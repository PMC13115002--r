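#' Paired registration landmarks
#'
#' Corresponding points in source (ring) and target (reference-slice)
#' pixel coordinates. Points are `(x, y)` = (column, row), 0-based.
#'
#' @param source,target Numeric `n x 2` matrices of `(x, y)` points.
#' @return An object of class `landmark_pairs`.
#' @export
landmark_pairs <- function(source, target) {
  source <- as.matrix(source); target <- as.matrix(target)
  stopifnot(ncol(source) == 2, ncol(target) == 2,
            nrow(source) == nrow(target), nrow(source) >= 1)
  structure(list(source = unname(source), target = unname(target)),
            class = "landmark_pairs")
}

#' Read landmark pairs from CSV
#'
#' Expects columns `x_src, y_src, x_dst, y_dst` in pixel units, 0-based.
#'
#' @param path CSV file path.
#' @return A [landmark_pairs()].
#' @export
read_landmarks <- function(path) {
  d <- utils::read.csv(path)
  need <- c("x_src", "y_src", "x_dst", "y_dst")
  if (!all(need %in% names(d))) {
    stop("landmark file must have columns ", paste(need, collapse = ", "))
  }
  landmark_pairs(cbind(d$x_src, d$y_src), cbind(d$x_dst, d$y_dst))
}

new_transform2d <- function(kind, A = diag(2), t = c(0, 0), ctrl = NULL,
                            W = NULL, lambda = 0, pairs = NULL) {
  structure(list(kind = kind, A = A, t = t, ctrl = ctrl, W = W,
                 lambda = lambda, pairs = pairs),
            class = "transform2d")
}

#' @export
print.transform2d <- function(x, ...) {
  cat(sprintf("<transform2d %s>\n", x$kind))
  if (x$kind != "tps") {
    cat("  A = [", paste(signif(t(x$A), 6), collapse = " "), "]  t = (",
        paste(signif(x$t, 6), collapse = ", "), ")\n")
  } else {
    cat(sprintf("  %d control points, lambda = %g\n", nrow(x$ctrl), x$lambda))
  }
  invisible(x)
}

#' Fit a rigid (or similarity) transform to landmarks
#'
#' Closed-form Procrustes solution: the rotation + translation (plus a
#' uniform scale when `allow_scale`) minimizing the mean squared landmark
#' residual. Reflections are disallowed unless `allow_reflection` (flipped
#' histology sections do occur).
#'
#' @param pairs A [landmark_pairs()] with `>= 2` pairs.
#' @param allow_scale Estimate a uniform scale (similarity transform).
#' @param allow_reflection Permit an improper rotation.
#' @return A `transform2d` of kind `"rigid"` or `"similarity"`.
#' @export
fit_rigid <- function(pairs, allow_scale = FALSE, allow_reflection = FALSE) {
  stopifnot(inherits(pairs, "landmark_pairs"))
  X <- pairs$source; Y <- pairs$target
  if (nrow(X) < 2) stop("rigid fit needs at least 2 landmark pairs")
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  if (all(abs(Xc) < 1e-12)) stop("all source landmarks coincide")
  H <- t(Xc) %*% Yc
  sv <- svd(H)
  S <- diag(2)
  if (!allow_reflection && det(sv$v %*% t(sv$u)) < 0) S <- diag(c(1, -1))
  R <- sv$v %*% S %*% t(sv$u)
  s <- 1
  if (allow_scale) s <- sum(diag(S) * sv$d) / sum(Xc^2)
  A <- s * R
  new_transform2d(if (allow_scale) "similarity" else "rigid",
                  A = A, t = as.vector(cy - A %*% cx))
}

#' Fit an affine transform to landmarks
#'
#' Ordinary least squares per output coordinate.
#'
#' @param pairs A [landmark_pairs()] with `>= 3` non-collinear pairs.
#' @return A `transform2d` of kind `"affine"`.
#' @export
fit_affine <- function(pairs) {
  stopifnot(inherits(pairs, "landmark_pairs"))
  X <- pairs$source; Y <- pairs$target
  if (nrow(X) < 3) stop("affine fit needs at least 3 landmark pairs")
  M <- cbind(X, 1)
  if (qr(M)$rank < 3) stop("landmarks are collinear: affine fit is degenerate")
  B <- qr.solve(M, Y)                     # 3 x 2
  new_transform2d("affine", A = t(B[1:2, ]), t = as.vector(B[3, ]))
}

tps_kernel <- function(r) ifelse(r > 0, r^2 * log(r), 0)

#' Fit a regularized thin-plate-spline transform
#'
#' With `lambda = 0` the spline interpolates the landmarks exactly; with
#' `lambda > 0` it trades landmark residual against bending energy, and as
#' `lambda` grows the map approaches the best affine fit (the bending
#' penalty does not act on the affine part).
#'
#' @param pairs A [landmark_pairs()] with `>= 3` non-collinear pairs.
#' @param lambda Regularization weight `>= 0`.
#' @return A `transform2d` of kind `"tps"`.
#' @export
fit_tps <- function(pairs, lambda = 0) {
  stopifnot(inherits(pairs, "landmark_pairs"), lambda >= 0)
  X <- pairs$source; Y <- pairs$target
  n <- nrow(X)
  if (n < 3) stop("TPS fit needs at least 3 landmark pairs")
  if (qr(cbind(X, 1))$rank < 3) stop("landmarks are collinear: TPS fit is degenerate")
  K <- tps_kernel(as.matrix(stats::dist(X)))
  P <- cbind(1, X)
  # block elimination of the bordered system: numerically stable for any
  # lambda (the naive bordered solve degrades as lambda grows)
  Minv <- solve(K + lambda * diag(n))
  MP <- Minv %*% P
  Aff <- solve(crossprod(P, MP), crossprod(MP, Y))   # rows: 1, x, y
  W <- Minv %*% (Y - P %*% Aff)
  new_transform2d("tps", A = t(Aff[2:3, ]), t = as.vector(Aff[1, ]),
                  ctrl = X, W = W, lambda = lambda, pairs = pairs)
}

#' Bending energy of a fitted TPS
#'
#' `trace(t(W) K W)`; zero iff the mapping is purely affine.
#'
#' @param t A `transform2d` of kind `"tps"`.
#' @return Non-negative scalar.
#' @export
tps_bending_energy <- function(t) {
  stopifnot(inherits(t, "transform2d"), t$kind == "tps")
  K <- tps_kernel(as.matrix(stats::dist(t$ctrl)))
  sum(diag(crossprod(t$W, K %*% t$W)))
}

#' Apply a transform to points
#'
#' Forward evaluation: maps `(x, y)` source points to target coordinates.
#'
#' @param t A `transform2d`.
#' @param pts Numeric `n x 2` matrix of `(x, y)` points.
#' @return `n x 2` matrix of mapped points.
#' @export
transform_points <- function(t, pts) {
  stopifnot(inherits(t, "transform2d"))
  pts <- matrix(as.numeric(pts), ncol = 2)
  out <- pts %*% t(t$A)
  out[, 1] <- out[, 1] + t$t[1]
  out[, 2] <- out[, 2] + t$t[2]
  if (t$kind == "tps") {
    nx <- outer(pts[, 1], t$ctrl[, 1], "-")
    ny <- outer(pts[, 2], t$ctrl[, 2], "-")
    U <- tps_kernel(sqrt(nx^2 + ny^2))
    out <- out + U %*% t$W
  }
  out
}

#' Invert a transform
#'
#' Linear kinds invert in closed form. A TPS has no closed-form inverse;
#' the inverse is approximated by refitting a TPS on the swapped landmark
#' pairs (standard practice for backward warping).
#'
#' @param t A `transform2d`.
#' @return A `transform2d` mapping target to source.
#' @export
invert_transform <- function(t) {
  stopifnot(inherits(t, "transform2d"))
  if (t$kind != "tps") {
    Ainv <- solve(t$A)
    return(new_transform2d(t$kind, A = Ainv, t = as.vector(-Ainv %*% t$t)))
  }
  fit_tps(landmark_pairs(t$pairs$target, t$pairs$source), lambda = t$lambda)
}

#' Resample a grid through a transform
#'
#' Samples the input on the target grid by inverse mapping: for each
#' target pixel, the source location `t^{-1}(x, y)` is looked up with
#' nearest-neighbour (default, value-preserving for binary/density grids)
#' or bilinear interpolation. Out-of-domain samples get `fill`.
#'
#' @param grid Matrix or `H x W x 3` array.
#' @param t A `transform2d` mapping source to target coordinates.
#' @param target_shape `(H, W)` of the output.
#' @param interpolation `"nearest"` or `"bilinear"`.
#' @param fill Fill value for out-of-domain pixels.
#' @return Resampled grid of shape `target_shape` (x3 for RGB input).
#' @export
apply_transform <- function(grid, t, target_shape = NULL,
                            interpolation = c("nearest", "bilinear"),
                            fill = 0) {
  interpolation <- match.arg(interpolation)
  stopifnot(inherits(t, "transform2d"))
  if (is.null(target_shape)) target_shape <- dim(grid)[1:2]
  resample_backward(grid, invert_transform(t), target_shape, interpolation,
                    fill)
}

# Resample `grid` on the target lattice by direct evaluation of a
# backward map `bt` (target coordinates -> source coordinates).
resample_backward <- function(grid, bt, target_shape,
                              interpolation = "nearest", fill = 0) {
  is_rgb <- length(dim(grid)) == 3L
  src_dim <- dim(grid)[1:2]
  H <- target_shape[1]; W <- target_shape[2]
  # target pixel centers, 0-based (x = col, y = row)
  xy <- cbind(rep(seq_len(W) - 1, each = H), rep(seq_len(H) - 1, times = W))
  src <- transform_points(bt, xy)
  sample_one <- function(m) {
    out <- rep(fill, H * W)
    if (interpolation == "nearest") {
      r <- round(src[, 2]) + 1; c <- round(src[, 1]) + 1
      ok <- r >= 1 & r <= src_dim[1] & c >= 1 & c <= src_dim[2]
      out[ok] <- m[cbind(r[ok], c[ok])]
    } else {
      x <- src[, 1]; y <- src[, 2]
      x0 <- floor(x); y0 <- floor(y)
      fx <- x - x0; fy <- y - y0
      ok <- x0 >= 0 & y0 >= 0 & x0 <= src_dim[2] - 2 & y0 <= src_dim[1] - 2
      # clamp exact right/bottom edge into range
      edge <- (x0 == src_dim[2] - 1 & fx == 0 & y0 >= 0 & y0 <= src_dim[1] - 1) |
              (y0 == src_dim[1] - 1 & fy == 0 & x0 >= 0 & x0 <= src_dim[2] - 1)
      ok <- ok | (edge & x0 >= 0 & y0 >= 0 & x0 <= src_dim[2] - 1 & y0 <= src_dim[1] - 1)
      x0k <- pmin(x0[ok], src_dim[2] - 2); y0k <- pmin(y0[ok], src_dim[1] - 2)
      fxk <- x[ok] - x0k; fyk <- y[ok] - y0k
      i00 <- m[cbind(y0k + 1, x0k + 1)]
      i01 <- m[cbind(y0k + 1, x0k + 2)]
      i10 <- m[cbind(y0k + 2, x0k + 1)]
      i11 <- m[cbind(y0k + 2, x0k + 2)]
      out[ok] <- i00 * (1 - fxk) * (1 - fyk) + i01 * fxk * (1 - fyk) +
                 i10 * (1 - fxk) * fyk + i11 * fxk * fyk
    }
    matrix(out, H, W)
  }
  if (is_rgb) {
    out <- array(fill, dim = c(H, W, dim(grid)[3]))
    for (ch in seq_len(dim(grid)[3])) out[, , ch] <- sample_one(grid[, , ch])
    out
  } else {
    sample_one(grid)
  }
}

#' Serialize a transform to JSON
#'
#' @param t A `transform2d`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transform <- function(t, path) {
  stopifnot(inherits(t, "transform2d"))
  obj <- list(kind = t$kind, A = t$A, t = t$t, lambda = t$lambda)
  if (t$kind == "tps") {
    obj$ctrl <- t$ctrl; obj$W <- t$W
    obj$pairs <- list(source = t$pairs$source, target = t$pairs$target)
  }
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a transform from JSON
#'
#' @param path Path written by [write_transform()].
#' @return A `transform2d`.
#' @export
read_transform <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  pairs <- if (!is.null(o$pairs)) landmark_pairs(o$pairs$source, o$pairs$target)
  new_transform2d(o$kind, A = matrix(o$A, 2, 2), t = as.numeric(o$t),
                  ctrl = if (!is.null(o$ctrl)) matrix(o$ctrl, ncol = 2),
                  W = if (!is.null(o$W)) matrix(o$W, ncol = 2),
                  lambda = o$lambda %||% 0, pairs = pairs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
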