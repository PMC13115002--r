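#' Sliding-window fiber density map
#'
#' Tiles the fiber mask into square windows of physical side
#' `sqrt(window_mm2)` millimetres (converted to pixels via the effective
#' resolution) and computes per-window density as the ratio of fiber
#' pixels to window area. Windows are non-overlapping by default, so the
#' grid drawn by [render_heatmap()] corresponds 1:1 to the analysis
#' windows; a custom `stride_px` yields overlapping maps.
#'
#' Partial windows at the right/bottom edges are normalized by their true
#' pixel count rather than padded, avoiding spurious low densities at the
#' borders.
#'
#' @param fibers A [fiber_mask()] (or a binary matrix, in which case
#'   `mpp_eff` is required).
#' @param window_mm2 Window area in square millimetres (`> 0`); 1 mm^2 is
#'   the conventional choice for myocardial innervation mapping.
#' @param mpp_eff Effective microns per pixel; taken from `fibers` when it
#'   is a `fiber_mask`.
#' @param tissue Optional tissue mask (matrix or `tissue_mask`); used to
#'   mark which windows are tissue-covered for the spatial statistics.
#' @param stride_px Optional window stride in pixels; defaults to the
#'   window side (non-overlapping tiling).
#' @return An object of class `density_map`: `density` (R x C matrix in
#'   `[0,1]`), `counts`, `areas`, `covered` (logical), `window_px`,
#'   `window_mm2`, `mpp_eff`, `origin`, `stride_px`.
#' @export
compute_density_map <- function(fibers, window_mm2 = 1, mpp_eff = NULL,
                                tissue = NULL, stride_px = NULL) {
  if (inherits(fibers, "fiber_mask")) {
    m <- fibers$mask
    if (is.null(mpp_eff)) mpp_eff <- fibers$mpp_eff
  } else {
    m <- matrix(as.integer(fibers > 0), nrow(fibers), ncol(fibers))
  }
  if (is.null(mpp_eff) || mpp_eff <= 0) stop("mpp_eff must be a positive number")
  if (window_mm2 <= 0) stop("window_mm2 must be > 0")
  window_px <- floor(sqrt(window_mm2) * 1000 / mpp_eff)
  if (window_px < 1) stop("window smaller than one pixel at this resolution")
  tm <- NULL
  if (!is.null(tissue)) {
    tm <- if (inherits(tissue, "tissue_mask")) tissue$mask else
      matrix(as.integer(tissue > 0), nrow(tissue), ncol(tissue))
    if (!all(dim(tm) == dim(m))) stop("tissue mask shape mismatch")
  }
  if (is.null(stride_px)) stride_px <- window_px
  stride_px <- as.integer(stride_px)
  if (stride_px < 1L) stop("stride_px must be >= 1")

  if (stride_px == window_px) {
    agg <- tile_sums(m, window_px)
    counts <- agg$sums
    areas <- agg$areas
    tsum <- if (is.null(tm)) areas else tile_sums(tm, window_px)$sums
  } else {
    r0 <- seq(1L, nrow(m), by = stride_px)
    c0 <- seq(1L, ncol(m), by = stride_px)
    counts <- areas <- tsum <- matrix(0, length(r0), length(c0))
    for (i in seq_along(r0)) for (j in seq_along(c0)) {
      rr <- r0[i]:min(r0[i] + window_px - 1L, nrow(m))
      cc <- c0[j]:min(c0[j] + window_px - 1L, ncol(m))
      counts[i, j] <- sum(m[rr, cc])
      areas[i, j] <- length(rr) * length(cc)
      tsum[i, j] <- if (is.null(tm)) areas[i, j] else sum(tm[rr, cc])
    }
  }
  structure(
    list(density = counts / areas, counts = counts, areas = areas,
         covered = tsum > 0, window_px = as.integer(window_px),
         window_mm2 = window_mm2, mpp_eff = mpp_eff,
         origin = c(0L, 0L), stride_px = stride_px),
    class = "density_map"
  )
}

# Per-tile sums by aggregating rows then columns with rowsum().
tile_sums <- function(m, w) {
  ri <- (seq_len(nrow(m)) - 1L) %/% w + 1L
  ci <- (seq_len(ncol(m)) - 1L) %/% w + 1L
  s <- rowsum(m, ri, reorder = TRUE)
  s <- t(rowsum(t(s), ci, reorder = TRUE))
  dimnames(s) <- NULL
  list(sums = s, areas = outer(tabulate(ri), tabulate(ci)))
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("<density_map %d x %d windows of %d px (%.3g mm^2), mean density %.4g>\n",
              nrow(x$density), ncol(x$density), x$window_px, x$window_mm2,
              mean(x$density[x$covered])))
  invisible(x)
}

#' Logarithmically spaced density bin edges
#'
#' `n_bins` edges with constant ratio between consecutive edges, spanning
#' `[lo, hi]`. These are the thresholds of a fixed logarithmic colour
#' scale: densities below `lo` fall in a background bin.
#'
#' @param n_bins Number of bins (= number of edges).
#' @param lo,hi Lowest and highest edge, `0 < lo < hi <= 1`.
#' @return Numeric vector of strictly increasing edges.
#' @export
log_bin_edges <- function(n_bins = 8, lo = 1e-4, hi = 1) {
  stopifnot(n_bins >= 2, lo > 0, hi > lo, hi <= 1)
  exp(seq(log(lo), log(hi), length.out = n_bins))
}

#' Heatmap rendering style
#'
#' A fixed logarithmic colour scale shared across slides: density bin
#' edges, a light-to-dark red palette (one colour per bin), overlay
#' opacity, and grid/legend switches.
#'
#' @param alpha Overlay opacity in `[0,1]`; 0.3 gives a semi-transparent
#'   overlay through which the histology remains visible.
#' @param bin_edges Strictly increasing density thresholds in `[0,1]`.
#' @param palette Matrix `n_bins x 3` of RGB in `[0,255]`, or `NULL` for
#'   the default light-to-dark red ramp.
#' @param draw_grid Draw grid lines at window boundaries.
#' @param draw_legend Append a legend strip of the bin colours.
#' @return An object of class `heatmap_style`.
#' @export
heatmap_style <- function(alpha = 0.3, bin_edges = log_bin_edges(),
                          palette = NULL, draw_grid = TRUE,
                          draw_legend = FALSE) {
  stopifnot(alpha >= 0, alpha <= 1, length(bin_edges) >= 1,
            all(diff(bin_edges) > 0), all(bin_edges >= 0), all(bin_edges <= 1))
  n <- length(bin_edges)
  if (is.null(palette)) {
    cols <- grDevices::colorRampPalette(c("#FEE0D2", "#A50F15"))(n)
    palette <- t(grDevices::col2rgb(cols))
  }
  stopifnot(nrow(palette) == n, ncol(palette) == 3)
  structure(list(alpha = alpha, bin_edges = bin_edges, palette = palette,
                 draw_grid = draw_grid, draw_legend = draw_legend),
            class = "heatmap_style")
}

#' Map densities to logarithmic bins
#'
#' Returns, for each density, the largest bin index `i` with
#' `bin_edges[i] <= d` (lower edges inclusive); densities below the first
#' edge map to the background bin, index 0.
#'
#' @param d Numeric vector/matrix of densities in `[0,1]`.
#' @param style A [heatmap_style()] (or a numeric vector of edges).
#' @return Integer bin indices, 0 = background, same shape as `d`.
#' @export
bin_density <- function(d, style = heatmap_style()) {
  edges <- if (inherits(style, "heatmap_style")) style$bin_edges else style
  idx <- findInterval(d, edges)
  if (is.matrix(d)) idx <- matrix(idx, nrow(d), ncol(d))
  idx
}

#' Render a density heatmap overlay
#'
#' Alpha-blends per-window bin colours onto the working slide image
#' (`out = round(alpha * heat + (1 - alpha) * base)`, round half up),
#' leaving background-bin windows untouched, then draws the analysis grid
#' and, optionally, a legend strip appended on the right.
#'
#' @param slide A [slide_image()] at the same working geometry as `dm`.
#' @param dm A [compute_density_map()] result with stride = window.
#' @param style A [heatmap_style()].
#' @return RGB array `H x W' x 3` in `[0,255]` (wider than the slide if a
#'   legend is drawn).
#' @export
render_heatmap <- function(slide, dm, style = heatmap_style()) {
  stopifnot(inherits(slide, "slide_image"), inherits(dm, "density_map"))
  d <- dim(slide$pixels)
  w <- dm$window_px
  if (dm$stride_px != w) stop("heatmap rendering requires non-overlapping windows")
  if (nrow(dm$density) != ceiling(d[1] / w) ||
      ncol(dm$density) != ceiling(d[2] / w)) {
    stop("density map geometry does not match slide")
  }
  bins <- bin_density(dm$density, style)
  ri <- (seq_len(d[1]) - 1L) %/% w + 1L
  ci <- (seq_len(d[2]) - 1L) %/% w + 1L
  binpx <- bins[cbind(rep(ri, times = d[2]), rep(ci, each = d[1]))]
  out <- slide$pixels
  sel <- binpx > 0
  if (any(sel)) {
    a <- style$alpha
    for (ch in 1:3) {
      base <- out[, , ch]
      heat <- style$palette[pmax(binpx, 1L), ch]
      blend <- floor(a * heat + (1 - a) * base + 0.5)  # round half up
      base[sel] <- blend[sel]
      out[, , ch] <- base
    }
  }
  if (isTRUE(style$draw_grid)) {
    grid_col <- c(80, 80, 80)
    rows <- seq(w, d[1] - 1L, by = w)
    cols <- seq(w, d[2] - 1L, by = w)
    for (ch in 1:3) {
      if (length(rows)) out[rows, , ch] <- grid_col[ch]
      if (length(cols)) out[, cols, ch] <- grid_col[ch]
    }
  }
  if (isTRUE(style$draw_legend)) {
    n <- nrow(style$palette)
    strip_w <- max(8L, d[2] %/% 20L)
    strip <- array(255, dim = c(d[1], strip_w, 3))
    block <- floor(d[1] / n)
    for (i in seq_len(n)) {
      rr <- ((i - 1L) * block + 1L):min(i * block, d[1])
      for (ch in 1:3) strip[rr, , ch] <- style$palette[n - i + 1L, ch]
    }
    out2 <- array(0, dim = c(d[1], d[2] + strip_w, 3))
    out2[, seq_len(d[2]), ] <- out
    out2[, d[2] + seq_len(strip_w), ] <- strip
    out <- out2
  }
  out
}

#' Write a density grid to CSV
#'
#' @param dm A [compute_density_map()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_density_csv <- function(dm, path) {
  utils::write.table(dm$density, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
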