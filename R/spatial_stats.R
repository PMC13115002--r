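#' Shannon entropy of a density distribution
#'
#' Natural-log Shannon entropy of the histogram of per-window densities
#' over the fixed logarithmic bins (tissue-covered windows only). Zero
#' for a degenerate distribution (all windows in one bin), maximal at
#' `ln k` when `k` occupied bins are equally filled. Quantifies the
#' heterogeneity of the innervation pattern of one slice.
#'
#' @param dm A [compute_density_map()] result, or a plain matrix of
#'   densities (all cells counted).
#' @param edges Histogram bin edges (lower edges, inclusive; values below
#'   the first edge fall in a background bin).
#' @return Entropy in nats (`>= 0`).
#' @export
shannon_entropy <- function(dm, edges = log_bin_edges()) {
  if (inherits(dm, "density_map")) {
    vals <- dm$density[dm$covered]
  } else {
    vals <- as.vector(dm)
  }
  if (!length(vals)) stop("no tissue-covered cells: entropy undefined")
  bins <- findInterval(vals, edges)
  p <- tabulate(bins + 1L, nbins = length(edges) + 1L)
  p <- p[p > 0] / length(vals)
  -sum(p * log(p))
}

#' Global Moran's I on a lattice
#'
#' `I = (N / W) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i - xbar)^2`
#' with binary contiguity weights (`w_ij = 1` for adjacent valid cells,
#' counted in both directions, `W = sum w_ij`). Positive values indicate
#' spatial clustering of similar densities, values near zero a random
#' arrangement, negative values an alternating/dispersed pattern.
#'
#' @param values `R x C` numeric matrix (e.g. a density grid).
#' @param valid Optional logical/binary matrix restricting the analysis
#'   (e.g. tissue-covered windows); default all cells.
#' @param adjacency `"queen"` (8 neighbours, default) or `"rook"` (4).
#' @return Moran's I (numeric scalar).
#' @export
morans_i <- function(values, valid = NULL, adjacency = c("queen", "rook")) {
  adjacency <- match.arg(adjacency)
  stopifnot(is.matrix(values))
  if (is.null(valid)) valid <- matrix(TRUE, nrow(values), ncol(values))
  valid <- valid > 0
  n <- sum(valid)
  if (n < 2) stop("Moran's I needs at least 2 valid cells")
  x <- values
  xbar <- mean(x[valid])
  z <- x - xbar
  z[!valid] <- 0
  denom <- sum(z[valid]^2)
  if (denom == 0) stop("zero variance: Moran's I undefined")
  offsets <- list(c(0, 1), c(1, 0))
  if (adjacency == "queen") offsets <- c(offsets, list(c(1, 1), c(1, -1)))
  num <- 0; W <- 0
  R <- nrow(x); C <- ncol(x)
  for (off in offsets) {
    dr <- off[1]; dc <- off[2]
    r1 <- seq_len(R - dr); r2 <- r1 + dr
    if (dc >= 0) { c1 <- seq_len(C - dc); c2 <- c1 + dc }
    else         { c1 <- seq_len(C + dc) - dc; c2 <- c1 + dc }
    ok <- valid[r1, c1, drop = FALSE] & valid[r2, c2, drop = FALSE]
    num <- num + 2 * sum(z[r1, c1, drop = FALSE] * z[r2, c2, drop = FALSE] * ok)
    W <- W + 2 * sum(ok)
  }
  if (W == 0) stop("no adjacent valid cell pairs")
  (n / W) * num / denom
}

#' Mean nearest-neighbour distance of a point pattern
#'
#' Mean, over all points, of the Euclidean distance to the nearest other
#' point. Mask pixels are treated as points at their centres (unit pixel
#' lattice), so values near 1 indicate near-contiguous fiber pixels.
#'
#' @param x A [fiber_mask()], a binary matrix, or an `n x 2` matrix of
#'   point coordinates.
#' @return Mean NND in pixels.
#' @export
mean_nnd <- function(x) {
  if (inherits(x, "fiber_mask")) x <- x$mask
  if (is.matrix(x) && ncol(x) == 2 && !all(x %in% c(0, 1))) {
    pts <- x
    if (nrow(pts) < 2) stop("mean NND needs at least 2 points")
    d <- as.matrix(stats::dist(pts))
    diag(d) <- Inf
    return(mean(apply(d, 1, min)))
  }
  mask_mean_nnd(x)
}

# NND over mask pixels: exact local search within a Chebyshev-2 window
# (any farther pixel is at Euclidean distance >= 3 > 2*sqrt(2), so a hit
# inside the window is the true nearest); isolated pixels fall back to a
# brute-force scan.
mask_mean_nnd <- function(mask) {
  pix <- which(mask > 0, arr.ind = TRUE)
  n <- nrow(pix)
  if (n < 2) stop("mean NND needs at least 2 points")
  R <- nrow(mask); C <- ncol(mask)
  m <- mask > 0
  best <- rep(Inf, n)
  for (dr in -2:2) for (dc in -2:2) {
    if (dr == 0 && dc == 0) next
    d <- sqrt(dr^2 + dc^2)
    rr <- pix[, 1] + dr; cc <- pix[, 2] + dc
    ok <- rr >= 1 & rr <= R & cc >= 1 & cc <= C
    hit <- ok
    hit[ok] <- m[cbind(rr[ok], cc[ok])]
    best[hit] <- pmin(best[hit], d)
  }
  iso <- which(!is.finite(best))
  if (length(iso)) {
    for (i in iso) {
      d2 <- (pix[, 1] - pix[i, 1])^2 + (pix[, 2] - pix[i, 2])^2
      d2[i] <- Inf
      best[i] <- sqrt(min(d2))
    }
  }
  mean(best)
}

#' Hotspot volume of a density map
#'
#' Total pixel area (at the working downscale) of analysis windows whose
#' density strictly exceeds `threshold` — the "volume" of high-density
#' innervation regions on one slice.
#'
#' @param dm A [compute_density_map()] result.
#' @param threshold Density threshold in `[0, 1]` (strict inequality). The
#'   conventional default is the lowest edge of the top logarithmic bin.
#' @return Pixel count (numeric scalar).
#' @export
hotspot_volume <- function(dm, threshold = NULL) {
  stopifnot(inherits(dm, "density_map"))
  if (is.null(threshold)) {
    edges <- log_bin_edges()
    threshold <- edges[length(edges) - 1L]
  }
  stopifnot(threshold >= 0, threshold <= 1)
  sum(dm$areas[dm$density > threshold])
}

#' Per-slice spatial metrics
#'
#' Computes the four per-slice innervation metrics from a density map
#' (and, for NND, the slice's fiber mask when available): Shannon
#' entropy, Moran's I, mean nearest-neighbour distance and hotspot
#' volume. Metrics whose preconditions fail (e.g. zero variance for
#' Moran's I) are reported as `NA`.
#'
#' @param dm A [compute_density_map()] result.
#' @param slice_index Slice position, 1 = apex.
#' @param fiber Optional [fiber_mask()] for the NND.
#' @param threshold Hotspot threshold (see [hotspot_volume()]).
#' @param edges Entropy histogram edges.
#' @param adjacency Moran's I adjacency.
#' @return One-row `data.frame` with columns `slice_index`, `entropy`,
#'   `morans_i`, `nnd_mean`, `hotspot_volume_px`.
#' @export
slice_metrics <- function(dm, slice_index, fiber = NULL, threshold = NULL,
                          edges = log_bin_edges(),
                          adjacency = c("queen", "rook")) {
  adjacency <- match.arg(adjacency)
  safe <- function(expr) tryCatch(expr, error = function(e) NA_real_)
  data.frame(
    slice_index = as.integer(slice_index),
    entropy = safe(shannon_entropy(dm, edges)),
    morans_i = safe(morans_i(dm$density, dm$covered, adjacency)),
    nnd_mean = if (is.null(fiber)) NA_real_ else safe(mean_nnd(fiber)),
    hotspot_volume_px = hotspot_volume(dm, threshold)
  )
}

#' Apex-to-base innervation profile
#'
#' Per-slice metrics for an ordered stack of density maps plus, for named
#' slice-index regions, the mean and Student-t 95% confidence interval of
#' each metric over the region's slices. Regions with a single slice
#' report the value with an undefined (NA) interval.
#'
#' @param slices List of [compute_density_map()] results ordered
#'   apex-to-base, or a list of `list(slice_index=, dm=, fiber=)`.
#' @param regions Named list of slice-index vectors (e.g.
#'   `list(apical = 1:2, mid = 3:5)`).
#' @param threshold,edges,adjacency Passed to [slice_metrics()].
#' @param fibers Optional list of [fiber_mask()]s parallel to `slices`.
#' @return An object of class `profile_table`: `metrics` (per-slice
#'   data.frame) and `summaries` (per-region data.frame with columns
#'   `region`, `metric`, `n`, `mean`, `ci_lo`, `ci_hi`).
#' @export
innervation_profile <- function(slices, regions = NULL, threshold = NULL,
                                edges = log_bin_edges(),
                                adjacency = c("queen", "rook"),
                                fibers = NULL) {
  adjacency <- match.arg(adjacency)
  if (length(slices) < 1) stop("need at least one slice")
  rows <- vector("list", length(slices))
  for (i in seq_along(slices)) {
    s <- slices[[i]]
    if (inherits(s, "density_map")) {
      dm <- s; idx <- i
      fb <- if (!is.null(fibers)) fibers[[i]]
    } else {
      dm <- s$dm; idx <- s$slice_index %||% i; fb <- s$fiber
    }
    rows[[i]] <- slice_metrics(dm, idx, fb, threshold, edges, adjacency)
  }
  metrics <- do.call(rbind, rows)
  metrics <- metrics[order(metrics$slice_index), ]
  summaries <- NULL
  if (!is.null(regions)) {
    out <- list()
    for (rn in names(regions)) {
      idx <- regions[[rn]]
      if (!all(idx %in% metrics$slice_index)) {
        stop("region '", rn, "' references absent slices")
      }
      sub <- metrics[metrics$slice_index %in% idx, ]
      for (mc in c("entropy", "morans_i", "nnd_mean", "hotspot_volume_px")) {
        v <- sub[[mc]][!is.na(sub[[mc]])]
        n <- length(v)
        mu <- if (n) mean(v) else NA_real_
        if (n >= 2) {
          half <- stats::qt(0.975, n - 1) * stats::sd(v) / sqrt(n)
          lo <- mu - half; hi <- mu + half
        } else {
          lo <- hi <- NA_real_
        }
        out[[length(out) + 1L]] <- data.frame(
          region = rn, metric = mc, n = n, mean = mu, ci_lo = lo, ci_hi = hi)
      }
    }
    summaries <- do.call(rbind, out)
  }
  structure(list(metrics = metrics, summaries = summaries),
            class = "profile_table")
}

#' @export
print.profile_table <- function(x, ...) {
  cat("Apex-to-base innervation profile\n")
  print(x$metrics, row.names = FALSE)
  if (!is.null(x$summaries)) {
    cat("\nRegion summaries (mean, 95% CI):\n")
    print(x$summaries, row.names = FALSE)
  }
  invisible(x)
}

#' Write a profile table to CSV (+ JSON summary)
#'
#' @param pt A [innervation_profile()] result.
#' @param path CSV output path; region summaries (if any) go to the same
#'   path with extension `.summary.json`.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(pt, path) {
  stopifnot(inherits(pt, "profile_table"))
  utils::write.csv(pt$metrics, path, row.names = FALSE)
  if (!is.null(pt$summaries)) {
    jsonlite::write_json(pt$summaries,
                         sub("\\.csv$", ".summary.json", path),
                         digits = NA, dataframe = "rows")
  }
  invisible(path)
}

#' Plot the innervation profile
#'
#' Four panels (entropy, Moran's I, NND, hotspot volume) against slice
#' index, apex on the left.
#'
#' @param pt A [innervation_profile()] result.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
plot_profile <- function(pt, path) {
  stopifnot(inherits(pt, "profile_table"))
  m <- pt$metrics
  grDevices::png(path, width = 900, height = 700)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  panels <- c(entropy = "Entropy (nats)", morans_i = "Moran's I",
              nnd_mean = "Mean NND (px)", hotspot_volume_px = "Hotspot volume (px)")
  for (nm in names(panels)) {
    graphics::plot(m$slice_index, m[[nm]], type = "b", pch = 19,
                   xlab = "Slice (1 = apex)", ylab = panels[[nm]])
  }
  invisible(path)
}
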