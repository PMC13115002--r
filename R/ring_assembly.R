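#' Fragment layout for ring reassembly
#'
#' A layout is the explicit description of where each histological
#' fragment of a myocardial ring sits on the assembled ring canvas: per
#' fragment a rigid placement (optional horizontal flip about the
#' fragment centre, rotation in degrees about the fragment centre,
#' translation in pixels) and a z-order resolving overlaps.
#'
#' @param ring_id Ring identifier.
#' @param fragments List of lists with fields `fragment_id`,
#'   `translation` (length-2 `(dx, dy)` px), `rotation` (degrees),
#'   `flip` (logical), `z_order` (integer).
#' @param canvas_size `(H, W)` of the assembled ring canvas.
#' @return An object of class `fragment_layout`.
#' @export
fragment_layout <- function(ring_id, fragments, canvas_size) {
  ids <- vapply(fragments, function(f) as.character(f$fragment_id), "")
  if (anyDuplicated(ids)) stop("fragment ids must be unique")
  fragments <- lapply(fragments, function(f) {
    list(fragment_id = as.character(f$fragment_id),
         translation = as.numeric(f$translation %||% c(0, 0)),
         rotation = as.numeric(f$rotation %||% 0),
         flip = isTRUE(f$flip),
         z_order = as.integer(f$z_order %||% 1L))
  })
  structure(list(ring_id = as.character(ring_id), fragments = fragments,
                 canvas_size = as.integer(canvas_size)),
            class = "fragment_layout")
}

#' @rdname fragment_layout
#' @param path JSON file path.
#' @export
read_layout_json <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = FALSE)
  fragment_layout(o$ring_id, o$fragments, unlist(o$canvas_size))
}

#' @rdname fragment_layout
#' @param layout A `fragment_layout`.
#' @export
write_layout_json <- function(layout, path) {
  jsonlite::write_json(unclass(layout), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

# Placement transform: fragment pixel (x, y) -> canvas coordinates.
# Flip (about the fragment's vertical centre axis), then rotation about
# the fragment centre, then translation.
placement_transform <- function(frag_dim, placement) {
  cx <- (frag_dim[2] - 1) / 2; cy <- (frag_dim[1] - 1) / 2
  ctr <- c(cx, cy)
  th <- placement$rotation * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  Fm <- if (isTRUE(placement$flip)) diag(c(-1, 1)) else diag(2)
  A <- R %*% Fm
  t <- ctr - A %*% ctr + placement$translation
  new_transform2d(if (isTRUE(placement$flip)) "affine" else "rigid",
                  A = A, t = as.vector(t))
}

#' Assemble a myocardial ring from fragments
#'
#' Rigidly places each fragment (flip, rotate, translate per the layout)
#' onto the ring canvas in increasing z-order; where transported tissue
#' overlaps, the higher z-order fragment wins. Image, tissue mask, fiber
#' mask and per-pixel density are transported with the same transform
#' (nearest-neighbour, preserving value ranges).
#'
#' @param fragments Named list (by fragment id) of lists with elements
#'   `image` (`H x W x 3`), `tissue` (binary matrix), optional `fiber`
#'   (binary matrix) and optional `density` (a [compute_density_map()]
#'   result, transported as a per-pixel density surface).
#' @param layout A [fragment_layout()].
#' @return An object of class `ring_composite`: `image`, `tissue`,
#'   `fiber` (or `NULL`), `density_px` (or `NULL`), `provenance` (integer
#'   matrix, 0 = empty, k = k-th layout fragment), `fragment_ids`,
#'   `area_change` (0), `ring_id`.
#' @export
assemble_ring <- function(fragments, layout) {
  stopifnot(inherits(layout, "fragment_layout"))
  H <- layout$canvas_size[1]; W <- layout$canvas_size[2]
  ord <- order(vapply(layout$fragments, `[[`, 1L, "z_order"))
  image <- array(255, dim = c(H, W, 3))
  tissue <- matrix(0L, H, W)
  prov <- matrix(0L, H, W)
  have_fiber <- all(vapply(fragments, function(f) !is.null(f$fiber), TRUE))
  have_dens <- all(vapply(fragments, function(f) !is.null(f$density), TRUE))
  fiber <- if (have_fiber) matrix(0L, H, W)
  dens_px <- if (have_dens) matrix(0, H, W)
  ids <- character(length(layout$fragments))
  for (k in seq_along(ord)) {
    pl <- layout$fragments[[ord[k]]]
    idx <- match(pl$fragment_id, names(fragments))
    if (is.na(idx)) stop("layout references absent fragment id: ", pl$fragment_id)
    fr <- fragments[[idx]]
    ids[ord[k]] <- pl$fragment_id
    tr <- placement_transform(dim(fr$tissue), pl)
    check_within_canvas(fr$tissue, tr, c(H, W), pl$fragment_id)
    tt <- apply_transform(fr$tissue, tr, c(H, W), "nearest", fill = 0)
    sel <- tt > 0
    img_t <- apply_transform(fr$image, tr, c(H, W), "nearest", fill = 255)
    for (ch in 1:3) {
      base <- image[, , ch]; base[sel] <- img_t[, , ch][sel]
      image[, , ch] <- base
    }
    tissue[sel] <- 1L
    prov[sel] <- ord[k]
    if (have_fiber) {
      ft <- apply_transform(fr$fiber, tr, c(H, W), "nearest", fill = 0)
      fiber[sel] <- as.integer(ft[sel] > 0)
    }
    if (have_dens) {
      dpx <- expand_density_px(fr$density, dim(fr$tissue))
      dt <- apply_transform(dpx, tr, c(H, W), "nearest", fill = 0)
      dens_px[sel] <- dt[sel]
    }
  }
  structure(list(image = image, tissue = tissue, fiber = fiber,
                 density_px = dens_px, provenance = prov,
                 fragment_ids = ids, area_change = 0,
                 refine_warning = FALSE, ring_id = layout$ring_id),
            class = "ring_composite")
}

#' @export
print.ring_composite <- function(x, ...) {
  cat(sprintf("<ring_composite '%s' %d x %d, %d fragments, %d tissue px, area_change %.4g>\n",
              x$ring_id, nrow(x$tissue), ncol(x$tissue),
              length(x$fragment_ids), sum(x$tissue), x$area_change))
  invisible(x)
}

# Expand a density map to per-pixel resolution on the fragment grid.
expand_density_px <- function(dm, frag_dim) {
  w <- dm$window_px
  ri <- pmin((seq_len(frag_dim[1]) - 1L) %/% w + 1L, nrow(dm$density))
  ci <- pmin((seq_len(frag_dim[2]) - 1L) %/% w + 1L, ncol(dm$density))
  dm$density[ri, ci, drop = FALSE]
}

check_within_canvas <- function(tissue, tr, canvas, id) {
  pix <- which(tissue > 0, arr.ind = TRUE)
  if (!nrow(pix)) return(invisible())
  # bounding-box corners of the tissue, (x, y) 0-based
  rx <- range(pix[, 2]) - 1; ry <- range(pix[, 1]) - 1
  corners <- cbind(rx[c(1, 2, 1, 2)], ry[c(1, 1, 2, 2)])
  mapped <- transform_points(tr, corners)
  if (any(mapped[, 1] < -0.5) || any(mapped[, 1] > canvas[2] - 0.5) ||
      any(mapped[, 2] < -0.5) || any(mapped[, 2] > canvas[1] - 0.5)) {
    stop("fragment exceeds canvas: ", id)
  }
}

#' Count seam-gap pixels of a composite
#'
#' Empty canvas pixels lying within `radius` of tissue from at least two
#' different fragments — the gaps (or residual mis-alignments) along
#' fragment seams.
#'
#' @param composite A [assemble_ring()] result.
#' @param radius Search radius in pixels.
#' @return Integer pixel count.
#' @export
seam_gap_pixels <- function(composite, radius = 3) {
  prov <- composite$provenance
  n <- max(prov)
  if (n < 2) return(0L)
  brush <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
  near <- matrix(0L, nrow(prov), ncol(prov))
  for (k in seq_len(n)) {
    dil <- EBImage::dilate(matrix(as.integer(prov == k), nrow(prov), ncol(prov)),
                           brush)
    near <- near + as.integer(dil > 0)
  }
  sum(prov == 0 & near >= 2)
}

#' Refine fragment seams with a bounded elastic correction
#'
#' Applies a small landmark-free thin-plate-spline warp that pulls facing
#' fragment boundaries toward their common seam, reducing seam gaps and
#' overlaps left by rigid placement. Correspondences are found within a
#' seam band of `band_px` between each pair of fragments; identity
#' anchors far from the seams keep the rest of the section fixed. If the
#' resulting tissue-area change would exceed `max_area_change` (relative
#' to the pre-correction tissue area), the composite is returned
#' unchanged with `refine_warning = TRUE`.
#'
#' @param composite A [assemble_ring()] result.
#' @param max_area_change Maximum allowed relative tissue-area change
#'   (default 0.01, i.e. 1% of the section area).
#' @param band_px Seam band half-width in pixels.
#' @param lambda TPS regularization for the seam warp.
#' @param max_pairs Maximum boundary correspondences per fragment pair.
#' @return A `ring_composite` with `area_change` set (or the input with
#'   `refine_warning = TRUE` if the bound would be violated).
#' @export
refine_boundaries <- function(composite, max_area_change = 0.01,
                              band_px = 10, lambda = 1, max_pairs = 150) {
  stopifnot(inherits(composite, "ring_composite"))
  prov <- composite$provenance
  nfrag <- max(prov)
  if (nfrag < 2) { composite$area_change <- 0; return(composite) }
  H <- nrow(prov); W <- ncol(prov)
  corr <- seam_correspondences(prov, band_px, max_pairs)
  if (is.null(corr) || nrow(corr$src) == 0) {
    composite$area_change <- 0
    return(composite)
  }
  # forward warp pulling both facing edges onto the seam midline; the
  # steep part of the displacement field lives in the (empty) gap, so
  # tissue itself is only gently displaced and does not fold
  mids <- (corr$src + corr$dst) / 2
  nvec <- corr$dst - corr$src
  nrm <- sqrt(rowSums(nvec^2)); nrm[nrm == 0] <- 1
  nvec <- nvec / nrm
  # edges land half a pixel to each side of the midline: touching, not
  # overlapping
  fsrc <- rbind(corr$src, corr$dst)
  ftgt <- rbind(mids - 0.5 * nvec, mids + 0.5 * nvec)
  anchors <- seam_anchors(prov, band_px, H, W)
  fsrc <- rbind(fsrc, anchors); ftgt <- rbind(ftgt, anchors)
  keep <- !duplicated(round(fsrc, 3))
  wt <- fit_tps(landmark_pairs(fsrc[keep, , drop = FALSE],
                               ftgt[keep, , drop = FALSE]), lambda = lambda)
  warped <- splat_forward(composite, wt)
  area_before <- sum(prov > 0)
  area_after <- sum(warped$provenance > 0)
  rel <- abs(area_after - area_before) / area_before
  if (rel > max_area_change) {
    composite$refine_warning <- TRUE
    warning(sprintf("seam correction aborted: area change %.3g exceeds bound %.3g",
                    rel, max_area_change))
    return(composite)
  }
  out <- composite
  out$provenance <- warped$provenance
  out$tissue <- matrix(as.integer(warped$provenance > 0), H, W)
  out$image <- warped$image
  out$fiber <- warped$fiber
  out$density_px <- warped$density_px
  out$area_change <- rel
  out
}

# Push every tissue pixel through the forward warp (nearest target
# pixel; later z-order fragments win collisions), then fill the isolated
# holes that rounding of a smooth displacement field can leave inside
# tissue.
splat_forward <- function(composite, wt) {
  prov <- composite$provenance
  H <- nrow(prov); W <- ncol(prov)
  pix <- which(prov > 0, arr.ind = TRUE)
  xy <- cbind(pix[, 2] - 1, pix[, 1] - 1)
  mapped <- round(transform_points(wt, xy))
  tr <- mapped[, 2] + 1; tc <- mapped[, 1] + 1
  ok <- tr >= 1 & tr <= H & tc >= 1 & tc <= W
  ordz <- order(prov[pix])          # ascending z: later fragments overwrite
  sel <- ordz[ok[ordz]]
  tgt <- cbind(tr[sel], tc[sel])
  src <- pix[sel, , drop = FALSE]
  new_prov <- matrix(0L, H, W)
  new_prov[tgt] <- prov[src]
  image <- array(255, dim = c(H, W, 3))
  for (ch in 1:3) {
    plane <- matrix(255, H, W)
    plane[tgt] <- composite$image[, , ch][src]
    image[, , ch] <- plane
  }
  fiber <- NULL
  if (!is.null(composite$fiber)) {
    fiber <- matrix(0L, H, W)
    fiber[tgt] <- composite$fiber[src]
  }
  dens <- NULL
  if (!is.null(composite$density_px)) {
    dens <- matrix(0, H, W)
    dens[tgt] <- composite$density_px[src]
  }
  # fill 1-px holes: empty pixels with >= 6 tissue neighbours
  nb <- neighbour_count(new_prov > 0)
  holes <- which(new_prov == 0 & nb >= 6, arr.ind = TRUE)
  if (nrow(holes)) {
    for (hh in seq_len(nrow(holes))) {
      r <- holes[hh, 1]; c <- holes[hh, 2]
      rr <- max(1, r - 1):min(H, r + 1); cc <- max(1, c - 1):min(W, c + 1)
      labs <- new_prov[rr, cc]
      lab <- as.integer(names(which.max(table(labs[labs > 0]))))
      new_prov[r, c] <- lab
      donors <- which(labs == lab, arr.ind = TRUE)
      dr <- rr[donors[1, 1]]; dc <- cc[donors[1, 2]]
      for (ch in 1:3) image[r, c, ch] <- image[dr, dc, ch]
      if (!is.null(fiber)) fiber[r, c] <- 0L       # conservative: no duplicated fibers
      if (!is.null(dens)) dens[r, c] <- dens[dr, dc]
    }
  }
  list(provenance = new_prov, image = image, fiber = fiber, density_px = dens)
}

# number of TRUE 8-neighbours per cell
neighbour_count <- function(m) {
  H <- nrow(m); W <- ncol(m)
  p <- matrix(0L, H + 2, W + 2)
  p[2:(H + 1), 2:(W + 1)] <- as.integer(m)
  out <- matrix(0L, H, W)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    out <- out + p[2:(H + 1) + dr, 2:(W + 1) + dc]
  }
  out
}

# Boundary-to-boundary correspondences between every pair of fragments
# whose edges approach within band_px.
seam_correspondences <- function(prov, band_px, max_pairs) {
  nfrag <- max(prov)
  H <- nrow(prov); W <- ncol(prov)
  bound <- vector("list", nfrag)
  for (k in seq_len(nfrag)) {
    mk <- prov == k
    er <- mk
    er[-1, ] <- er[-1, ] & mk[-H, ]; er[-H, ] <- er[-H, ] & mk[-1, ]
    er[, -1] <- er[, -1] & mk[, -W]; er[, -W] <- er[, -W] & mk[, -1]
    pix <- which(mk & !er, arr.ind = TRUE)
    bound[[k]] <- cbind(pix[, 2] - 1, pix[, 1] - 1)   # (x, y)
  }
  src <- dst <- matrix(0, 0, 2)
  min_evidence <- 8L
  for (i in seq_len(nfrag - 1)) for (j in (i + 1):nfrag) {
    bi <- bound[[i]]; bj <- bound[[j]]
    if (!nrow(bi) || !nrow(bj)) next
    n_take <- min(max_pairs, nrow(bi))
    take <- bi[round(seq(1, nrow(bi), length.out = n_take)), , drop = FALSE]
    psrc <- pdst <- matrix(0, 0, 2)
    for (r in seq_len(nrow(take))) {
      p <- take[r, ]
      d2 <- (bj[, 1] - p[1])^2 + (bj[, 2] - p[2])^2
      q <- bj[which.min(d2), ]
      # only pull edges that face an actual gap: the pair must be
      # separated (distance >= 2) and the segment between them must
      # cross empty canvas, so touching seams and facing arc contours
      # are left alone
      gap_between <- any(vapply(c(0.25, 0.5, 0.75), function(tt) {
        m <- round(p + tt * (q - p))
        prov[m[2] + 1, m[1] + 1] == 0
      }, TRUE))
      if (min(d2) >= 4 && min(d2) <= band_px^2 && gap_between) {
        psrc <- rbind(psrc, p); pdst <- rbind(pdst, q)
      }
    }
    # act only on substantial evidence of a genuine seam gap; a handful
    # of accidental matches along facing arc contours is left alone
    if (nrow(psrc) >= min_evidence) {
      src <- rbind(src, psrc); dst <- rbind(dst, pdst)
    }
  }
  if (!nrow(src)) return(NULL)
  list(src = src, dst = dst)
}

# Identity anchor points on a coarse grid away from all seams, plus the
# canvas corners, keeping the warp local to the seams.
seam_anchors <- function(prov, band_px, H, W) {
  step <- max(as.integer(band_px), 8L)
  gx <- seq(0, W - 1, by = step); gy <- seq(0, H - 1, by = step)
  grid <- cbind(rep(gx, each = length(gy)), rep(gy, times = length(gx)))
  # keep anchors whose band-sized neighbourhood sees at most one fragment
  nfrag <- max(prov)
  brush <- EBImage::makeBrush(2L * as.integer(band_px) + 1L, shape = "disc")
  near <- matrix(0L, H, W)
  for (k in seq_len(nfrag)) {
    dil <- EBImage::dilate(matrix(as.integer(prov == k), H, W), brush)
    near <- near + as.integer(dil > 0)
  }
  keep <- near[cbind(grid[, 2] + 1, grid[, 1] + 1)] <= 1L
  corners <- cbind(c(0, W - 1, 0, W - 1), c(0, 0, H - 1, H - 1))
  unique(rbind(grid[keep, , drop = FALSE], corners))
}
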