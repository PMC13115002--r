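#' Tissue-mask parameters
#'
#' Controls the background-removal stage that separates intact tissue from
#' glass. A pixel is kept when its blurred grayscale is darker than
#' `brightness_max` or (with `combine = "or"`, the default) its Sobel
#' gradient magnitude reaches `gradient_min`; small connected components
#' are then dropped and the mask is dilated.
#'
#' Defaults are tuned for a 16x-downscaled brightfield slide and are
#' engineering choices — all of them should be reviewed per staining batch.
#'
#' @param blur_sigma Gaussian blur standard deviation in pixels (`>= 0`).
#' @param brightness_max Grayscale threshold in `[0, 255]`; pixels strictly
#'   darker than this count as tissue.
#' @param gradient_min Sobel gradient-magnitude threshold (`>= 0`).
#' @param min_area_px Minimum connected-component area kept, inclusive.
#' @param dilate_radius Disc radius (px) for the final binary dilation.
#' @param combine How brightness and gradient criteria combine:
#'   `"or"` (default) or `"and"`.
#' @return An object of class `mask_params`.
#' @export
mask_params <- function(blur_sigma = 2, brightness_max = 220,
                        gradient_min = 10, min_area_px = 500,
                        dilate_radius = 3, combine = c("or", "and")) {
  combine <- match.arg(combine)
  stopifnot(blur_sigma >= 0, brightness_max >= 0, brightness_max <= 255,
            gradient_min >= 0, min_area_px >= 0, dilate_radius >= 0)
  structure(list(blur_sigma = blur_sigma, brightness_max = brightness_max,
                 gradient_min = gradient_min,
                 min_area_px = as.integer(min_area_px),
                 dilate_radius = as.integer(dilate_radius),
                 combine = combine),
            class = "mask_params")
}

# ITU-R BT.601 luma
rgb_to_gray <- function(pixels) {
  0.299 * pixels[, , 1] + 0.587 * pixels[, , 2] + 0.114 * pixels[, , 3]
}

gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  # kernel clamped to the image so tiny test images stay valid
  size <- 2L * as.integer(ceiling(2.5 * sigma)) + 1L
  size <- min(size, 2L * ((min(dim(m)) - 1L) %/% 2L) + 1L)
  if (size < 3L) return(m)
  k <- EBImage::makeBrush(size, shape = "Gaussian", sigma = sigma)
  EBImage::filter2(m, k, boundary = "replicate")
}

sobel_magnitude <- function(m) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  if (min(dim(m)) < 3L) return(matrix(0, nrow(m), ncol(m)))
  gx <- EBImage::filter2(m, kx, boundary = "replicate")
  gy <- EBImage::filter2(m, t(kx), boundary = "replicate")
  sqrt(gx^2 + gy^2)
}

#' Segment tissue from background
#'
#' Grayscale conversion, Gaussian blurring, brightness/gradient threshold
#' filtering, small-component removal and morphological dilation, yielding
#' a binary mask of intact tissue on the working (downscaled) slide.
#'
#' @param slide A [slide_image()].
#' @param params A [mask_params()].
#' @return An object of class `tissue_mask`: list with `mask` (integer
#'   `H x W` matrix of 0/1) and `params`.
#' @export
compute_tissue_mask <- function(slide, params = mask_params()) {
  stopifnot(inherits(slide, "slide_image"), inherits(params, "mask_params"))
  g <- gaussian_blur(rgb_to_gray(slide$pixels), params$blur_sigma)
  dark <- g < params$brightness_max
  edge <- sobel_magnitude(g) >= params$gradient_min
  keep <- if (params$combine == "or") dark | edge else dark & edge
  m <- matrix(as.integer(keep), nrow(keep), ncol(keep))
  m <- filter_components(m, params$min_area_px)
  if (params$dilate_radius > 0 && any(m > 0)) {
    brush <- EBImage::makeBrush(2L * params$dilate_radius + 1L, shape = "disc")
    m <- matrix(as.integer(EBImage::dilate(m, brush) > 0), nrow(m), ncol(m))
  }
  structure(list(mask = m, params = params), class = "tissue_mask")
}

#' @export
print.tissue_mask <- function(x, ...) {
  cat(sprintf("<tissue_mask %d x %d, %d tissue px (%.1f%%)>\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask),
              100 * mean(x$mask)))
  invisible(x)
}

# 8-connected labeling: EBImage::bwlabel is 4-connected, so merge labels
# that touch diagonally with a union-find over label ids.
label_components8 <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  n <- max(lab)
  if (n <= 1L) return(lab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union2 <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[rb] <<- ra }
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),   # down-right
    cbind(as.vector(lab[-1, -nc]),  as.vector(lab[-nr, -1]))   # up-right
  )
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  if (nrow(pairs)) {
    pairs <- unique(pairs)
    for (i in seq_len(nrow(pairs))) union2(pairs[i, 1], pairs[i, 2])
  }
  roots <- vapply(seq_len(n), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

#' Remove small connected components
#'
#' Drops every 8-connected component of a binary mask whose pixel area is
#' strictly below `min_area_px` (the threshold is inclusive: a component of
#' exactly `min_area_px` pixels survives).
#'
#' @param mask Binary matrix (0/1 or logical).
#' @param min_area_px Minimum area in pixels, inclusive.
#' @return Integer 0/1 matrix, a subset of the input.
#' @export
filter_components <- function(mask, min_area_px) {
  m <- matrix(as.integer(mask > 0), nrow(mask), ncol(mask))
  if (min_area_px <= 1L || !any(m > 0)) return(m)
  lab <- label_components8(m)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area_px)
  matrix(as.integer(lab %in% keep), nrow(m), ncol(m))
}
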