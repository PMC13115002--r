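#' HSV colour range for chromogen classification
#'
#' Inclusive per-channel bounds on the 8-bit HSV convention: hue on
#' 0–179 (half-degrees), saturation and value on 0–255. The defaults are
#' a published working range for UCHL-1 DAB staining; they must be
#' recalibrated per detection system, antibody dilution and counterstain
#' intensity.
#'
#' @param h,s,v Length-2 numeric `(lo, hi)` bounds, `lo <= hi`.
#' @return An object of class `hsv_range`.
#' @export
hsv_range <- function(h = c(0, 80), s = c(12, 125), v = c(31, 162)) {
  chk <- function(x, hi, name) {
    if (length(x) != 2L || x[1] > x[2] || x[1] < 0 || x[2] > hi) {
      stop(sprintf("%s bounds must satisfy 0 <= lo <= hi <= %d", name, hi))
    }
  }
  chk(h, 179L, "hue"); chk(s, 255L, "saturation"); chk(v, 255L, "value")
  structure(list(h = h, s = s, v = v), class = "hsv_range")
}

#' Convert 8-bit RGB to 8-bit HSV
#'
#' Returns hue in `[0, 179]` (half-degrees), saturation and value in
#' `[0, 255]`, matching the common 8-bit computer-vision convention.
#' Achromatic pixels get hue 0.
#'
#' @param pixels `H x W x 3` array of values in `[0, 255]`.
#' @return `H x W x 3` array: channels H, S, V.
#' @export
rgb_to_hsv8 <- function(pixels) {
  d <- dim(pixels)
  stopifnot(length(d) == 3L, d[3] == 3L)
  rgb <- rbind(as.vector(pixels[, , 1]), as.vector(pixels[, , 2]),
               as.vector(pixels[, , 3]))
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 255)
  out <- array(0, dim = d)
  out[, , 1] <- round(hsv[1, ] * 180) %% 180   # 0..179 half-degrees
  out[, , 2] <- round(hsv[2, ] * 255)
  out[, , 3] <- round(hsv[3, ] * 255)
  out
}

#' Classify nerve-fiber pixels by HSV range
#'
#' A working-image pixel is classified as a nerve fiber iff it lies inside
#' the tissue mask and each of its H, S, V components falls within the
#' inclusive bounds of `range`. Classification is performed exclusively
#' within the tissue mask; spatial coordinates are preserved relative to
#' the slide.
#'
#' @param slide A [slide_image()].
#' @param tissue A [compute_tissue_mask()] result (or a binary matrix of
#'   the same shape as the slide).
#' @param range An [hsv_range()].
#' @return An object of class `fiber_mask`: list with `mask` (0/1 matrix),
#'   `mpp_eff`, `slide_ref`.
#' @export
classify_fibers <- function(slide, tissue, range = hsv_range()) {
  stopifnot(inherits(slide, "slide_image"), inherits(range, "hsv_range"))
  tm <- if (inherits(tissue, "tissue_mask")) tissue$mask else
    matrix(as.integer(tissue > 0), nrow(tissue), ncol(tissue))
  d <- dim(slide$pixels)
  if (!all(dim(tm) == d[1:2])) stop("tissue mask shape does not match slide")
  hsv <- rgb_to_hsv8(slide$pixels)
  inr <- hsv[, , 1] >= range$h[1] & hsv[, , 1] <= range$h[2] &
         hsv[, , 2] >= range$s[1] & hsv[, , 2] <= range$s[2] &
         hsv[, , 3] >= range$v[1] & hsv[, , 3] <= range$v[2]
  fiber_mask(matrix(as.integer(inr & tm > 0), d[1], d[2]),
             mpp_eff = effective_mpp(slide), slide_ref = slide$source_id)
}

#' Construct a fiber mask
#'
#' @param mask Binary `H x W` matrix; 1 marks a fiber-classified pixel.
#' @param mpp_eff Effective microns per pixel of the working image.
#' @param slide_ref Source slide identifier.
#' @return An object of class `fiber_mask`.
#' @export
fiber_mask <- function(mask, mpp_eff, slide_ref = "slide") {
  m <- matrix(as.integer(mask > 0), nrow(mask), ncol(mask))
  stopifnot(mpp_eff > 0)
  structure(list(mask = m, mpp_eff = mpp_eff,
                 slide_ref = as.character(slide_ref)),
            class = "fiber_mask")
}

#' @export
print.fiber_mask <- function(x, ...) {
  cat(sprintf("<fiber_mask '%s' %d x %d, %d fiber px, %.3g um/px>\n",
              x$slide_ref, nrow(x$mask), ncol(x$mask), sum(x$mask),
              x$mpp_eff))
  invisible(x)
}
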