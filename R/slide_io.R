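#' Construct a slide image
#'
#' A `slide_image` is the in-memory working representation of a scanned
#' histology slide: an 8-bit RGB pixel grid plus the physical resolution
#' metadata needed to convert between pixels and microns.
#'
#' @param pixels Numeric array `H x W x 3` with values in `[0, 255]`.
#' @param mpp_base Microns per pixel at the slide's native resolution
#'   (before any downscaling). Must be `> 0`.
#' @param downscale Integer downscale factor already applied to `pixels`
#'   relative to the native scan (`>= 1`).
#' @param source_id Opaque identifier for the source slide.
#' @return An object of class `slide_image`.
#' @seealso [load_slide()], [effective_mpp()]
#' @export
slide_image <- function(pixels, mpp_base, downscale = 1L, source_id = "slide") {
  if (is.matrix(pixels)) {
    pixels <- array(rep(pixels, 3L), dim = c(dim(pixels), 3L))
  }
  stopifnot(is.array(pixels), length(dim(pixels)) == 3L, dim(pixels)[3] == 3L)
  if (any(pixels < 0) || any(pixels > 255)) {
    stop("pixel values must lie in [0, 255]")
  }
  if (!is.numeric(mpp_base) || length(mpp_base) != 1L || is.na(mpp_base) ||
      mpp_base <= 0) {
    stop("mpp_base must be a single positive number")
  }
  downscale <- as.integer(downscale)
  if (is.na(downscale) || downscale < 1L) stop("downscale must be >= 1")
  structure(
    list(pixels = pixels, mpp_base = mpp_base, downscale = downscale,
         source_id = as.character(source_id)),
    class = "slide_image"
  )
}

#' @export
print.slide_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<slide_image '%s': %d x %d px, mpp_base = %g, downscale = %d (effective %g um/px)>\n",
              x$source_id, d[1], d[2], x$mpp_base, x$downscale,
              effective_mpp(x)))
  invisible(x)
}

#' @export
dim.slide_image <- function(x) dim(x$pixels)[1:2]

#' Effective resolution of a working image
#'
#' The physical size of one pixel of the (possibly downscaled) working
#' image: `mpp_base * downscale` microns per pixel.
#'
#' @param slide A [slide_image()].
#' @return Microns per pixel (numeric scalar).
#' @export
effective_mpp <- function(slide) {
  stopifnot(inherits(slide, "slide_image"))
  slide$mpp_base * slide$downscale
}

#' Load a raster slide image
#'
#' Reads a PNG or TIFF slide image, applies integer-factor box (area)
#' downsampling, and attaches resolution metadata. Area averaging is used
#' because downstream density estimates are pixel-count fractions, which
#' box filtering preserves in the mean.
#'
#' Resolution is taken from the file's DPI / resolution tags when present
#' (converted to microns per pixel); otherwise `mpp` must be supplied.
#'
#' @param path Path to a PNG or TIFF file.
#' @param downscale Integer downscale factor `>= 1`.
#' @param mpp Optional microns-per-pixel override for files without
#'   resolution metadata (or to trust the caller over the file).
#' @param source_id Identifier; defaults to the file name.
#' @return A [slide_image()].
#' @export
load_slide <- function(path, downscale = 1L, mpp = NULL, source_id = NULL) {
  if (!file.exists(path)) stop("cannot read slide: ", path)
  downscale <- as.integer(downscale)
  if (is.na(downscale) || downscale < 1L) stop("downscale must be >= 1")
  ext <- tolower(tools::file_ext(path))
  file_mpp <- NULL
  if (ext == "png") {
    raw <- png::readPNG(path, info = TRUE)
    info <- attr(raw, "info")
    if (!is.null(info$dpi) && all(is.finite(info$dpi)) && info$dpi[1] > 0) {
      file_mpp <- 25400 / info$dpi[1]
    }
  } else if (ext %in% c("tif", "tiff")) {
    raw <- tiff::readTIFF(path, info = TRUE)
    info <- attributes(raw)
    if (!is.null(info$x.resolution) && isTRUE(info$x.resolution > 0)) {
      unit <- if (is.null(info$resolution.unit)) "inch" else info$resolution.unit
      per_um <- switch(unit,
                       inch = info$x.resolution / 25400,
                       cm   = info$x.resolution / 10000,
                       info$x.resolution / 25400)
      file_mpp <- 1 / per_um
    }
  } else {
    stop("unsupported image format: ", ext)
  }
  mpp_base <- if (!is.null(mpp)) mpp else file_mpp
  if (is.null(mpp_base)) {
    stop("missing mpp: file carries no resolution metadata and no `mpp` override given")
  }
  px <- array(as.numeric(raw), dim = dim(raw))   # drop reader attributes
  if (length(dim(px)) == 2L) px <- array(rep(px, 3L), dim = c(dim(px), 3L))
  if (dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]  # drop alpha
  px <- round(px * 255)
  if (downscale > 1L) px <- box_downscale(px, downscale)
  slide_image(px, mpp_base = mpp_base, downscale = downscale,
              source_id = if (is.null(source_id)) basename(path) else source_id)
}

# Box (area) downsampling by an integer factor; partial edge blocks are
# averaged over their true pixel count.
box_downscale <- function(pixels, factor) {
  factor <- as.integer(factor)
  d <- dim(pixels)
  ri <- (seq_len(d[1]) - 1L) %/% factor + 1L
  ci <- (seq_len(d[2]) - 1L) %/% factor + 1L
  nr <- max(ri); nc <- max(ci)
  rcount <- tabulate(ri, nr); ccount <- tabulate(ci, nc)
  out <- array(0, dim = c(nr, nc, d[3]))
  for (ch in seq_len(d[3])) {
    s <- rowsum(pixels[, , ch], ri, reorder = TRUE)      # nr x W
    s <- t(rowsum(t(s), ci, reorder = TRUE))             # nr x nc
    out[, , ch] <- s / outer(rcount, ccount)
  }
  out
}

#' Write a slide image to PNG
#'
#' Writes 8-bit RGB with a DPI tag encoding the effective resolution, so
#' that reloading with `downscale = 1` recovers both pixels and mpp.
#'
#' @param slide A [slide_image()].
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_slide_png <- function(slide, path) {
  stopifnot(inherits(slide, "slide_image"))
  png::writePNG(round(slide$pixels) / 255, path,
                dpi = 25400 / effective_mpp(slide))
  invisible(path)
}
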