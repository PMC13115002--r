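#' Phantom specification
#'
#' Describes a synthetic immunostained slide with exact ground truth:
#' tissue geometry on the canvas, a fiber-fraction field in `[0,1]`, and
#' the stain colours. Each tissue pixel is independently drawn as a fiber
#' pixel with probability given by the field (Bernoulli truth model — the
#' density metric is pixel-count based, so per-pixel sampling is the
#' natural ground truth).
#'
#' Default colours emulate DAB-brown fibers on a hematoxylin-blue
#' counterstain over white glass, and are chosen to sit strictly inside
#' (fiber) respectively outside (tissue, background) the default
#' [hsv_range()], so phantom pixel classification is exact by
#' construction.
#'
#' @param seed RNG seed; identical specs produce bit-identical phantoms.
#' @param canvas `(H, W)` canvas size in pixels.
#' @param mpp_eff Effective microns per pixel of the phantom working
#'   image (default 8, i.e. a 0.5 um/px scan downscaled 16x).
#' @param geometry List with `type` (`"disc"`, `"annulus"`,
#'   `"half_annulus"`), optional `center` `(x, y)` (default canvas
#'   centre), `r_outer`, `r_inner` in pixels.
#' @param fiber_fraction Scalar, `H x W` matrix, or `function(x, y)`
#'   giving the per-pixel fiber probability in `[0, 1]`.
#' @param colors List with RGB triplets `fiber`, `tissue`, `background`.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(seed = 1L, canvas = c(256L, 256L), mpp_eff = 8,
                         geometry = list(type = "annulus"),
                         fiber_fraction = 0.05,
                         colors = list(fiber = c(120, 108, 82),
                                       tissue = c(190, 185, 220),
                                       background = c(255, 255, 255))) {
  canvas <- as.integer(canvas)
  stopifnot(length(canvas) == 2, all(canvas >= 8), mpp_eff > 0)
  geometry$type <- match.arg(geometry$type, c("disc", "annulus", "half_annulus"))
  if (is.null(geometry$center)) {
    geometry$center <- c((canvas[2] - 1) / 2, (canvas[1] - 1) / 2)
  }
  if (is.null(geometry$r_outer)) geometry$r_outer <- 0.4 * min(canvas)
  if (is.null(geometry$r_inner)) {
    geometry$r_inner <- if (geometry$type == "disc") 0 else 0.5 * geometry$r_outer
  }
  if (geometry$r_outer <= 0 || geometry$r_inner < 0 ||
      geometry$r_inner >= geometry$r_outer ||
      geometry$r_outer > min(canvas) / 2) {
    stop("degenerate phantom geometry")
  }
  structure(list(seed = as.integer(seed), canvas = canvas, mpp_eff = mpp_eff,
                 geometry = geometry, fiber_fraction = fiber_fraction,
                 colors = colors),
            class = "phantom_spec")
}

# Evaluate code under a fixed seed without disturbing the caller's RNG.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

phantom_tissue <- function(spec) {
  H <- spec$canvas[1]; W <- spec$canvas[2]
  g <- spec$geometry
  x <- matrix(rep(seq_len(W) - 1, each = H), H, W)
  y <- matrix(rep(seq_len(H) - 1, times = W), H, W)
  dx <- x - g$center[1]; dy <- y - g$center[2]
  r2 <- dx^2 + dy^2
  m <- r2 <= g$r_outer^2 & r2 >= g$r_inner^2
  if (g$type == "half_annulus") m <- m & dy <= 0
  matrix(as.integer(m), H, W)
}

phantom_field <- function(spec, tissue) {
  H <- spec$canvas[1]; W <- spec$canvas[2]
  f <- spec$fiber_fraction
  fld <- if (is.function(f)) {
    x <- matrix(rep(seq_len(W) - 1, each = H), H, W)
    y <- matrix(rep(seq_len(H) - 1, times = W), H, W)
    f(x, y)
  } else if (is.matrix(f)) f else matrix(f, H, W)
  stopifnot(all(dim(fld) == c(H, W)), all(fld >= 0), all(fld <= 1))
  fld * (tissue > 0)
}

#' Generate a phantom slide with ground truth
#'
#' @param spec A [phantom_spec()].
#' @return List: `slide` (a [slide_image()]), `truth` (exact
#'   [fiber_mask()]), `tissue` (binary matrix), `field` (the realized
#'   fiber-fraction field, zero outside tissue).
#' @export
make_phantom_slide <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  tissue <- phantom_tissue(spec)
  if (!any(tissue > 0)) stop("degenerate phantom geometry: no tissue pixels")
  field <- phantom_field(spec, tissue)
  H <- spec$canvas[1]; W <- spec$canvas[2]
  fiber <- matrix(0L, H, W)
  idx <- which(tissue > 0)
  fiber[idx] <- with_seed(spec$seed,
                          as.integer(stats::runif(length(idx)) < field[idx]))
  img <- array(0, dim = c(H, W, 3))
  for (ch in 1:3) {
    plane <- matrix(spec$colors$background[ch], H, W)
    plane[tissue > 0] <- spec$colors$tissue[ch]
    plane[fiber > 0] <- spec$colors$fiber[ch]
    img[, , ch] <- plane
  }
  list(slide = slide_image(img, mpp_base = spec$mpp_eff, downscale = 1L,
                           source_id = sprintf("phantom_seed%d", spec$seed)),
       truth = fiber_mask(fiber, mpp_eff = spec$mpp_eff,
                          slide_ref = sprintf("phantom_seed%d", spec$seed)),
       tissue = tissue, field = field)
}

translation_transform <- function(dxy) {
  new_transform2d("rigid", A = diag(2), t = as.numeric(dxy))
}

compose_transforms <- function(outer, inner) {
  # (outer o inner)(x) = A_o (A_i x + t_i) + t_o
  stopifnot(outer$kind != "tps", inner$kind != "tps")
  new_transform2d("affine", A = outer$A %*% inner$A,
                  t = as.vector(outer$A %*% inner$t + outer$t))
}

#' Generate a fragmented phantom ring
#'
#' Cuts a phantom annulus into `n_fragments` angular sectors, displaces
#' each into its own fragment canvas by the inverse of a known rigid
#' placement (rotations are multiples of 90 degrees and translations are
#' integer, so the round trip through nearest-neighbour resampling is
#' exact), and optionally perturbs each fragment by an integer seam
#' jitter so reassembly leaves seam gaps for [refine_boundaries()] to
#' close.
#'
#' @param spec A [phantom_spec()] with annulus geometry.
#' @param n_fragments Number of angular sectors (`>= 1`).
#' @param placements Optional list of per-fragment placements (fields
#'   `translation`, `rotation`, `flip`); defaults to deterministic 90
#'   degree rotations with small integer translations.
#' @param seam_jitter Integer magnitude (px) of random per-fragment
#'   displacement applied before cutting (emulating processing
#'   deformation), or an `n_fragments x 2` matrix of explicit `(dx, dy)`
#'   displacements.
#' @return List: `fragments` (named list of `image`/`tissue`/`fiber`),
#'   `layout` (a [fragment_layout()]), `truth` (the uncut
#'   `ring_composite`), `slide`, `field`.
#' @export
make_phantom_ring <- function(spec, n_fragments = 3, placements = NULL,
                              seam_jitter = 0) {
  stopifnot(inherits(spec, "phantom_spec"))
  n_fragments <- as.integer(n_fragments)
  if (is.na(n_fragments) || n_fragments < 1) stop("invalid n_fragments")
  ph <- make_phantom_slide(spec)
  H <- spec$canvas[1]; W <- spec$canvas[2]
  g <- spec$geometry
  x <- matrix(rep(seq_len(W) - 1, each = H), H, W)
  y <- matrix(rep(seq_len(H) - 1, times = W), H, W)
  ang <- atan2(y - g$center[2], x - g$center[1]) %% (2 * pi)
  sector <- pmin(floor(ang / (2 * pi / n_fragments)) + 1L, n_fragments)
  prov <- matrix(0L, H, W)
  prov[ph$tissue > 0] <- sector[ph$tissue > 0]
  if (is.null(placements)) {
    placements <- lapply(seq_len(n_fragments), function(k) {
      list(translation = c(((k * 13L) %% 11L) - 5L, ((k * 7L) %% 11L) - 5L),
           rotation = 90 * ((k - 1L) %% 4L), flip = FALSE)
    })
  }
  if (is.matrix(seam_jitter)) {
    stopifnot(nrow(seam_jitter) == n_fragments, ncol(seam_jitter) == 2)
    jit <- round(seam_jitter)
  } else if (seam_jitter > 0) {
    jit <- with_seed(spec$seed + 9999L, matrix(
      sample(seq(-as.integer(seam_jitter), as.integer(seam_jitter)),
             2L * n_fragments, replace = TRUE), n_fragments, 2))
  } else {
    jit <- matrix(0L, n_fragments, 2)
  }
  fragments <- list()
  frag_defs <- vector("list", n_fragments)
  for (k in seq_len(n_fragments)) {
    pl <- placements[[k]]
    P <- placement_transform(c(H, W), pl)
    C <- compose_transforms(invert_transform(P), translation_transform(jit[k, ]))
    sel <- prov == k
    msk <- function(m, fillv) { m2 <- m; m2[!sel] <- fillv; m2 }
    img_k <- ph$slide$pixels
    for (ch in 1:3) img_k[, , ch][!sel] <- spec$colors$background[ch]
    as_bin <- function(m) matrix(as.integer(m > 0), H, W)
    fragments[[sprintf("f%d", k)]] <- list(
      image = apply_transform(img_k, C, c(H, W), "nearest", fill = 255),
      tissue = as_bin(apply_transform(msk(ph$tissue, 0L), C, c(H, W),
                                      "nearest", 0)),
      fiber = as_bin(apply_transform(msk(ph$truth$mask, 0L), C, c(H, W),
                                     "nearest", 0)))
    frag_defs[[k]] <- list(fragment_id = sprintf("f%d", k),
                           translation = pl$translation,
                           rotation = pl$rotation, flip = isTRUE(pl$flip),
                           z_order = k)
  }
  layout <- fragment_layout(sprintf("ring_seed%d", spec$seed), frag_defs,
                            c(H, W))
  truth <- structure(list(image = ph$slide$pixels, tissue = ph$tissue,
                          fiber = ph$truth$mask, density_px = NULL,
                          provenance = prov,
                          fragment_ids = sprintf("f%d", seq_len(n_fragments)),
                          area_change = 0, refine_warning = FALSE,
                          ring_id = layout$ring_id),
                     class = "ring_composite")
  list(fragments = fragments, layout = layout, truth = truth,
       slide = ph$slide, field = ph$field)
}

#' Generate a phantom heart stack with reference volume
#'
#' A stack of `n_slices` annular phantom slides whose fiber fraction
#' follows `gradient` apex-to-base and whose annulus tapers (radii grow
#' from apex to base, as ventricular rings do). Each slide is displaced
#' by a known integer in-plane shift relative to the reference anatomy;
#' four landmarks on the outer contour encode the shift, so the
#' registration stage has real work to do with an exactly known answer.
#' The reference volume is a blurred grayscale rendering of the unshifted
#' tissue geometry stacked at `dz` spacing.
#'
#' @param n_slices Number of slices (`>= 2`), slice 1 = apex.
#' @param gradient Per-slice fiber fractions, length `n_slices`.
#' @param canvas `(H, W)` canvas per slice.
#' @param mpp_eff Effective microns per pixel.
#' @param seed Base RNG seed.
#' @param dz Slice spacing in mm.
#' @param r_outer_range Outer annulus radius at apex and base (px).
#' @return List: `slides` (per-slice [make_phantom_slide()] outputs),
#'   `landmarks` (per-slice [landmark_pairs()], source = slide, target =
#'   reference), `reference` (a `volume3d`), `truth` (data.frame with
#'   `slice_index`, `fraction`, `tissue_px`, `shift_x`, `shift_y`),
#'   `dz`, `mpp_eff`.
#' @export
make_phantom_heart <- function(n_slices = 8, gradient = NULL,
                               canvas = c(192L, 192L), mpp_eff = 8,
                               seed = 1L, dz = 4,
                               r_outer_range = NULL) {
  n_slices <- as.integer(n_slices)
  if (is.na(n_slices) || n_slices < 2) stop("n_slices must be >= 2")
  if (is.null(gradient)) gradient <- seq(0.01, 0.10, length.out = n_slices)
  if (length(gradient) != n_slices) {
    stop("gradient length must equal n_slices")
  }
  canvas <- as.integer(canvas)
  if (is.null(r_outer_range)) {
    r_outer_range <- c(0.20, 0.42) * min(canvas)
  }
  r_out <- seq(r_outer_range[1], r_outer_range[2], length.out = n_slices)
  slides <- vector("list", n_slices)
  lms <- vector("list", n_slices)
  ref_slices <- vector("list", n_slices)
  truth <- data.frame(slice_index = seq_len(n_slices), fraction = gradient,
                      tissue_px = 0L, shift_x = 0L, shift_y = 0L)
  c0 <- c((canvas[2] - 1) / 2, (canvas[1] - 1) / 2)
  for (z in seq_len(n_slices)) {
    sh <- c(((z * 3L) %% 7L) - 3L, ((z * 5L) %% 7L) - 3L)
    spec_z <- phantom_spec(
      seed = seed + z, canvas = canvas, mpp_eff = mpp_eff,
      geometry = list(type = "annulus", center = c0 + sh,
                      r_outer = r_out[z], r_inner = 0.5 * r_out[z]),
      fiber_fraction = gradient[z])
    slides[[z]] <- make_phantom_slide(spec_z)
    truth$tissue_px[z] <- sum(slides[[z]]$tissue)
    truth$shift_x[z] <- sh[1]; truth$shift_y[z] <- sh[2]
    # landmarks on the outer contour, slide frame -> reference frame
    th <- c(0, 0.5, 1, 1.5) * pi
    tgt <- cbind(c0[1] + r_out[z] * cos(th), c0[2] + r_out[z] * sin(th))
    lms[[z]] <- landmark_pairs(sweep(tgt, 2, sh, "+"), tgt)
    # reference anatomy: unshifted tissue rendered and blurred
    spec_ref <- phantom_spec(
      seed = seed + z, canvas = canvas, mpp_eff = mpp_eff,
      geometry = list(type = "annulus", center = c0,
                      r_outer = r_out[z], r_inner = 0.5 * r_out[z]),
      fiber_fraction = 0)
    ref_slices[[z]] <- gaussian_blur(0.8 * phantom_tissue(spec_ref), 2)
  }
  reference <- build_volume(ref_slices, dz = dz,
                            in_plane_spacing = mpp_eff / 1000,
                            ids = sprintf("reference_%02d", seq_len(n_slices)))
  list(slides = slides, landmarks = lms, reference = reference,
       truth = truth, dz = dz, mpp_eff = mpp_eff)
}
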