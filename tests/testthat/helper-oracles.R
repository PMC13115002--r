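# Independent brute-force oracles and small fixture builders used across
# the suite. The oracles deliberately share no code with the package
# implementations they check.

# O(N^2) Moran's I: literal double sum over all cell pairs.
brute_morans_i <- function(values, valid = NULL, adjacency = "rook") {
  R <- nrow(values); C <- ncol(values)
  if (is.null(valid)) valid <- matrix(TRUE, R, C)
  cells <- which(valid > 0, arr.ind = TRUE)
  n <- nrow(cells)
  x <- values[cells]
  xbar <- mean(x)
  num <- 0; W <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    dr <- abs(cells[i, 1] - cells[j, 1])
    dc <- abs(cells[i, 2] - cells[j, 2])
    adj <- if (adjacency == "rook") dr + dc == 1 else max(dr, dc) == 1
    if (adj) {
      num <- num + (x[i] - xbar) * (x[j] - xbar)
      W <- W + 1
    }
  }
  (n / W) * num / sum((x - xbar)^2)
}

# All-pairs mean nearest-neighbour distance.
brute_mean_nnd <- function(pts) {
  n <- nrow(pts)
  mean(vapply(seq_len(n), function(i) {
    d2 <- (pts[, 1] - pts[i, 1])^2 + (pts[, 2] - pts[i, 2])^2
    d2[i] <- Inf
    sqrt(min(d2))
  }, 0))
}

# Component areas by flood fill (8-connectivity), for filter_components
# checks.
brute_component_areas <- function(mask) {
  m <- mask > 0
  seen <- matrix(FALSE, nrow(m), ncol(m))
  areas <- integer(0)
  for (r0 in seq_len(nrow(m))) for (c0 in seq_len(ncol(m))) {
    if (!m[r0, c0] || seen[r0, c0]) next
    queue <- matrix(c(r0, c0), 1, 2)
    seen[r0, c0] <- TRUE
    area <- 0L
    while (nrow(queue)) {
      p <- queue[1, , drop = FALSE]; queue <- queue[-1, , drop = FALSE]
      area <- area + 1L
      for (dr in -1:1) for (dc in -1:1) {
        r <- p[1] + dr; c <- p[2] + dc
        if (r >= 1 && r <= nrow(m) && c >= 1 && c <= ncol(m) &&
            m[r, c] && !seen[r, c]) {
          seen[r, c] <- TRUE
          queue <- rbind(queue, c(r, c))
        }
      }
    }
    areas <- c(areas, area)
  }
  areas
}

# Uniform RGB slide builder.
flat_slide <- function(H, W, rgb, mpp = 8) {
  px <- array(0, dim = c(H, W, 3))
  for (ch in 1:3) px[, , ch] <- rgb[ch]
  slide_image(px, mpp_base = mpp, downscale = 1L, source_id = "flat")
}

# Deterministic radial jitter that opens clean seam gaps of about
# `mag` pixels between annulus sectors.
radial_jitter <- function(n, mag = 2) {
  th <- (seq_len(n) - 0.5) * 2 * pi / n
  round(mag * cbind(cos(th), sin(th)))
}

# Write a make_phantom_heart() result to disk as pipeline inputs.
write_heart_inputs <- function(ph, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- nrow(ph$truth)
  slides <- landmarks <- character(n)
  for (z in seq_len(n)) {
    slides[z] <- file.path(dir, sprintf("slice_%02d.png", z))
    write_slide_png(ph$slides[[z]]$slide, slides[z])
    lp <- ph$landmarks[[z]]
    landmarks[z] <- file.path(dir, sprintf("slice_%02d_landmarks.csv", z))
    utils::write.csv(
      data.frame(x_src = lp$source[, 1], y_src = lp$source[, 2],
                 x_dst = lp$target[, 1], y_dst = lp$target[, 2]),
      landmarks[z], row.names = FALSE)
  }
  ref <- file.path(dir, "reference.nii.gz")
  write_volume_nifti(ph$reference, ref)
  list(slides = slides, landmarks = landmarks, reference = ref)
}

# Study-condition pipeline config for a phantom heart written by
# write_heart_inputs(): the phantom works at its native (already
# downscaled) resolution, 0.04 mm^2 windows, hotspot threshold at half
# the apical fiber fraction.
heart_config <- function(inp, out_dir) {
  pipeline_config(list(
    slides = inp$slides, landmarks = inp$landmarks,
    reference = inp$reference, output_dir = out_dir,
    downscale = 1, mpp = 8, window_mm2 = 0.04,
    fiber_hsv = list(h = c(0, 80), s = c(12, 125), v = c(31, 162)),
    stats = list(hotspot_threshold = 0.005)))
}

expect_same_matrix <- function(a, b, tol = 0) {
  expect_equal(dim(a), dim(b))
  expect_lte(max(abs(a - b)), tol)
}
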