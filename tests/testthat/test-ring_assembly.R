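test_that("a single fragment with identity placement reproduces itself", {
  sp <- phantom_spec(seed = 3, canvas = c(120, 120), fiber_fraction = 0.1)
  ph <- make_phantom_slide(sp)
  frags <- list(f1 = list(image = ph$slide$pixels, tissue = ph$tissue,
                          fiber = ph$truth$mask))
  lay <- fragment_layout("r1", list(list(fragment_id = "f1",
                                         translation = c(0, 0),
                                         rotation = 0, z_order = 1)),
                         c(120, 120))
  comp <- assemble_ring(frags, lay)
  expect_identical(comp$tissue, ph$tissue)
  expect_identical(comp$fiber, ph$truth$mask)
  expect_identical(comp$image, ph$slide$pixels)
  expect_equal(comp$area_change, 0)
})

test_that("three displaced annulus sectors reassemble exactly", {
  sp <- phantom_spec(seed = 4, canvas = c(200, 200), fiber_fraction = 0.08)
  pr <- make_phantom_ring(sp, n_fragments = 3)
  comp <- assemble_ring(pr$fragments, pr$layout)
  inter <- sum(comp$tissue & pr$truth$tissue)
  union <- sum(comp$tissue | pr$truth$tissue)
  expect_gte(inter / union, 0.999)
  # fiber pixels transported without loss (integer lattice placements)
  expect_equal(sum(comp$fiber), sum(pr$truth$fiber))
  expect_identical(comp$fiber, pr$truth$fiber)
})

test_that("layouts referencing absent fragments or oversized placements fail", {
  sp <- phantom_spec(seed = 5, canvas = c(100, 100), fiber_fraction = 0.05)
  pr <- make_phantom_ring(sp, n_fragments = 2)
  bad <- pr$layout
  bad$fragments[[1]]$fragment_id <- "ghost"
  expect_error(assemble_ring(pr$fragments, bad), "absent fragment")
  far <- pr$layout
  far$fragments[[2]]$translation <- c(90, 0)
  expect_error(assemble_ring(pr$fragments, far), "exceeds canvas")
})

test_that("assembly is equivariant under a common rigid shift of the layout", {
  sp <- phantom_spec(seed = 6, canvas = c(140, 140),
                     geometry = list(type = "annulus", r_outer = 40),
                     fiber_fraction = 0.05)
  pr <- make_phantom_ring(sp, n_fragments = 2)
  comp <- assemble_ring(pr$fragments, pr$layout)
  shifted <- pr$layout
  for (i in seq_along(shifted$fragments)) {
    shifted$fragments[[i]]$translation <-
      shifted$fragments[[i]]$translation + c(6, -4)
  }
  comp2 <- assemble_ring(pr$fragments, shifted)
  H <- 140; W <- 140
  expect_identical(comp2$tissue[(1:(H - 4)) + 0, 7:W],
                   comp$tissue[5:H, 1:(W - 6)])
})

test_that("density surfaces transported with fragments conserve counts", {
  sp <- phantom_spec(seed = 8, canvas = c(180, 180), fiber_fraction = 0.1)
  pr <- make_phantom_ring(sp, n_fragments = 3)
  frags <- lapply(pr$fragments, function(f) {
    f$density <- compute_density_map(fiber_mask(f$fiber, 8),
                                     window_mm2 = 0.01, tissue = f$tissue)
    f
  })
  comp <- assemble_ring(frags, pr$layout)
  total_frag <- sum(vapply(frags, function(f) sum(f$density$counts), 0))
  # per-pixel transported density integrates back to the fragment counts
  expect_equal(sum(comp$density_px), total_frag, tolerance = 0.005 * total_frag)
})

test_that("an already-seamless composite is returned unchanged", {
  sp <- phantom_spec(seed = 9, canvas = c(160, 160), fiber_fraction = 0.05)
  pr <- make_phantom_ring(sp, n_fragments = 3)
  comp <- assemble_ring(pr$fragments, pr$layout)
  ref <- refine_boundaries(comp)
  expect_equal(ref$area_change, 0)
  expect_false(ref$refine_warning)
  expect_identical(ref$tissue, comp$tissue)
})

test_that("seam refinement closes a 2-px gap within the 1% area bound", {
  sp <- phantom_spec(seed = 10, canvas = c(300, 300),
                     geometry = list(type = "annulus", r_outer = 120),
                     fiber_fraction = 0.05)
  # the two half-annuli pull 1 px apart on each side of the horizontal
  # cut: a clean 2-px seam gap, well under 1% of the section area
  pr <- make_phantom_ring(sp, n_fragments = 2,
                          seam_jitter = rbind(c(0, 1), c(0, -1)))
  comp <- assemble_ring(pr$fragments, pr$layout)
  g0 <- seam_gap_pixels(comp, 2)
  expect_gt(g0, 0)
  ref <- refine_boundaries(comp)
  expect_false(ref$refine_warning)
  expect_lt(seam_gap_pixels(ref, 2), g0)
  expect_lte(ref$area_change, 0.01)
})

test_that("refinement aborts with a warning when the bound would be broken", {
  sp <- phantom_spec(seed = 11, canvas = c(200, 200),
                     geometry = list(type = "annulus", r_outer = 70),
                     fiber_fraction = 0.05)
  pr <- make_phantom_ring(sp, n_fragments = 3,
                          seam_jitter = radial_jitter(3, 4))
  comp <- assemble_ring(pr$fragments, pr$layout)
  expect_warning(ref <- refine_boundaries(comp, max_area_change = 0.001),
                 "aborted")
  expect_true(ref$refine_warning)
  expect_identical(ref$tissue, comp$tissue)   # unchanged composite
  expect_equal(ref$area_change, 0)
})

test_that("returned composites always respect the configured area bound", {
  for (seed in c(12, 13)) {
    sp <- phantom_spec(seed = seed, canvas = c(220, 220), fiber_fraction = 0.05)
    pr <- make_phantom_ring(sp, n_fragments = 3, seam_jitter = 2)
    comp <- assemble_ring(pr$fragments, pr$layout)
    ref <- suppressWarnings(refine_boundaries(comp))
    expect_lte(ref$area_change, 0.01)
  }
})

test_that("layout JSON round trips", {
  lay <- fragment_layout("ring7",
                         list(list(fragment_id = "a", translation = c(3, -2),
                                   rotation = 90, flip = TRUE, z_order = 2),
                              list(fragment_id = "b", z_order = 1)),
                         c(64, 80))
  f <- withr::local_tempfile(fileext = ".json")
  write_layout_json(lay, f)
  re <- read_layout_json(f)
  expect_equal(re$ring_id, "ring7")
  expect_equal(re$canvas_size, c(64L, 80L))
  expect_equal(re$fragments[[1]]$translation, c(3, -2))
  expect_true(re$fragments[[1]]$flip)
  expect_error(fragment_layout("x", list(list(fragment_id = "a"),
                                         list(fragment_id = "a")), c(4, 4)),
               "unique")
})
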