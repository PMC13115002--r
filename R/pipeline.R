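#' Assemble a validated pipeline configuration
#'
#' Fills defaults and validates a (possibly nested) configuration list
#' for [run_pipeline()]. Every published working parameter — downscale
#' 16, 1 mm^2 analysis window, overlay alpha 0.3, the default HSV range —
#' is a default here, never a constant.
#'
#' @param config Named list, typically from [read_config()]. Recognised
#'   fields: `slides` (character vector of slide image paths, ordered
#'   apex-to-base), `rings` (optional list of
#'   `list(layout = <json path>, fragments = <named character vector of
#'   image paths>)`), `landmarks` (optional character vector of landmark
#'   CSV paths parallel to the slices), `reference` (optional NIfTI
#'   path), `output_dir`, `downscale`, `mpp`, `window_mm2`, `dz`,
#'   `tissue_mask` (see [mask_params()]), `fiber_hsv` (`h`/`s`/`v`
#'   bounds), `heatmap` (`alpha`, `n_bins`, `lo`, `hi`, `draw_grid`,
#'   `draw_legend`), `registration` (`tps`, `lambda`), `stats`
#'   (`hotspot_threshold`, `adjacency`, `regions`), `seed`.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  cfg_err <- function(field, msg) {
    stop(structure(class = c("config_error", "error", "condition"),
                   list(message = sprintf("config field `%s`: %s", field, msg),
                        call = NULL)))
  }
  num1 <- function(field, x, lo = -Inf, hi = Inf) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < lo || x > hi) {
      cfg_err(field, sprintf("must be a number in [%g, %g]", lo, hi))
    }
    x
  }
  out <- config
  out$downscale <- num1("downscale", config$downscale %||% 16, 1)
  out$window_mm2 <- num1("window_mm2", config$window_mm2 %||% 1, 1e-9)
  out$dz <- num1("dz", config$dz %||% 4, 1e-9)
  out$seed <- num1("seed", config$seed %||% 1)
  out$output_dir <- config$output_dir %||% "innervmap_out"
  if (is.null(config$fiber_hsv)) {
    message("config: `fiber_hsv` not given; using the default UCHL-1 DAB range")
    out$fiber_hsv <- hsv_range()
  } else {
    fh <- config$fiber_hsv
    out$fiber_hsv <- tryCatch(
      hsv_range(unlist(fh$h), unlist(fh$s), unlist(fh$v)),
      error = function(e) cfg_err("fiber_hsv", conditionMessage(e)))
  }
  tm <- config$tissue_mask %||% list()
  out$tissue_mask <- tryCatch(
    mask_params(blur_sigma = tm$blur_sigma %||% 2,
                brightness_max = tm$brightness_max %||% 220,
                gradient_min = tm$gradient_min %||% 10,
                min_area_px = tm$min_area_px %||% 500,
                dilate_radius = tm$dilate_radius %||% 3,
                combine = tm$combine %||% "or"),
    error = function(e) cfg_err("tissue_mask", conditionMessage(e)))
  hm <- config$heatmap %||% list()
  edges <- log_bin_edges(hm$n_bins %||% 8, hm$lo %||% 1e-4, hm$hi %||% 1)
  out$heatmap <- heatmap_style(alpha = num1("heatmap.alpha",
                                            hm$alpha %||% 0.3, 0, 1),
                               bin_edges = edges,
                               draw_grid = hm$draw_grid %||% TRUE,
                               draw_legend = hm$draw_legend %||% FALSE)
  st <- config$stats %||% list()
  out$stats <- list(
    hotspot_threshold = num1("stats.hotspot_threshold",
                             st$hotspot_threshold %||% edges[length(edges) - 1L],
                             0, 1),
    adjacency = match.arg(st$adjacency %||% "queen", c("queen", "rook")),
    regions = st$regions)
  rg <- config$registration %||% list()
  out$registration <- list(tps = isTRUE(rg$tps),
                           lambda = num1("registration.lambda",
                                         rg$lambda %||% 0.001, 0))
  structure(out, class = "pipeline_config")
}

#' Read a pipeline configuration file
#'
#' YAML or JSON, validated through [pipeline_config()].
#'
#' @param path Config file path.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (tolower(tools::file_ext(path)) == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  pipeline_config(raw)
}

missing_input <- function(msg) {
  stop(structure(class = c("missing_input", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Run the slide-to-statistics pipeline
#'
#' Executes the requested stages in order
#' `slide -> ring -> register -> fuse -> stats`, writing per-stage
#' artifacts under `config$output_dir` and a `manifest.json` listing
#' every output with its MD5 checksum. The pipeline itself is
#' deterministic: identical config and inputs reproduce byte-identical
#' CSV/JSON outputs.
#'
#' Stage semantics: `slide` loads each slide, masks tissue, classifies
#' fibers, computes the density map and writes the heatmap overlay;
#' `ring` assembles fragment layouts into ring composites with bounded
#' seam refinement (when `config$rings` is given, ring composites replace
#' the plain slides downstream); `register` fits landmark transforms
#' (rigid, optionally + TPS) per slice and resamples the density surface
#' into the reference frame; `fuse` stacks registered slices into a 3D
#' volume (interpolating missing slices) and writes NIfTI; `stats`
#' computes the apex-to-base innervation profile.
#'
#' @param config A [pipeline_config()] (or plain list passed through it).
#' @param stages Character subset of
#'   `c("slide", "ring", "register", "fuse", "stats")`.
#' @return Invisibly, the manifest: list with `outputs` (per-file md5)
#'   and `state` (in-memory per-slice results).
#' @export
run_pipeline <- function(config,
                         stages = c("slide", "ring", "register", "fuse",
                                    "stats")) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  add_out <- function(p) outputs <<- c(outputs, p)
  state <- list(slices = NULL, registered = NULL, volume = NULL)

  if ("slide" %in% stages) {
    if (is.null(config$slides) || !length(config$slides)) {
      missing_input("stage `slide`: no `slides` configured")
    }
    state$slices <- lapply(seq_along(config$slides), function(i) {
      p <- config$slides[[i]]
      if (!file.exists(p)) missing_input(paste("slide not found:", p))
      sl <- load_slide(p, downscale = config$downscale, mpp = config$mpp)
      tis <- compute_tissue_mask(sl, config$tissue_mask)
      fib <- classify_fibers(sl, tis, config$fiber_hsv)
      dm <- compute_density_map(fib, config$window_mm2, tissue = tis)
      base <- sprintf("slice_%02d", i)
      hm <- render_heatmap(sl, dm, config$heatmap)
      png::writePNG(hm / 255, file.path(config$output_dir,
                                        paste0(base, "_heatmap.png")))
      add_out(file.path(config$output_dir, paste0(base, "_heatmap.png")))
      png::writePNG(fib$mask + 0, file.path(config$output_dir,
                                            paste0(base, "_fibers.png")))
      add_out(file.path(config$output_dir, paste0(base, "_fibers.png")))
      write_density_csv(dm, file.path(config$output_dir,
                                      paste0(base, "_density.csv")))
      add_out(file.path(config$output_dir, paste0(base, "_density.csv")))
      list(slide = sl, tissue = tis, fiber = fib, dm = dm,
           density_px = expand_density_px(dm, dim(fib$mask)))
    })
  }

  if ("ring" %in% stages && !is.null(config$rings)) {
    if (is.null(state$slices) && is.null(config$rings)) {
      missing_input("stage `ring`: nothing to assemble")
    }
    ring_slices <- lapply(seq_along(config$rings), function(ri) {
      rg <- config$rings[[ri]]
      layout <- read_layout_json(rg$layout)
      frags <- lapply(rg$fragments, function(p) {
        if (!file.exists(p)) missing_input(paste("fragment not found:", p))
        sl <- load_slide(p, downscale = config$downscale, mpp = config$mpp)
        tis <- compute_tissue_mask(sl, config$tissue_mask)
        fib <- classify_fibers(sl, tis, config$fiber_hsv)
        dm <- compute_density_map(fib, config$window_mm2, tissue = tis)
        list(image = sl$pixels, tissue = tis$mask, fiber = fib$mask,
             density = dm, mpp_eff = effective_mpp(sl))
      })
      names(frags) <- names(rg$fragments)
      comp <- assemble_ring(frags, layout)
      comp <- refine_boundaries(comp, max_area_change = rg$max_area_change %||% 0.01)
      base <- sprintf("ring_%02d", ri)
      png::writePNG(comp$image / 255,
                    file.path(config$output_dir, paste0(base, "_composite.png")))
      add_out(file.path(config$output_dir, paste0(base, "_composite.png")))
      mpp_eff <- frags[[1]]$mpp_eff
      fib <- fiber_mask(comp$fiber, mpp_eff, comp$ring_id)
      dm <- compute_density_map(fib, config$window_mm2, tissue = comp$tissue)
      write_density_csv(dm, file.path(config$output_dir,
                                      paste0(base, "_density.csv")))
      add_out(file.path(config$output_dir, paste0(base, "_density.csv")))
      list(slide = NULL, tissue = comp$tissue, fiber = fib, dm = dm,
           density_px = expand_density_px(dm, dim(comp$tissue)),
           composite = comp)
    })
    state$slices <- ring_slices
  }

  if ("register" %in% stages) {
    if (is.null(state$slices)) {
      missing_input("stage `register`: no slice/ring outputs available")
    }
    ref_shape <- NULL
    if (!is.null(config$reference) && file.exists(config$reference)) {
      refvol <- read_volume_nifti(config$reference)
      ref_shape <- dim(refvol$voxels)[2:3]
      state$reference <- refvol
    }
    state$registered <- lapply(seq_along(state$slices), function(i) {
      sl <- state$slices[[i]]
      shape <- ref_shape %||% dim(sl$density_px)
      tr <- NULL
      if (!is.null(config$landmarks) && length(config$landmarks) >= i &&
          nzchar(config$landmarks[[i]] %||% "")) {
        lp <- read_landmarks(config$landmarks[[i]])
        tr <- fit_rigid(lp)
        if (isTRUE(config$registration$tps) && nrow(lp$source) >= 3) {
          mapped <- transform_points(tr, lp$source)
          tr_tps <- fit_tps(landmark_pairs(mapped, lp$target),
                            lambda = config$registration$lambda)
          reg <- apply_transform(
            apply_transform(sl$density_px, tr, shape, "nearest"),
            tr_tps, shape, "nearest")
          tr <- list(rigid = tr, tps = tr_tps)
        } else {
          reg <- apply_transform(sl$density_px, tr, shape, "nearest")
        }
        write_transform(if (is.list(tr) && !inherits(tr, "transform2d"))
                          tr$rigid else tr,
                        file.path(config$output_dir,
                                  sprintf("slice_%02d_transform.json", i)))
        add_out(file.path(config$output_dir,
                          sprintf("slice_%02d_transform.json", i)))
      } else {
        reg <- sl$density_px
        if (!all(dim(reg) == shape)) {
          pad <- matrix(0, shape[1], shape[2])
          rr <- seq_len(min(shape[1], nrow(reg)))
          cc <- seq_len(min(shape[2], ncol(reg)))
          pad[rr, cc] <- reg[rr, cc]
          reg <- pad
        }
      }
      reg
    })
  }

  if ("fuse" %in% stages) {
    if (is.null(state$registered)) {
      missing_input("stage `fuse`: no registered slices available")
    }
    mpp_eff <- NULL
    for (sl in state$slices) {
      if (!is.null(sl$fiber)) { mpp_eff <- sl$fiber$mpp_eff; break }
    }
    vol <- build_volume(state$registered, dz = config$dz,
                        in_plane_spacing = (mpp_eff %||% 1000) / 1000)
    vol <- interpolate_missing(vol)
    state$volume <- vol
    vp <- file.path(config$output_dir, "innervation_volume.nii.gz")
    write_volume_nifti(vol, vp)
    add_out(vp)
    add_out(file.path(config$output_dir, "innervation_volume.provenance.json"))
  }

  if ("stats" %in% stages) {
    if (is.null(state$slices)) {
      missing_input("stage `stats`: no density outputs available")
    }
    pt <- innervation_profile(
      lapply(seq_along(state$slices), function(i)
        list(slice_index = i, dm = state$slices[[i]]$dm,
             fiber = state$slices[[i]]$fiber)),
      regions = config$stats$regions,
      threshold = config$stats$hotspot_threshold,
      edges = config$heatmap$bin_edges,
      adjacency = config$stats$adjacency)
    state$profile <- pt
    pp <- file.path(config$output_dir, "profile.csv")
    write_profile_csv(pt, pp)
    add_out(pp)
    if (!is.null(pt$summaries)) {
      add_out(file.path(config$output_dir, "profile.summary.json"))
    }
    plot_profile(pt, file.path(config$output_dir, "profile.png"))
    add_out(file.path(config$output_dir, "profile.png"))
  }

  manifest <- list(
    stages = stages,
    outputs = lapply(outputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest,
                       file.path(config$output_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(list(manifest = manifest, state = state))
}
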