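#' Configure a full location-distribution pipeline run
#'
#' Bundles paths, method and resampling parameters for [run_pipeline()].
#' Defaults reproduce the standard operating point of the method:
#' sampling size `S = 70`, threshold level `T = 5`, with the sweep (when
#' enabled) spanning the twelve sampling sizes of [sampling_sizes()] and
#' threshold levels 1-8.
#'
#' @param out_dir Output directory for all artifacts.
#' @param synthetic Generate a synthetic orchard scene instead of
#'   reading inputs from disk.
#' @param image_path RGB image to segment (ignored when `synthetic`).
#' @param mask_path Optional precomputed segmentation mask; skips the
#'   classifier.
#' @param truth_path Canopy-range truth mask (required for a sweep on
#'   real inputs; the generated truth is used when `synthetic`).
#' @param plants_path Optional externally detected plant table
#'   (`plant_id,row_px,col_px`); when absent, plants are located from
#'   core-density blobs.
#' @param method Segmentation baseline: `"color"`, `"forest"` or
#'   `"margin"` (the trainable kinds need `train_labels_path`).
#' @param train_labels_path 0/1 mask of training labels for the
#'   trainable classifiers.
#' @param S,T Operating sampling size and threshold level.
#' @param S_list,T_levels Sweep axes.
#' @param sweep Run the (S, T) IoU sweep and select best parameters.
#' @param fp_rate,fn_rate,clump_radius_px Classifier-noise emulation
#'   applied to the segmented mask (synthetic studies; default off).
#' @param seed Master seed for every random stage.
#' @param scene A [scene_config()] for synthetic runs (its
#'   `random_seed` is overridden by `seed`).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, synthetic = FALSE, image_path = NULL,
                            mask_path = NULL, truth_path = NULL,
                            plants_path = NULL,
                            method = c("color", "forest", "margin"),
                            train_labels_path = NULL,
                            S = 70L, T = 5L,
                            S_list = sampling_sizes(), T_levels = 1:8,
                            sweep = FALSE, fp_rate = 0, fn_rate = 0,
                            clump_radius_px = 0L, seed = 1L,
                            scene = scene_config()) {
  method <- match.arg(method)
  cfg <- list(out_dir = out_dir, synthetic = isTRUE(synthetic),
              image_path = image_path, mask_path = mask_path,
              truth_path = truth_path, plants_path = plants_path,
              method = method, train_labels_path = train_labels_path,
              S = assert_count(S, "S"), T = assert_count(T, "T"),
              S_list = as.integer(S_list), T_levels = as.integer(T_levels),
              sweep = isTRUE(sweep), fp_rate = fp_rate, fn_rate = fn_rate,
              clump_radius_px = as.integer(clump_radius_px),
              seed = as.integer(seed), scene = scene)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the location-distribution pipeline
#'
#' Chains the stages segment -> resample -> binarize/gradient ->
#' sweep (optional) -> fuse, writing every artifact under
#' `config$out_dir` and a `manifest.json` recording each output with its
#' producing stage and MD5 checksum plus the resolved configuration.
#' Identical configuration and seed give bit-identical artifacts. A
#' stage failure aborts with the stage name and cause; outputs already
#' written are retained with a `.partial` suffix.
#'
#' @param config A [pipeline_config()].
#' @return The manifest, invisibly (list with `config`, `artifacts`,
#'   and, when the sweep ran, `best_parameters`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  state <- new.env(parent = emptyenv())
  state$artifacts <- data.frame(path = character(), stage = character(),
                                stringsAsFactors = FALSE)
  emit <- function(path, stage) {
    state$artifacts <- rbind(state$artifacts,
                             data.frame(path = path, stage = stage,
                                        stringsAsFactors = FALSE))
    path
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      for (p in state$artifacts$path)
        if (file.exists(p)) file.rename(p, paste0(p, ".partial"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  out <- function(f) file.path(config$out_dir, f)

  scene <- NULL
  if (config$synthetic) {
    run_stage("synth", {
      sc <- config$scene
      sc$random_seed <- config$seed
      scene <- generate_scene(sc)
      paths <- write_scene(scene, config$out_dir)
      for (p in paths) emit(p, "synth")
    })
  }

  mask <- NULL; image <- NULL
  run_stage("segment", {
    if (config$synthetic) {
      image <- scene$rgb
      mask <- segment(image, pixel_classifier())
    } else if (!is.null(config$mask_path)) {
      mask <- read_mask(config$mask_path)
    } else {
      if (is.null(config$image_path))
        pldm_stop("no image_path or mask_path given",
                  class = "pldm_validation_error")
      image <- read_image(config$image_path)
      cl <- if (config$method == "color") pixel_classifier() else {
        if (is.null(config$train_labels_path))
          pldm_stop("method '", config$method,
                    "' needs train_labels_path", class = "pldm_validation_error")
        labels <- read_mask(config$train_labels_path)
        kind <- c(forest = "forest_like", margin = "margin_like")[config$method]
        train_classifier(extract_features(image), as.vector(labels), kind)
      }
      mask <- segment(image, cl)
    }
    if (config$fp_rate > 0 || config$fn_rate > 0)
      mask <- corrupt_mask(mask, config$fp_rate, config$fn_rate,
                            config$clump_radius_px,
                            seed = derive_seed(config$seed, 999L))
    emit(write_mask(mask, out("segmentation_mask.png")), "segment")
  })

  dist <- NULL; grad <- NULL; bin <- NULL
  run_stage("resample", {
    dist <- tile_ratios(mask, config$S)
    grad <- gradient_map(dist)
    bin <- binarize_distribution(dist, config$T)
    emit(write_ratio_grid(dist, out("ratio_grid.csv")), "resample")
    emit(write_image(gradient_rgb(grad), out("gradient_map.png")), "resample")
    emit(write_mask(reconstruct_pixel_map(bin),
                    out("binary_distribution.png")), "resample")
  })

  best <- NULL
  if (config$sweep) run_stage("sweep", {
    truth <- if (config$synthetic) scene$canopy_mask else {
      if (is.null(config$truth_path))
        pldm_stop("sweep needs truth_path", class = "pldm_validation_error")
      read_mask(config$truth_path)
    }
    sw <- sweep_iou(stats::setNames(list(list(image1 = mask)), config$method),
                    list(image1 = truth), config$S_list, config$T_levels)
    write.csv(as.data.frame(sw), out("sweep.csv"), row.names = FALSE)
    emit(out("sweep.csv"), "sweep")
    surf <- iou_surface(sw, config$method)
    write.csv(cbind(S = rownames(surf), as.data.frame(surf)),
              out(paste0("surface_", config$method, ".csv")),
              row.names = FALSE)
    emit(out(paste0("surface_", config$method, ".csv")), "sweep")
    curves <- per_image_curves(sw, config$method, config$T)
    write.csv(curves,
              out(paste0("curves_", config$method, "_T", config$T, ".csv")),
              row.names = FALSE)
    emit(out(paste0("curves_", config$method, "_T", config$T, ".csv")), "sweep")
    best <- best_parameters(sw, config$method)
  })

  run_stage("fuse", {
    plants <- if (!is.null(config$plants_path)) read_plants(config$plants_path)
              else locate_plants_from_cores(grad)
    base <- if (!is.null(image)) image else mask
    emit(write_image(fuse(base, grad, plants, style = "gradient"),
                     out("location_distribution.png")), "fuse")
    emit(write_image(fuse(base, bin, plants, style = "binary"),
                     out("binary_location_distribution.png")), "fuse")
    if (is.null(config$plants_path))
      emit(write_plants(plants, out("located_plants.csv")), "fuse")
  })

  manifest <- list(
    config = lapply(unclass(config)[setdiff(names(config), "scene")],
                    function(x) x),
    scene_config = if (config$synthetic) unclass(config$scene) else NULL,
    best_parameters = best,
    artifacts = data.frame(
      path = basename(state$artifacts$path),
      stage = state$artifacts$stage,
      md5 = unname(tools::md5sum(state$artifacts$path)),
      stringsAsFactors = FALSE)
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
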