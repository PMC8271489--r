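#' Configure a synthetic trellised-orchard scene
#'
#' Describes a top-down scene of a trellised orchard (kiwifruit-style):
#' plants on a regular grid (3 m along the row, 4 m between rows by
#' default, at 0.02 m/px the ultra-high-resolution ground sampling
#' distance of low-altitude UAV flights), thin divergent vine skeletons
#' radiating from each plant, and a grassy textured background. Ground
#' truth for the canopy *range* is defined constructively as the
#' morphological dilation of the vine skeletons by `canopy_dilation_px`.
#'
#' Defaults for the vine architecture (25 canes per plant, walks up to
#' 100 px with branch probability 0.06, widths 1-3 px, canopy dilation
#' 15 px = 0.3 m) emulate a mature trellised planting: canopies of
#' adjacent plants merge into near-continuous strips along the row, and
#' the vine-pixel density inside the canopy range sits near 0.35 - well
#' above the lowest ratio threshold (0.11), so canopy tiles separate
#' cleanly from scattered classifier noise at a few percent.
#'
#' @param image_height_px,image_width_px Scene size in pixels.
#' @param resolution_m_per_px Ground sampling distance (m per pixel).
#' @param plant_spacing_m Spacing between plants along a row (maps to
#'   column pitch).
#' @param row_spacing_m Spacing between rows (maps to row pitch).
#' @param vines_per_plant Number of vine skeletons per plant (0 allowed:
#'   a bare scene).
#' @param vine_max_length_px Maximum walk length of a vine skeleton.
#' @param canopy_dilation_px Dilation radius defining the canopy range
#'   around the vine set.
#' @param branch_prob Per-step probability that a walk spawns a branch.
#' @param random_seed Master seed; per-plant sub-streams are derived from
#'   it so edits to one part of the configuration leave other plants'
#'   geometry unchanged.
#' @return A `scene_config` list.
#' @export
scene_config <- function(image_height_px = 600L, image_width_px = 800L,
                         resolution_m_per_px = 0.02,
                         plant_spacing_m = 3.0, row_spacing_m = 4.0,
                         vines_per_plant = 25L, vine_max_length_px = 100L,
                         canopy_dilation_px = 15L, branch_prob = 0.06,
                         random_seed = 1L) {
  h <- assert_count(image_height_px, "image_height_px")
  w <- assert_count(image_width_px, "image_width_px")
  if (!is.numeric(resolution_m_per_px) || resolution_m_per_px <= 0)
    pldm_stop("resolution_m_per_px must be > 0", class = "pldm_validation_error")
  if (plant_spacing_m <= 0 || row_spacing_m <= 0)
    pldm_stop("spacings must be > 0", class = "pldm_validation_error")
  col_pitch <- plant_spacing_m / resolution_m_per_px
  row_pitch <- row_spacing_m / resolution_m_per_px
  if (col_pitch < 1 || row_pitch < 1)
    pldm_stop("plant spacing in pixels must be >= 1",
              class = "pldm_validation_error")
  cfg <- list(
    image_height_px = h, image_width_px = w,
    resolution_m_per_px = resolution_m_per_px,
    plant_spacing_m = plant_spacing_m, row_spacing_m = row_spacing_m,
    vines_per_plant = assert_count(vines_per_plant, "vines_per_plant", min = 0L),
    vine_max_length_px = assert_count(vine_max_length_px, "vine_max_length_px"),
    canopy_dilation_px = assert_count(canopy_dilation_px, "canopy_dilation_px",
                                      min = 0L),
    branch_prob = branch_prob,
    random_seed = as.integer(random_seed)
  )
  class(cfg) <- "scene_config"
  cfg
}

# 0-based grid centers along one axis; errors naming the offending dimension
.grid_centers <- function(extent_px, pitch_px, dim_name) {
  first <- floor(pitch_px / 2)
  if (first > extent_px - 1)
    pldm_stop("plant grid does not fit: ", dim_name, " = ", extent_px,
              " px is smaller than half the pitch (", pitch_px, " px)",
              class = "pldm_config_error")
  seq(first, extent_px - 1, by = pitch_px)
}

# paint one vine skeleton (biased random walk with branching) into `mask`,
# returning the updated mask; walk stops at image bounds
.walk_vine <- function(mask, r0, c0, max_len, branch_prob) {
  h <- nrow(mask); w <- ncol(mask)
  width <- sample(1:3, 1L)
  off <- seq.int(-((width - 1L) %/% 2L), (width %/% 2L))
  len <- sample(seq.int(max(2L, ceiling(max_len / 2)), max_len), 1L)
  # each stack entry: (row, col, heading, steps remaining)
  stack <- list(c(r0, c0, runif(1, 0, 2 * pi), len))
  nseg <- 0L
  while (length(stack) && nseg < 25L) {
    seg <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    nseg <- nseg + 1L
    r <- seg[1]; cc <- seg[2]; ang <- seg[3]; steps <- seg[4]
    while (steps > 0) {
      ang <- ang + rnorm(1, 0, 0.3)
      r <- r + sin(ang); cc <- cc + cos(ang)
      ri <- round(r); ci <- round(cc)
      if (ri < 1 || ri > h || ci < 1 || ci > w) break
      rows <- pmin(pmax(ri + off, 1L), h)
      cols <- pmin(pmax(ci + off, 1L), w)
      mask[rows, cols] <- 1L
      if (runif(1) < branch_prob)
        stack[[length(stack) + 1L]] <-
          c(r, cc, ang + runif(1, -1.2, 1.2), floor(steps * 0.6))
      steps <- steps - 1
    }
  }
  mask
}

#' Generate a synthetic orchard scene with ground truth
#'
#' Deterministic for a fixed `random_seed`. Plants are placed on the
#' spacing grid; each plant grows `vines_per_plant` branching
#' random-walk skeletons (1-3 px wide) radiating from its center; the
#' background is low-amplitude grassy texture and vine pixels carry a
#' distinct bright-green color. The true canopy range is the dilation of
#' the vine set by `canopy_dilation_px`, so every vine pixel lies inside
#' the canopy mask.
#'
#' @param config A [scene_config()].
#' @return A `synthetic_scene`: list with `rgb` (`H x W x 3`, values in
#'   `[0, 1]`), `vine_mask` and `canopy_mask` (0/1 matrices), `plants`
#'   (data frame `plant_id,row_px,col_px`, 0-based centers) and `config`.
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  h <- config$image_height_px; w <- config$image_width_px
  row_pitch <- config$row_spacing_m / config$resolution_m_per_px
  col_pitch <- config$plant_spacing_m / config$resolution_m_per_px
  centers_r <- .grid_centers(h, row_pitch, "image_height_px")
  centers_c <- .grid_centers(w, col_pitch, "image_width_px")
  grid <- expand.grid(col_px = centers_c, row_px = centers_r)[, c("row_px", "col_px")]
  plants <- data.frame(plant_id = seq_len(nrow(grid)),
                       row_px = grid$row_px, col_px = grid$col_px)

  vine <- matrix(0L, h, w)
  for (p in seq_len(nrow(plants))) {
    if (config$vines_per_plant == 0L) break
    vine <- with_seed(derive_seed(config$random_seed, p), {
      m <- vine
      for (v in seq_len(config$vines_per_plant))
        m <- .walk_vine(m, plants$row_px[p] + 1L, plants$col_px[p] + 1L,
                        config$vine_max_length_px, config$branch_prob)
      m
    })
  }
  canopy <- dilate_disc(vine, config$canopy_dilation_px)

  rgb <- with_seed(derive_seed(config$random_seed, 0L), {
    base <- c(0.38, 0.42, 0.25)  # dry-grass inter-row ground
    img <- array(0, c(h, w, 3L))
    for (k in 1:3)
      img[, , k] <- pmin(pmax(base[k] + rnorm(h * w, 0, 0.04), 0), 1)
    img
  })
  vine_col <- c(0.10, 0.85, 0.15)  # distinct canopy green
  for (k in 1:3) {
    ch <- rgb[, , k]
    ch[vine == 1L] <- vine_col[k]
    rgb[, , k] <- ch
  }

  structure(list(rgb = rgb, vine_mask = vine, canopy_mask = canopy,
                 plants = plants, config = config),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> %d x %d px, %d plants, %d vine px, %d canopy px\n",
              nrow(x$vine_mask), ncol(x$vine_mask), nrow(x$plants),
              sum(x$vine_mask), sum(x$canopy_mask)))
  invisible(x)
}

#' Corrupt a mask with classifier-style salt-and-pepper noise
#'
#' Emulates the scattered errors a per-pixel classifier leaves on thin
#' divergent vines: each background pixel flips to vine with probability
#' `fp_rate` (optionally grown into clumps of radius `clump_radius_px`),
#' and each vine pixel drops to background with probability `fn_rate`.
#' Deterministic for a fixed seed; with both rates 0 the output is the
#' input, with both rates 1 it is the exact complement.
#'
#' @param mask Integer 0/1 matrix.
#' @param fp_rate,fn_rate Flip probabilities in `[0, 1]`.
#' @param clump_radius_px Dilation radius applied to the false-positive
#'   seed pixels (0 = isolated single-pixel noise).
#' @param seed Integer seed.
#' @return Corrupted 0/1 matrix.
#' @export
corrupt_mask <- function(mask, fp_rate, fn_rate, clump_radius_px = 0L,
                         seed = 1L) {
  assert_mask(mask)
  if (!is.numeric(fp_rate) || !is.numeric(fn_rate) ||
      fp_rate < 0 || fp_rate > 1 || fn_rate < 0 || fn_rate > 1)
    pldm_stop("fp_rate and fn_rate must lie in [0, 1]",
              class = "pldm_validation_error")
  clump_radius_px <- assert_count(clump_radius_px, "clump_radius_px", min = 0L)
  with_seed(seed, {
    u <- matrix(runif(length(mask)), nrow(mask), ncol(mask))
    fp_seed <- (mask == 0L) & (u < fp_rate)
    fn_flip <- (mask == 1L) & (u < fn_rate)
    fp <- if (clump_radius_px > 0L)
      dilate_disc(fp_seed + 0L, clump_radius_px) == 1L else fp_seed
    out <- mask
    out[fn_flip] <- 0L
    out[fp] <- 1L
    out
  })
}

#' Write a synthetic scene to disk
#'
#' Emits `rgb.png`, `vine_mask.png` and `canopy_mask.png` (0/255),
#' `plants.csv` (`plant_id,row_px,col_px`, 0-based) and
#' `scene_config.yaml` into `dir`.
#'
#' @param scene A `synthetic_scene`.
#' @param dir Output directory (created if absent).
#' @return Character vector of the written paths, invisibly.
#' @export
write_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "synthetic_scene"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(rgb = file.path(dir, "rgb.png"),
             vine = file.path(dir, "vine_mask.png"),
             canopy = file.path(dir, "canopy_mask.png"),
             plants = file.path(dir, "plants.csv"),
             config = file.path(dir, "scene_config.yaml"))
  write_image(scene$rgb, paths["rgb"])
  write_mask(scene$vine_mask, paths["vine"])
  write_mask(scene$canopy_mask, paths["canopy"])
  write_plants(scene$plants, paths["plants"])
  yaml::write_yaml(unclass(scene$config), paths["config"])
  invisible(paths)
}
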