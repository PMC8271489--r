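#' Locate plants from core-density blobs of a gradient map
#'
#' Desk-scale stand-in for a trained trunk detector: connected
#' components of core-class tiles are reduced to their pixel-space
#' centroids, and centroids closer than `min_separation_px` are merged
#' (size-weighted, closest pair first) so one plant is not reported
#' twice. Deterministic; invariant to how the non-core classes are
#' labeled.
#'
#' @param grad A `gradient_map`.
#' @param min_separation_px Minimum center-to-center distance between
#'   reported plants.
#' @return Data frame `plant_id,row_px,col_px` (0-based pixel centers),
#'   ordered by row then column; zero rows when no core tile exists.
#' @export
locate_plants_from_cores <- function(grad, min_separation_px = 50L) {
  stopifnot(inherits(grad, "gradient_map"))
  min_separation_px <- assert_count(min_separation_px, "min_separation_px")
  core <- (grad$class == "core") + 0
  empty <- data.frame(plant_id = integer(), row_px = numeric(),
                      col_px = numeric())
  if (!any(core == 1)) return(empty)
  lab <- EBImage::bwlabel(core)
  S <- grad$S; h <- grad$source_dim[1]; w <- grad$source_dim[2]
  # pixel-space center of tile (tr, tc), honoring truncated edge tiles
  tile_center <- function(t, extent) {
    lo <- (t - 1) * S          # 0-based first pixel
    hi <- pmin(t * S, extent) - 1
    (lo + hi) / 2
  }
  cents <- do.call(rbind, lapply(seq_len(max(lab)), function(l) {
    ij <- which(lab == l, arr.ind = TRUE)
    c(row = mean(tile_center(ij[, 1], h)),
      col = mean(tile_center(ij[, 2], w)),
      n = nrow(ij))
  }))
  # merge centroids closer than the separation floor, closest pair first
  repeat {
    if (nrow(cents) < 2L) break
    d <- as.matrix(stats::dist(cents[, c("row", "col")]))
    diag(d) <- Inf
    if (min(d) >= min_separation_px) break
    pair <- which(d == min(d), arr.ind = TRUE)[1, ]
    i <- min(pair); j <- max(pair)
    wsum <- cents[i, "n"] + cents[j, "n"]
    cents[i, "row"] <- (cents[i, "row"] * cents[i, "n"] +
                        cents[j, "row"] * cents[j, "n"]) / wsum
    cents[i, "col"] <- (cents[i, "col"] * cents[i, "n"] +
                        cents[j, "col"] * cents[j, "n"]) / wsum
    cents[i, "n"] <- wsum
    cents <- cents[-j, , drop = FALSE]
  }
  ord <- order(cents[, "row"], cents[, "col"])
  data.frame(plant_id = seq_along(ord),
             row_px = unname(cents[ord, "row"]),
             col_px = unname(cents[ord, "col"]))
}

# paint a filled red disc / box outline into an RGB array; 0-based centers
.draw_marker <- function(img, row0, col0, radius) {
  h <- dim(img)[1]; w <- dim(img)[2]
  rs <- max(1L, round(row0) + 1L - radius):min(h, round(row0) + 1L + radius)
  cs <- max(1L, round(col0) + 1L - radius):min(w, round(col0) + 1L + radius)
  for (r in rs) for (cc in cs) {
    if ((r - 1 - row0)^2 + (cc - 1 - col0)^2 <= radius^2) {
      img[r, cc, 1] <- 1; img[r, cc, 2] <- 0; img[r, cc, 3] <- 0
    }
  }
  img
}

.draw_box <- function(img, row0, col0, bh, bw) {
  h <- dim(img)[1]; w <- dim(img)[2]
  r1 <- round(row0 - bh / 2) + 1L; r2 <- round(row0 + bh / 2) + 1L
  c1 <- round(col0 - bw / 2) + 1L; c2 <- round(col0 + bw / 2) + 1L
  rs <- max(1L, r1):min(h, r2); cs <- max(1L, c1):min(w, c2)
  edge_r <- intersect(c(r1, r2), seq_len(h))
  edge_c <- intersect(c(c1, c2), seq_len(w))
  for (k in 1:3) {
    val <- if (k == 1) 1 else 0
    img[edge_r, cs, k] <- val
    img[rs, edge_c, k] <- val
  }
  img
}

#' Fuse plant locations onto a distribution map
#'
#' Produces the final location-distribution image: the per-tile canopy
#' rendering is alpha-blended onto the base image, then each plant is
#' marked with a filled red dot (5 px radius by default) and, when box
#' dimensions are present, a red box. In `gradient` style every tile is
#' tinted with its density-class color; in `binary` style only active
#' tiles are tinted (yellow), and pixels outside active tiles and marker
#' footprints are left untouched.
#'
#' @param base `H x W x 3` RGB array (e.g. the orthomosaic) or a 0/1
#'   matrix, which is promoted to grayscale RGB.
#' @param grid A `gradient_map` (style `"gradient"`) or
#'   `binary_distribution` (style `"binary"`).
#' @param plants Data frame with `plant_id`, `row_px`, `col_px`
#'   (0-based), optionally `box_height_px`, `box_width_px`; may have
#'   zero rows.
#' @param style `"gradient"` or `"binary"`; defaults to the grid's type.
#' @param alpha Blend weight of the distribution overlay in `[0, 1]`.
#' @param marker_radius_px Radius of the red plant dot.
#' @return Annotated `H x W x 3` RGB array with the base dimensions.
#' @export
fuse <- function(base, grid, plants, style = NULL, alpha = 0.5,
                 marker_radius_px = 5L) {
  if (is.matrix(base)) {
    assert_mask(base, "base")
    base <- array(rep(base + 0, 3L), c(dim(base), 3L))
  }
  assert_rgb(base, "base")
  if (is.null(style))
    style <- if (inherits(grid, "binary_distribution")) "binary" else "gradient"
  style <- match.arg(style, c("gradient", "binary"))
  if (!identical(as.integer(dim(base)[1:2]), as.integer(grid$source_dim)))
    pldm_stop("base dimensions do not match the tile grid's source",
              class = "pldm_validation_error")
  h <- dim(base)[1]; w <- dim(base)[2]
  out <- base
  if (style == "gradient") {
    stopifnot(inherits(grid, "gradient_map"))
    overlay <- gradient_rgb(grid)
    out <- (1 - alpha) * base + alpha * overlay
  } else {
    stopifnot(inherits(grid, "binary_distribution"))
    act <- reconstruct_pixel_map(grid) == 1L
    tint <- c(1, 1, 0)  # yellow canopy-range tiles
    for (k in 1:3) {
      ch <- out[, , k]
      ch[act] <- (1 - alpha) * ch[act] + alpha * tint[k]
      out[, , k] <- ch
    }
  }
  if (nrow(plants)) {
    if (any(plants$row_px < 0 | plants$row_px > h - 1 |
            plants$col_px < 0 | plants$col_px > w - 1))
      pldm_stop("plant center outside image bounds",
                class = "pldm_validation_error")
    has_box <- all(c("box_height_px", "box_width_px") %in% names(plants))
    for (i in seq_len(nrow(plants))) {
      if (has_box && !is.na(plants$box_height_px[i]))
        out <- .draw_box(out, plants$row_px[i], plants$col_px[i],
                         plants$box_height_px[i], plants$box_width_px[i])
      out <- .draw_marker(out, plants$row_px[i], plants$col_px[i],
                          as.integer(marker_radius_px))
    }
  }
  pmin(pmax(out, 0), 1)
}
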