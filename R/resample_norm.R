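#' Candidate sampling sizes for resampling normalization
#'
#' The twelve square tile side lengths (in pixels) swept when optimizing
#' the distribution map: 35 to 90 in steps of 5.
#'
#' @return Integer vector of length 12.
#' @export
#' @examples
#' sampling_sizes()
sampling_sizes <- function() {
  seq(35L, 90L, by = 5L)
}

#' Tile a segmentation mask into per-tile vine-pixel ratios
#'
#' Resampling normalization, step one: the mask is partitioned into square
#' tiles of side `S` (edge tiles truncated, never padded) and each tile is
#' summarized by the ratio `R = vine pixels / total pixels` of that tile.
#' Because edge tiles use their actual pixel count, the identity
#' `sum(R * n) == total vine pixels` holds tile by tile on the stored
#' integer counts.
#'
#' @param mask Integer 0/1 matrix, vine = 1.
#' @param S Sampling size: tile side length in pixels, `>= 1`.
#' @return A `distribution_map`: list with `S`, `ratio` (tile matrix of
#'   ratios in `[0, 1]`), `vine` and `npix` (integer count matrices), and
#'   `source_dim` (`c(H, W)` of the mask).
#' @export
#' @examples
#' m <- matrix(0L, 4, 4); m[1:2, 1:2] <- 1L
#' tile_ratios(m, 2)$ratio
tile_ratios <- function(mask, S) {
  assert_mask(mask)
  S <- assert_count(S, "S")
  h <- nrow(mask); w <- ncol(mask)
  gr <- ((seq_len(h) - 1L) %/% S) + 1L
  gc <- ((seq_len(w) - 1L) %/% S) + 1L
  vine_rows <- rowsum(mask + 0L, gr, reorder = TRUE)
  vine <- t(rowsum(t(vine_rows), gc, reorder = TRUE))
  storage.mode(vine) <- "integer"
  dimnames(vine) <- NULL
  npix <- outer(tabulate(gr), tabulate(gc))
  storage.mode(npix) <- "integer"
  structure(
    list(S = S, ratio = vine / npix, vine = vine, npix = npix,
         source_dim = c(h, w)),
    class = "distribution_map"
  )
}

#' @export
print.distribution_map <- function(x, ...) {
  cat(sprintf("<distribution_map> S = %d, %d x %d tiles over %d x %d px, mean R = %.3f\n",
              x$S, nrow(x$ratio), ncol(x$ratio),
              x$source_dim[1], x$source_dim[2], mean(x$ratio)))
  invisible(x)
}

# canopy density classes, densest first; palette per class
.gradient_classes <- c("core", "coverage", "transition", "naked")
.gradient_palette <- rbind(
  core       = c(0, 100, 0),
  coverage   = c(0, 200, 0),
  transition = c(255, 255, 255),
  naked      = c(139, 69, 19)
)

#' Gradient map palette
#'
#' RGB colors (0-255) used when rendering the four canopy density classes:
#' dark green = core area, green = coverage area, white = transition area,
#' brown = naked land.
#'
#' @return A 4 x 3 numeric matrix with row names `core`, `coverage`,
#'   `transition`, `naked`.
#' @export
gradient_palette <- function() .gradient_palette

#' Classify a distribution map into four canopy density classes
#'
#' Each tile's ratio `R` is mapped to a density class: `naked` when
#' `R == 0` exactly, `transition` when `0 < R < low`, `coverage` when
#' `low <= R < high`, and `core` when `R >= high`. Class boundaries
#' default to thirds.
#'
#' @param dist A `distribution_map` from [tile_ratios()].
#' @param cutpoints Numeric `c(low, high)` with `0 < low < high < 1`.
#' @return A `gradient_map`: list with `S`, `class` (character tile
#'   matrix), `cutpoints` and `source_dim`.
#' @export
gradient_map <- function(dist, cutpoints = c(1 / 3, 2 / 3)) {
  stopifnot(inherits(dist, "distribution_map"))
  if (length(cutpoints) != 2L || anyNA(cutpoints) ||
      !(0 < cutpoints[1] && cutpoints[1] < cutpoints[2] && cutpoints[2] < 1))
    pldm_stop("cutpoints must satisfy 0 < low < high < 1",
              class = "pldm_validation_error")
  r <- dist$ratio
  cls <- matrix("transition", nrow(r), ncol(r))
  cls[r == 0] <- "naked"
  cls[r >= cutpoints[1]] <- "coverage"
  cls[r >= cutpoints[2]] <- "core"
  structure(
    list(S = dist$S, class = cls, cutpoints = cutpoints,
         source_dim = dist$source_dim),
    class = "gradient_map"
  )
}

# Table of the eight threshold levels: level 1 carries the highest cutoff.
.threshold_table <- c(0.88, 0.77, 0.66, 0.55, 0.44, 0.33, 0.22, 0.11)

#' Threshold value of a threshold level
#'
#' The `(0, 1)` ratio range is divided into eight equal gradients indexed
#' by the threshold level `T`; level 1 carries the highest cutoff (0.88)
#' and level 8 the lowest (0.11), in steps of 0.11, so a higher level
#' admits more tiles. Values are the conventional two-decimal ones
#' (`0.11 * (9 - T)`), strictly decreasing in `T`.
#'
#' @param T Integer threshold level(s) in `1..8` (vectorized).
#' @return Numeric threshold value(s) in `(0, 1)`.
#' @export
#' @examples
#' threshold_of_level(5) # 0.44
#' threshold_of_level(1:8)
threshold_of_level <- function(T) {
  if (length(T) < 1L || anyNA(T) || any(T != as.integer(T)) ||
      any(T < 1L) || any(T > 8L))
    pldm_stop("T must be integer threshold level(s) in 1..8",
              class = "pldm_validation_error")
  .threshold_table[as.integer(T)]
}

#' Binarize a distribution map at a threshold level
#'
#' A tile is active iff its ratio `R` is greater than or equal to the
#' threshold value of level `T` (inclusive, so a ratio exactly at the
#' cutoff counts). Active-tile count is non-decreasing in `T`.
#'
#' @param dist A `distribution_map`.
#' @param T Threshold level in `1..8`.
#' @return A `binary_distribution`: list with `S`, `active` (logical tile
#'   matrix), `level`, `threshold` and `source_dim`.
#' @export
binarize_distribution <- function(dist, T) {
  stopifnot(inherits(dist, "distribution_map"))
  thr <- threshold_of_level(assert_count(T, "T"))
  structure(
    list(S = dist$S, active = dist$ratio >= thr, level = as.integer(T),
         threshold = thr, source_dim = dist$source_dim),
    class = "binary_distribution"
  )
}

#' Expand a tile grid back to pixel resolution by block fill
#'
#' Every pixel of tile `t` receives `t`'s value: the active flag (0/1
#' matrix) for a `binary_distribution`, or the class label (character
#' matrix, see [gradient_palette()] for colors) for a `gradient_map`.
#' Output dimensions equal the source mask's. Re-tiling a reconstructed
#' binary map at the same `S` and re-binarizing is a fixed point.
#'
#' @param grid A `binary_distribution` or `gradient_map`.
#' @param source_dim Optional `c(H, W)`; must match the grid's stored
#'   source dimensions if given.
#' @return Integer 0/1 matrix (binary) or character class matrix (gradient).
#' @export
reconstruct_pixel_map <- function(grid, source_dim = NULL) {
  if (!inherits(grid, c("binary_distribution", "gradient_map")))
    pldm_stop("grid must be a binary_distribution or gradient_map",
              class = "pldm_validation_error")
  if (!is.null(source_dim) && !identical(as.integer(source_dim),
                                         as.integer(grid$source_dim)))
    pldm_stop("source_dim mismatch: grid was built over ",
              paste(grid$source_dim, collapse = "x"), ", requested ",
              paste(source_dim, collapse = "x"),
              class = "pldm_validation_error")
  h <- grid$source_dim[1]; w <- grid$source_dim[2]
  ri <- ((seq_len(h) - 1L) %/% grid$S) + 1L
  ci <- ((seq_len(w) - 1L) %/% grid$S) + 1L
  vals <- if (inherits(grid, "binary_distribution")) grid$active + 0L else grid$class
  if (nrow(vals) != max(ri) || ncol(vals) != max(ci))
    pldm_stop("tile grid dimensions are inconsistent with source_dim",
              class = "pldm_validation_error")
  vals[ri, ci, drop = FALSE]
}

#' Render a gradient map as an RGB raster
#'
#' Block-fills the gradient classes to pixel resolution and applies the
#' class palette.
#'
#' @param grad A `gradient_map`.
#' @return `H x W x 3` array with values in `[0, 1]`.
#' @export
gradient_rgb <- function(grad) {
  stopifnot(inherits(grad, "gradient_map"))
  cls <- reconstruct_pixel_map(grad)
  pal <- .gradient_palette / 255
  out <- array(0, c(nrow(cls), ncol(cls), 3L))
  for (k in 1:3) out[, , k] <- matrix(pal[cls, k], nrow(cls), ncol(cls))
  out
}

#' Write / read a ratio grid as CSV
#'
#' Plain-text serialization of a `distribution_map`: a header line
#' `S,rows,cols`, one line with those three integers, then the ratio grid
#' row-major, one tile row per line. Tile pixel counts are recomputed from
#' `S` and the source dimensions on read. The source dimensions are
#' stored as two extra header fields `src_h,src_w`.
#'
#' @param dist A `distribution_map`.
#' @param path Output CSV path.
#' @return `write_ratio_grid` returns `path` invisibly; `read_ratio_grid`
#'   returns a `distribution_map` (with `vine` counts recovered by
#'   rounding `R * n`).
#' @export
write_ratio_grid <- function(dist, path) {
  stopifnot(inherits(dist, "distribution_map"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("S,rows,cols,src_h,src_w", con)
  writeLines(paste(dist$S, nrow(dist$ratio), ncol(dist$ratio),
                   dist$source_dim[1], dist$source_dim[2], sep = ","), con)
  writeLines(apply(format(dist$ratio, digits = 17, trim = TRUE), 1,
                   paste, collapse = ","), con)
  invisible(path)
}

#' @rdname write_ratio_grid
#' @export
read_ratio_grid <- function(path) {
  if (!file.exists(path))
    pldm_stop("cannot read ratio grid: ", path, class = "pldm_io_error")
  lines <- readLines(path)
  hdr <- as.integer(strsplit(lines[2], ",")[[1]])
  S <- hdr[1]; nr <- hdr[2]; nc <- hdr[3]; src <- hdr[4:5]
  vals <- do.call(rbind, lapply(lines[3:(2 + nr)],
                                function(l) as.numeric(strsplit(l, ",")[[1]])))
  ri <- ((seq_len(src[1]) - 1L) %/% S) + 1L
  ci <- ((seq_len(src[2]) - 1L) %/% S) + 1L
  npix <- outer(tabulate(ri), tabulate(ci))
  storage.mode(npix) <- "integer"
  vine <- matrix(as.integer(round(vals * npix)), nr, nc)
  structure(list(S = S, ratio = vals, vine = vine, npix = npix,
                 source_dim = src),
            class = "distribution_map")
}
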