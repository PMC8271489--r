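#' Read a binary segmentation mask from a PNG or TIFF file
#'
#' Accepts single-channel or RGB rasters. Channels are collapsed by
#' maximum and the result thresholded at 128/255, so grayscale files with
#' values in \{0, 255\} round-trip losslessly to \{0, 1\}.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return Integer 0/1 matrix, vine = 1.
#' @export
read_mask <- function(path) {
  img <- read_raster(path)
  if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), max)
  out <- matrix(as.integer(img >= 128 / 255), nrow(img), ncol(img))
  out
}

# shared PNG/TIFF reader returning values in [0,1]
read_raster <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    pldm_stop("cannot read raster: file not found: ", path,
              class = "pldm_io_error")
  ext <- tolower(tools::file_ext(path))
  img <- tryCatch(
    switch(ext,
           png = png::readPNG(path),
           tif = , tiff = tiff::readTIFF(path),
           pldm_stop("unsupported raster format '", ext, "': ", path,
                     class = "pldm_format_error")),
    error = function(e) {
      if (inherits(e, "pldm_error")) stop(e)
      pldm_stop("not a readable ", ext, " image: ", path,
                class = "pldm_format_error")
    })
  if (length(dim(img)) == 3L && dim(img)[3] > 3L)
    img <- img[, , 1:3, drop = FALSE]  # drop alpha
  img
}

#' Write a binary mask as a 0/255 grayscale PNG
#'
#' @param mask Integer 0/1 matrix.
#' @param path Output path (`.png`).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  assert_mask(mask)
  png::writePNG(mask + 0, target = path)
  invisible(path)
}

#' Read / write an RGB image
#'
#' @param image `H x W x 3` array in `[0, 1]`.
#' @param path Image path; PNG written, PNG/TIFF read.
#' @return `read_image` returns an `H x W x 3` array; `write_image`
#'   returns `path` invisibly.
#' @export
read_image <- function(path) {
  img <- read_raster(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  img
}

#' @rdname read_image
#' @export
write_image <- function(image, path) {
  assert_rgb(image)
  png::writePNG(pmin(pmax(image, 0), 1), target = path)
  invisible(path)
}

#' Cut an image into network-sized tiles
#'
#' Partitions the image exactly into `ceil(H/t) * ceil(W/t)` tiles of side
#' `tile_size_px`; edge tiles are kept at their partial size, never
#' padded, so pixel counts are conserved. The default side of 417 px
#' matches the chip size used to train segmentation networks on clipped
#' orthomosaics.
#'
#' @param image Matrix or `H x W x C` array.
#' @param tile_size_px Tile side length in pixels.
#' @return List with `tiles` (named list of sub-images, names =
#'   `tile_id`) and `index` (a `tile_index` data frame with columns
#'   `tile_id`, `row_offset_px`, `col_offset_px`, `height_px`,
#'   `width_px`; offsets 0-based, origin top-left).
#' @export
tile_image <- function(image, tile_size_px = 417L) {
  t <- assert_count(tile_size_px, "tile_size_px")
  d <- dim(image)
  if (is.null(d) || any(d[1:2] < 1L))
    pldm_stop("image must be a nonempty matrix or array",
              class = "pldm_validation_error")
  h <- d[1]; w <- d[2]
  nr <- ceiling(h / t); nc <- ceiling(w / t)
  idx <- expand.grid(tc = seq_len(nc), tr = seq_len(nr))[, c("tr", "tc")]
  index <- data.frame(
    tile_id = seq_len(nrow(idx)),
    row_offset_px = (idx$tr - 1L) * t,
    col_offset_px = (idx$tc - 1L) * t,
    height_px = pmin(idx$tr * t, h) - (idx$tr - 1L) * t,
    width_px = pmin(idx$tc * t, w) - (idx$tc - 1L) * t
  )
  attr(index, "tile_size_px") <- t
  attr(index, "image_dim") <- d
  class(index) <- c("tile_index", "data.frame")
  tiles <- lapply(seq_len(nrow(index)), function(i) {
    r0 <- index$row_offset_px[i]; c0 <- index$col_offset_px[i]
    rows <- (r0 + 1L):(r0 + index$height_px[i])
    cols <- (c0 + 1L):(c0 + index$width_px[i])
    if (length(d) == 3L) image[rows, cols, , drop = FALSE]
    else image[rows, cols, drop = FALSE]
  })
  names(tiles) <- as.character(index$tile_id)
  list(tiles = tiles, index = index)
}

#' Reassemble tiles into the original image
#'
#' Exact inverse of [tile_image()]: tiles are placed at their recorded
#' offsets, so the list order does not matter as long as names carry the
#' tile ids.
#'
#' @param tiles Named list of sub-images (names = `tile_id`), or unnamed
#'   in `index` row order.
#' @param index The `tile_index` from [tile_image()].
#' @return The reassembled matrix or array.
#' @export
stitch_tiles <- function(tiles, index) {
  stopifnot(inherits(index, "tile_index"))
  d <- attr(index, "image_dim")
  if (is.null(names(tiles))) names(tiles) <- as.character(index$tile_id)
  out <- if (length(d) == 3L) array(0, d) else
    matrix(0L, d[1], d[2])
  for (i in seq_len(nrow(index))) {
    id <- as.character(index$tile_id[i])
    tl <- tiles[[id]]
    if (is.null(tl))
      pldm_stop("missing tile: tile_id ", id, class = "pldm_validation_error")
    td <- dim(tl)
    if (td[1] != index$height_px[i] || td[2] != index$width_px[i])
      pldm_stop("tile shape mismatch for tile_id ", id, ": got ",
                td[1], "x", td[2], ", expected ", index$height_px[i], "x",
                index$width_px[i], class = "pldm_validation_error")
    rows <- (index$row_offset_px[i] + 1L):(index$row_offset_px[i] + td[1])
    cols <- (index$col_offset_px[i] + 1L):(index$col_offset_px[i] + td[2])
    if (length(d) == 3L) out[rows, cols, ] <- tl else out[rows, cols] <- tl
  }
  if (length(d) != 3L) storage.mode(out) <- storage.mode(tiles[[1]])
  out
}

#' Serialize / restore a tile index as JSON
#'
#' @param index A `tile_index`.
#' @param path JSON path.
#' @return `write_tile_index` returns `path` invisibly; `read_tile_index`
#'   returns a `tile_index`.
#' @export
write_tile_index <- function(index, path) {
  stopifnot(inherits(index, "tile_index"))
  obj <- list(tile_size_px = attr(index, "tile_size_px"),
              image_dim = attr(index, "image_dim"),
              tiles = as.data.frame(index))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_tile_index
#' @export
read_tile_index <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  index <- as.data.frame(obj$tiles)
  attr(index, "tile_size_px") <- as.integer(obj$tile_size_px)
  attr(index, "image_dim") <- as.integer(obj$image_dim)
  class(index) <- c("tile_index", "data.frame")
  index
}

#' Read / write plant-location tables
#'
#' CSV with header `plant_id,row_px,col_px` (optionally
#' `box_height_px,box_width_px` for detector boxes). Coordinates are
#' 0-based pixel positions, origin top-left, and must be nonnegative.
#'
#' @param path CSV path.
#' @param plants Data frame with columns `plant_id`, `row_px`, `col_px`.
#' @return `read_plants` returns a data frame (zero rows for a
#'   header-only file); `write_plants` returns `path` invisibly.
#' @export
read_plants <- function(path) {
  if (!file.exists(path))
    pldm_stop("cannot read plant table: ", path, class = "pldm_io_error")
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                 error = function(e)
                   pldm_stop("malformed plant table: ", path,
                             class = "pldm_parse_error"))
  need <- c("plant_id", "row_px", "col_px")
  if (!all(need %in% names(df)))
    pldm_stop("plant table must have header plant_id,row_px,col_px: ", path,
              class = "pldm_parse_error")
  for (col in c("row_px", "col_px")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) | v < 0)
    if (length(bad))
      pldm_stop("invalid ", col, " at line ", bad[1] + 1L, " of ", path,
                class = "pldm_parse_error")
    df[[col]] <- v
  }
  df
}

#' @rdname read_plants
#' @export
write_plants <- function(plants, path) {
  stopifnot(is.data.frame(plants),
            all(c("plant_id", "row_px", "col_px") %in% names(plants)))
  if (nrow(plants) && any(plants$row_px < 0 | plants$col_px < 0))
    pldm_stop("plant coordinates must be nonnegative",
              class = "pldm_validation_error")
  write.csv(plants, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
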