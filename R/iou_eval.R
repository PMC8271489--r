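#' Intersection over union of two binary rasters
#'
#' `|P intersect Q| / |P union Q|` over foreground pixels; symmetric,
#' bounded in `[0, 1]`, and defined as 1 when both rasters are empty
#' (perfect agreement on "nothing there").
#'
#' @param P,Q Integer 0/1 matrices of equal dimensions.
#' @return IoU in `[0, 1]`.
#' @export
#' @examples
#' a <- matrix(0L, 4, 4); a[1:2, 1:2] <- 1L
#' iou(a, a) # 1
iou <- function(P, Q) {
  assert_mask(P, "P"); assert_mask(Q, "Q")
  assert_same_dim(P, Q, c("P", "Q"))
  inter <- sum(P == 1L & Q == 1L)
  uni <- sum(P == 1L | Q == 1L)
  if (uni == 0L) return(1.0)
  inter / uni
}

#' Score one (S, T) configuration against canopy ground truth
#'
#' The full resampling-normalization scoring path: tile the mask at
#' sampling size `S`, binarize the ratio grid at threshold level `T`,
#' block-fill back to pixel resolution, and take the pixel-level IoU
#' against the true canopy range. IoU is computed in image space (not on
#' the tile grid) so the score does not depend on how the truth would be
#' rasterized to tiles.
#'
#' @param mask Segmentation mask (0/1 matrix).
#' @param truth True canopy-range mask of the same dimensions.
#' @param S Sampling size (px).
#' @param T Threshold level in `1..8`.
#' @return IoU in `[0, 1]`.
#' @export
score_configuration <- function(mask, truth, S, T) {
  assert_mask(mask); assert_mask(truth, "truth")
  assert_same_dim(mask, truth, c("mask", "truth"))
  rec <- reconstruct_pixel_map(binarize_distribution(tile_ratios(mask, S), T))
  iou(rec, truth)
}

#' Sweep IoU over methods, sampling sizes and threshold levels
#'
#' Exhaustive grid: one record per (method, S, T, image). With the
#' twelve default sampling sizes and eight threshold levels, three
#' methods on one image yield 288 binarized distribution maps.
#'
#' @param masks Named list of methods; each element a named list of
#'   segmentation masks keyed by `image_id`.
#' @param truths Named list of canopy-truth masks keyed by `image_id`;
#'   every image appearing under a method must have a truth.
#' @param S_list Sampling sizes to sweep (default [sampling_sizes()]).
#' @param T_levels Threshold levels to sweep (default `1:8`).
#' @return A `sweep_result` data frame with columns
#'   `method, S, T, image_id, iou` and attributes `S_list`, `T_levels`.
#' @export
sweep_iou <- function(masks, truths, S_list = sampling_sizes(),
                      T_levels = 1:8) {
  if (!is.list(masks) || is.null(names(masks)) || !length(masks))
    pldm_stop("masks must be a named list of methods",
              class = "pldm_validation_error")
  if (!length(S_list))
    pldm_stop("S_list must be nonempty", class = "pldm_validation_error")
  if (!length(T_levels))
    pldm_stop("T_levels must be nonempty", class = "pldm_validation_error")
  threshold_of_level(T_levels)  # validates range
  rows <- list()
  for (method in names(masks)) {
    imgs <- masks[[method]]
    if (is.null(names(imgs)))
      names(imgs) <- as.character(seq_along(imgs))
    for (image_id in names(imgs)) {
      if (is.null(truths[[image_id]]))
        pldm_stop("missing truth for image_id '", image_id, "'",
                  class = "pldm_validation_error")
      truth <- truths[[image_id]]
      for (S in S_list) {
        dist <- tile_ratios(imgs[[image_id]], S)
        for (T in T_levels) {
          rec <- reconstruct_pixel_map(binarize_distribution(dist, T))
          rows[[length(rows) + 1L]] <- data.frame(
            method = method, S = as.integer(S), T = as.integer(T),
            image_id = image_id, iou = iou(rec, truth),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "S_list") <- as.integer(S_list)
  attr(out, "T_levels") <- as.integer(T_levels)
  class(out) <- c("sweep_result", "data.frame")
  out
}

.check_method <- function(sweep, method) {
  stopifnot(inherits(sweep, "sweep_result") || is.data.frame(sweep))
  if (!method %in% sweep$method)
    pldm_stop("unknown method '", method, "' in sweep",
              class = "pldm_lookup_error")
  sweep[sweep$method == method, , drop = FALSE]
}

#' Best sampling-size/threshold pair for a method
#'
#' Argmax of the mean IoU over images; ties broken deterministically by
#' smaller `S`, then smaller `T`.
#'
#' @param sweep A `sweep_result` from [sweep_iou()].
#' @param method Method name present in the sweep.
#' @return List with `S`, `T` and `mean_iou`.
#' @export
best_parameters <- function(sweep, method) {
  sub <- .check_method(sweep, method)
  agg <- aggregate(iou ~ S + T, data = sub, FUN = mean)
  agg <- agg[order(-agg$iou, agg$S, agg$T), , drop = FALSE]
  list(S = as.integer(agg$S[1]), T = as.integer(agg$T[1]),
       mean_iou = agg$iou[1])
}

#' Mean-IoU surface over the (S, T) grid for one method
#'
#' @param sweep A `sweep_result`.
#' @param method Method name.
#' @return Numeric matrix, rows = sampling sizes (in `S_list` order),
#'   columns = threshold levels; cells are means over images.
#' @export
iou_surface <- function(sweep, method) {
  sub <- .check_method(sweep, method)
  S_list <- attr(sweep, "S_list"); T_levels <- attr(sweep, "T_levels")
  if (is.null(S_list)) S_list <- sort(unique(sub$S))
  if (is.null(T_levels)) T_levels <- sort(unique(sub$T))
  surf <- matrix(NA_real_, length(S_list), length(T_levels),
                 dimnames = list(S = S_list, T = T_levels))
  agg <- aggregate(iou ~ S + T, data = sub, FUN = mean)
  surf[cbind(match(agg$S, S_list), match(agg$T, T_levels))] <- agg$iou
  surf
}

#' Per-image IoU curves across sampling sizes at a fixed threshold level
#'
#' @param sweep A `sweep_result`.
#' @param method Method name.
#' @param T Threshold level to slice at.
#' @return Data frame, one row per image, one column per sampling size
#'   (named `S<value>`), plus a leading `image_id` column.
#' @export
per_image_curves <- function(sweep, method, T = 5L) {
  sub <- .check_method(sweep, method)
  sub <- sub[sub$T == T, , drop = FALSE]
  S_list <- attr(sweep, "S_list")
  if (is.null(S_list)) S_list <- sort(unique(sub$S))
  ids <- unique(sub$image_id)
  out <- data.frame(image_id = ids, stringsAsFactors = FALSE)
  for (S in S_list)
    out[[paste0("S", S)]] <-
      sub$iou[match(paste(ids, S), paste(sub$image_id, sub$S))]
  out
}
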