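#' Per-pixel features for vine/background classification
#'
#' One record per pixel, in R's column-major raster order. Features:
#' the `R`, `G`, `B` channels on a 0-255 scale, the excess-green index
#' `ExG = 2G - R - B` (a standard vegetation index for RGB-only imagery),
#' and the local gray-level variance in a 3 x 3 window (texture cue that
#' separates grassy ground from smooth canopy).
#'
#' @param image `H x W x 3` RGB array with values in `[0, 1]`.
#' @return Data frame with columns `R`, `G`, `B`, `exg`,
#'   `local_variance`; `nrow = H * W`.
#' @export
extract_features <- function(image) {
  assert_rgb(image)
  d <- dim(image)
  chan <- function(k) matrix(image[, , k], d[1], d[2]) * 255
  r <- chan(1); g <- chan(2); b <- chan(3)
  exg <- 2 * g - r - b
  gray <- (r + g + b) / 3
  k <- matrix(1 / 9, 3, 3)
  if (all(dim(gray) >= 3L)) {
    m1 <- EBImage::filter2(gray, k)
    m2 <- EBImage::filter2(gray^2, k)
  } else {
    # images narrower than the window: same circular 3x3 mean, by hand
    box_mean <- function(x) {
      h <- nrow(x); w <- ncol(x)
      ri <- function(i) ((i - 1L) %% h) + 1L
      ci <- function(j) ((j - 1L) %% w) + 1L
      out <- x
      for (i in seq_len(h)) for (j in seq_len(w))
        out[i, j] <- mean(x[ri(i + (-1:1)), ci(j + (-1:1))])
      out
    }
    m1 <- box_mean(gray)
    m2 <- box_mean(gray^2)
  }
  v <- pmax(m2 - m1^2, 0)
  v[v < 1e-8] <- 0  # squash representation error on flat patches
  data.frame(R = as.vector(r), G = as.vector(g), B = as.vector(b),
             exg = as.vector(exg), local_variance = as.vector(v))
}

#' Construct a threshold-based pixel classifier
#'
#' The excess-green thresholding rule `ExG >= exg_threshold` needs no
#' training (it is always fitted); [train_classifier()] can refit the
#' threshold from labeled pixels.
#'
#' @param exg_threshold Cutoff on the 0-255-scale excess-green index.
#' @return A `pixel_classifier` of kind `color_threshold`.
#' @export
pixel_classifier <- function(exg_threshold = 150) {
  structure(list(kind = "color_threshold", fitted = TRUE,
                 exg_threshold = exg_threshold,
                 feature_names = c("R", "G", "B", "exg", "local_variance")),
            class = "pixel_classifier")
}

#' @export
print.pixel_classifier <- function(x, ...) {
  cat(sprintf("<pixel_classifier> kind = %s, fitted = %s\n",
              x$kind, x$fitted))
  invisible(x)
}

#' Train a baseline per-pixel classifier
#'
#' Baselines standing in for the classical vine segmenters:
#' `color_threshold` (excess-green cutoff refit as the midpoint between
#' class means), `forest_like` (random forest, 100 trees) and
#' `margin_like` (RBF support vector machine on a subsample of at most
#' `svm_subsample` pixels — kernel methods scale quadratically, and a
#' few thousand pixels saturate accuracy on these features).
#'
#' @param features Feature table from [extract_features()].
#' @param labels Binary vector (1 = vine), one per feature row, with at
#'   least two pixels of each class.
#' @param kind One of `"color_threshold"`, `"forest_like"`,
#'   `"margin_like"`.
#' @param svm_subsample Training-set cap for the margin classifier.
#' @return A fitted `pixel_classifier`.
#' @export
train_classifier <- function(features, labels,
                             kind = c("color_threshold", "forest_like",
                                      "margin_like"),
                             svm_subsample = 5000L) {
  kind <- match.arg(kind)
  stopifnot(is.data.frame(features))
  labels <- as.integer(labels)
  if (length(labels) != nrow(features))
    pldm_stop("labels length must match feature rows",
              class = "pldm_validation_error")
  if (anyNA(labels) || !all(labels %in% c(0L, 1L)))
    pldm_stop("labels must be binary 0/1", class = "pldm_validation_error")
  if (sum(labels == 0L) < 2L || sum(labels == 1L) < 2L)
    pldm_stop("need at least two pixels of each class",
              class = "pldm_validation_error")
  cl <- switch(
    kind,
    color_threshold = {
      thr <- mean(c(mean(features$exg[labels == 1L]),
                    mean(features$exg[labels == 0L])))
      flip <- mean(features$exg[labels == 1L]) < mean(features$exg[labels == 0L])
      structure(list(kind = kind, fitted = TRUE, exg_threshold = thr,
                     invert = flip,
                     feature_names = names(features)),
                class = "pixel_classifier")
    },
    forest_like = {
      keep <- subsample_classes(labels, 50000L)
      fit <- randomForest::randomForest(features[keep, , drop = FALSE],
                                        factor(labels[keep], levels = 0:1),
                                        ntree = 100)
      structure(list(kind = kind, fitted = TRUE, model = fit,
                     feature_names = names(features)),
                class = "pixel_classifier")
    },
    margin_like = {
      keep <- subsample_classes(labels, as.integer(svm_subsample))
      x <- features[keep, , drop = FALSE]
      scale_cols <- vapply(x, function(v) stats::var(v) > 0, logical(1))
      fit <- e1071::svm(x, factor(labels[keep], levels = 0:1),
                        kernel = "radial", scale = scale_cols)
      structure(list(kind = kind, fitted = TRUE, model = fit,
                     feature_names = names(features)),
                class = "pixel_classifier")
    })
  cl
}

# class-stratified deterministic subsample of row indices (at most `cap`),
# keeping at least two rows per class
subsample_classes <- function(labels, cap) {
  n <- length(labels)
  if (n <= cap) return(seq_len(n))
  with_seed(20210444L, {
    idx <- unlist(lapply(split(seq_len(n), labels), function(ix) {
      take <- max(2L, round(cap * length(ix) / n))
      if (length(ix) <= take) ix else sample(ix, take)
    }), use.names = FALSE)
    sort(idx)
  })
}

#' Segment an image into a vine mask
#'
#' Applies a fitted per-pixel classifier to every pixel. Predictions
#' depend only on each pixel's features (plus the 3 x 3 texture window),
#' so there is no other spatial coupling. An optional median post-filter
#' (odd kernel width) can knock down isolated salt-and-pepper errors.
#'
#' @param image `H x W x 3` RGB array.
#' @param classifier A fitted `pixel_classifier`.
#' @param median_filter_px `NULL` (default, off) or an odd kernel width.
#' @return Integer 0/1 mask with the image's dimensions.
#' @export
segment <- function(image, classifier, median_filter_px = NULL) {
  assert_rgb(image)
  if (!inherits(classifier, "pixel_classifier") || !isTRUE(classifier$fitted))
    pldm_stop("classifier is not fitted", class = "pldm_state_error")
  feats <- extract_features(image)
  pred <- switch(
    classifier$kind,
    color_threshold = {
      p <- as.integer(feats$exg >= classifier$exg_threshold)
      if (isTRUE(classifier$invert)) 1L - p else p
    },
    forest_like = as.integer(as.character(predict(classifier$model, feats))),
    margin_like = as.integer(as.character(predict(classifier$model, feats))),
    pldm_stop("unknown classifier kind: ", classifier$kind,
              class = "pldm_validation_error"))
  mask <- matrix(pred, dim(image)[1], dim(image)[2])
  if (!is.null(median_filter_px)) {
    median_filter_px <- assert_count(median_filter_px, "median_filter_px")
    if (median_filter_px %% 2L == 0L)
      pldm_stop("median_filter_px must be odd", class = "pldm_validation_error")
    sm <- EBImage::medianFilter(mask + 0, (median_filter_px - 1L) / 2L)
    mask <- matrix(as.integer(sm >= 0.5), nrow(mask), ncol(mask))
  }
  mask
}

#' Confusion counts for a binary segmentation
#'
#' @param pred,truth Integer 0/1 masks of equal dimensions.
#' @return 2 x 2 integer matrix `n[true_class, pred_class]` with
#'   dimnames `background`/`vine`; entries sum to the pixel count.
#' @export
confusion_summary <- function(pred, truth) {
  assert_mask(pred, "pred"); assert_mask(truth, "truth")
  assert_same_dim(pred, truth)
  tab <- table(factor(truth, levels = 0:1), factor(pred, levels = 0:1))
  out <- matrix(as.integer(tab), 2, 2,
                dimnames = list(true = c("background", "vine"),
                                pred = c("background", "vine")))
  out
}

#' Mean per-class pixel accuracy (mAP), as a percentage
#'
#' The per-class ratio of correctly classified pixels to true pixels of
#' that class, averaged over the classes present in `truth` and scaled
#' to percent. Equals 100 iff `pred == truth` when both classes are
#' present; 0 for a full complement.
#'
#' @param pred,truth Integer 0/1 masks of equal dimensions.
#' @return A percentage in `[0, 100]`.
#' @export
evaluate_map <- function(pred, truth) {
  cm <- confusion_summary(pred, truth)
  per_class <- diag(cm) / rowSums(cm)
  100 * mean(per_class[rowSums(cm) > 0])
}

#' Signal-to-noise ratio of a segmentation, in decibels
#'
#' `10 * log10(TP / misclassified)`, where TP counts correctly detected
#' vine pixels and misclassified counts all erroneous pixels of either
#' class. Higher is cleaner; a perfect segmentation (no errors) reports
#' `Inf`.
#'
#' @param pred,truth Integer 0/1 masks of equal dimensions; `pred` must
#'   detect at least one true vine pixel.
#' @return SNR in dB (`Inf` when error-free).
#' @export
evaluate_snr <- function(pred, truth) {
  assert_mask(pred, "pred"); assert_mask(truth, "truth")
  assert_same_dim(pred, truth)
  tp <- sum(pred == 1L & truth == 1L)
  err <- sum(pred != truth)
  if (tp == 0L)
    pldm_stop("SNR undefined: no correctly classified vine pixel",
              class = "pldm_undefined_result_error")
  if (err == 0L) return(Inf)
  10 * log10(tp / err)
}

#' Save / load a classifier artifact
#'
#' Single-file binary artifact (RDS).
#'
#' @param classifier A `pixel_classifier`.
#' @param path Artifact path.
#' @return `save_classifier` returns `path` invisibly; `load_classifier`
#'   returns the `pixel_classifier`.
#' @export
save_classifier <- function(classifier, path) {
  stopifnot(inherits(classifier, "pixel_classifier"))
  saveRDS(classifier, path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  if (!file.exists(path))
    pldm_stop("cannot read classifier artifact: ", path,
              class = "pldm_io_error")
  obj <- readRDS(path)
  if (!inherits(obj, "pixel_classifier"))
    pldm_stop("not a classifier artifact: ", path, class = "pldm_format_error")
  obj
}
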