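test_that("features come one per pixel with the documented values", {
  img <- array(runif(10 * 10 * 3), c(10, 10, 3))
  f <- extract_features(img)
  expect_equal(nrow(f), 100L)
  expect_true(all(is.finite(as.matrix(f))))
  # pure green pixel: ExG = 2*255 - 0 - 0 = 510
  g <- array(0, c(1, 2, 3)); g[1, 1, 2] <- 1
  fg <- extract_features(g)
  expect_equal(fg$exg[1], 510)
  # constant-color image has zero local variance everywhere
  flat <- array(0.4, c(8, 8, 3))
  expect_true(all(extract_features(flat)$local_variance == 0))
  expect_error(extract_features(matrix(0, 5, 5)), "RGB")
})

test_that("classifiers fit a linearly separable two-color fixture exactly", {
  img <- array(0, c(20, 20, 3))
  img[, , 2] <- matrix(rep(c(0.9, 0.1), each = 200), 20, 20)  # left half green
  labels <- as.vector(matrix(rep(c(1L, 0L), each = 200), 20, 20))
  feats <- extract_features(img)
  for (kind in c("color_threshold", "forest_like", "margin_like")) {
    cl <- train_classifier(feats, labels, kind)
    expect_true(cl$fitted)
    pred <- as.vector(segment(img, cl))
    expect_equal(mean(pred == labels), 1.0)
  }
})

test_that("training learns inverted labels no worse than chance", {
  img <- array(0, c(20, 20, 3))
  img[, , 2] <- matrix(rep(c(0.9, 0.1), each = 200), 20, 20)
  labels <- as.vector(matrix(rep(c(0L, 1L), each = 200), 20, 20))  # inverted
  feats <- extract_features(img)
  for (kind in c("color_threshold", "forest_like")) {
    cl <- train_classifier(feats, labels, kind)
    acc <- mean(as.vector(segment(img, cl)) == labels)
    expect_gte(acc, 0.5)
  }
})

test_that("degenerate label sets are rejected", {
  feats <- data.frame(R = 1:10, G = 1:10, B = 1:10, exg = 1:10,
                      local_variance = 0)
  expect_error(train_classifier(feats, rep(1L, 10), "forest_like"),
               "each class")
  expect_error(train_classifier(feats, c(1L, rep(0L, 9)), "forest_like"),
               "each class")
  expect_error(train_classifier(feats, rep(c(0L, 2L), 5), "forest_like"),
               "binary")
})

test_that("color thresholding reproduces truth on a noiseless scene", {
  # vine pixels carry the distinct canopy green on a flat background
  sc <- generate_scene(small_scene_config(seed = 3L))
  img <- array(0, c(dim(sc$vine_mask), 3L))
  base <- c(0.38, 0.42, 0.25); vine <- c(0.10, 0.85, 0.15)
  for (k in 1:3)
    img[, , k] <- ifelse(sc$vine_mask == 1L, vine[k], base[k])
  expect_identical(segment(img, pixel_classifier()), sc$vine_mask)
  # and an all-background image maps to an all-zero mask
  flat <- array(rep(base, each = 100), c(10, 10, 3))
  expect_true(all(segment(flat, pixel_classifier()) == 0L))
})

test_that("unfitted or unknown classifiers are refused", {
  img <- array(0.5, c(4, 4, 3))
  bad <- structure(list(kind = "forest_like", fitted = FALSE),
                   class = "pixel_classifier")
  expect_error(segment(img, bad), "not fitted")
})

test_that("random forest recovers truth from noisy training labels", {
  sc <- generate_scene(scene_config(120L, 160L, vines_per_plant = 8L,
                                    vine_max_length_px = 30L,
                                    canopy_dilation_px = 8L, random_seed = 4L))
  noisy_labels <- corrupt_mask(sc$vine_mask, 0.02, 0.02, seed = 9L)
  feats <- extract_features(sc$rgb)
  set.seed(1)
  cl <- train_classifier(feats, as.vector(noisy_labels), "forest_like")
  pred <- segment(sc$rgb, cl)
  expect_gt(mean(pred == sc$vine_mask), 0.9)
})

test_that("segmentation depends only on pixel color, not position", {
  set.seed(6)
  img <- array(runif(12 * 12 * 3), c(12, 12, 3))
  perm <- sample(144)
  shuffled <- array(0, dim(img))
  for (k in 1:3) shuffled[, , k] <- matrix(img[, , k][perm], 12, 12)
  cl <- pixel_classifier()
  expect_identical(as.vector(segment(shuffled, cl)),
                   as.vector(segment(img, cl))[perm])
})

test_that("median post-filter removes isolated noise and needs an odd width", {
  m <- matrix(0L, 30, 30); m[10:20, 10:20] <- 1L
  img <- array(0, c(30, 30, 3)); img[, , 2] <- m  # green block
  noisy <- segment(img, pixel_classifier(exg_threshold = 100))
  expect_identical(noisy, m)
  filtered <- segment(img, pixel_classifier(exg_threshold = 100),
                      median_filter_px = 3L)
  expect_equal(sum(filtered != m), 4L)  # only the block corners erode
  expect_error(segment(img, pixel_classifier(), median_filter_px = 4L), "odd")
})

test_that("mAP is the mean per-class recall, in percent", {
  m <- random_mask(10, 10, 0.4)
  expect_equal(evaluate_map(m, m), 100)
  both <- matrix(c(rep(1L, 30), rep(0L, 70)), 10, 10)
  expect_equal(evaluate_map(1L - both, both), 0)
  # 10 vine / 90 background, 5 vine recovered, background all correct:
  # (50% + 100%) / 2 = 75%
  truth <- matrix(0L, 10, 10); truth[1, 1:10] <- 1L
  pred <- matrix(0L, 10, 10); pred[1, 1:5] <- 1L
  expect_equal(evaluate_map(pred, truth), 75)
  cm <- confusion_summary(pred, truth)
  expect_equal(sum(cm), 100L)
  expect_equal(unname(cm["vine", "vine"]), 5L)
  expect_error(evaluate_map(pred, truth[1:5, , drop = FALSE]), "dimensions")
})

test_that("mAP is symmetric under simultaneous class relabeling", {
  set.seed(8)
  for (k in 1:5) {
    truth <- random_mask(15, 15, 0.4)
    pred <- random_mask(15, 15, 0.4)
    expect_equal(evaluate_map(pred, truth),
                 evaluate_map(1L - pred, 1L - truth))
  }
})

test_that("SNR follows 10*log10(TP/errors) with a perfect sentinel", {
  m <- random_mask(20, 20, 0.5)
  expect_identical(evaluate_snr(m, m), Inf)
  # 100 TP, 10 errors -> 10 dB
  truth <- matrix(0L, 20, 20); truth[1:5, 1:20] <- 1L  # 100 vine
  pred <- truth; pred[6, 1:10] <- 1L                   # 10 false positives
  expect_equal(evaluate_snr(pred, truth), 10)
  # 1000 TP, 50 errors -> 10*log10(20) = 13.0103 dB
  truth2 <- matrix(0L, 40, 40); truth2[1:25, 1:40] <- 1L
  pred2 <- truth2; pred2[26:40, 1:40][1:50] <- 1L
  expect_equal(evaluate_snr(pred2, truth2), 13.0103, tolerance = 1e-5)
  expect_error(evaluate_snr(1L - m, m), "undefined")
})

test_that("classifier artifacts survive a save/load round-trip", {
  path <- withr::local_tempfile(fileext = ".rds")
  cl <- pixel_classifier(exg_threshold = 123)
  save_classifier(cl, path)
  back <- load_classifier(path)
  expect_identical(back$exg_threshold, 123)
  expect_error(load_classifier("/nonexistent.rds"), "artifact")
})
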