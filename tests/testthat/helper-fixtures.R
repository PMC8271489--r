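# shared fixtures, built in code at test time

# random 0/1 mask with given foreground probability
random_mask <- function(h, w, p = 0.3) {
  matrix(as.integer(runif(h * w) < p), h, w)
}

# small scene that generates in well under a second
small_scene_config <- function(seed = 1L, ...) {
  scene_config(image_height_px = 200L, image_width_px = 320L,
               vines_per_plant = 8L, vine_max_length_px = 30L,
               canopy_dilation_px = 8L, random_seed = seed, ...)
}

# independent oracle: per-pixel double-loop tile ratio counter
naive_tile_ratios <- function(mask, S) {
  h <- nrow(mask); w <- ncol(mask)
  nr <- ceiling(h / S); nc <- ceiling(w / S)
  vine <- matrix(0, nr, nc); npix <- matrix(0, nr, nc)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    ti <- ((i - 1) %/% S) + 1; tj <- ((j - 1) %/% S) + 1
    npix[ti, tj] <- npix[ti, tj] + 1
    vine[ti, tj] <- vine[ti, tj] + mask[i, j]
  }
  vine / npix
}

# independent oracle: IoU via set arithmetic on coordinate lists
naive_iou <- function(P, Q) {
  keys <- function(M) {
    ij <- which(M == 1L, arr.ind = TRUE)
    paste(ij[, 1], ij[, 2])
  }
  p <- keys(P); q <- keys(Q)
  u <- union(p, q)
  if (length(u) == 0L) return(1.0)
  length(intersect(p, q)) / length(u)
}
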