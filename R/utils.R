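# internal validation and RNG helpers

pldm_stop <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "pldm_error")))
}

#' @noRd
assert_mask <- function(mask, arg = "mask") {
  if (!is.matrix(mask) || length(mask) == 0L)
    pldm_stop(arg, " must be a nonempty matrix", class = "pldm_validation_error")
  if (anyNA(mask) || !all(mask == 0L | mask == 1L))
    pldm_stop(arg, " must contain only 0/1 values", class = "pldm_validation_error")
  invisible(mask)
}

assert_same_dim <- function(a, b, what = c("pred", "truth")) {
  if (!identical(dim(a)[1:2], dim(b)[1:2]))
    pldm_stop(what[1], " and ", what[2], " dimensions differ: ",
              paste(dim(a)[1:2], collapse = "x"), " vs ",
              paste(dim(b)[1:2], collapse = "x"),
              class = "pldm_validation_error")
  invisible(TRUE)
}

assert_count <- function(x, arg, min = 1L) {
  if (length(x) != 1L || is.na(x) || x < min || x != as.integer(x))
    pldm_stop(arg, " must be a single integer >= ", min,
              class = "pldm_validation_error")
  as.integer(x)
}

assert_rgb <- function(image, arg = "image") {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L)
    pldm_stop(arg, " must be an H x W x 3 RGB array",
              class = "pldm_validation_error")
  invisible(image)
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

# Deterministic sub-seed for unit `id` of a master seed: edits to one part
# of a configuration leave other units' random streams unchanged.
derive_seed <- function(seed, id) {
  as.integer((as.double(seed) * 1000003 + as.double(id) * 7919) %% 2147483647)
}

# disc-shaped dilation; radius 0 is the identity
dilate_disc <- function(mask, radius_px) {
  if (radius_px == 0L || !any(mask == 1L)) return(mask)
  brush <- EBImage::makeBrush(2L * as.integer(radius_px) + 1L, shape = "disc")
  out <- EBImage::dilate(mask, brush)
  storage.mode(out) <- "integer"
  out
}
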