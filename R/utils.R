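# Internal helpers shared across modules.
#
# Raster convention used throughout the package: pixels are addressed
# (row, col), origin at the top-left corner, 0-based in every exported
# value; boxes are half-open, c(r0, c0, r1, c1), so a box covers rows
# r0 .. r1 - 1 and columns c0 .. c1 - 1. Internally R matrices are
# 1-based; the two helpers below do the conversion in one place.

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' @keywords internal
box_new <- function(r0, c0, r1, c1) {
  stopifnot(r1 >= r0, c1 >= c0)
  c(r0 = unname(r0), c0 = unname(c0), r1 = unname(r1), c1 = unname(c1))
}

# Crop a matrix or H x W x C array to a half-open 0-based box.
box_crop <- function(x, box) {
  ri <- (box[["r0"]] + 1):box[["r1"]]
  ci <- (box[["c0"]] + 1):box[["c1"]]
  if (length(dim(x)) == 3L) x[ri, ci, , drop = FALSE] else x[ri, ci, drop = FALSE]
}

# Paste values into a matrix at a box position (in place semantics via return).
box_paste <- function(canvas, patch, box) {
  ri <- (box[["r0"]] + 1):box[["r1"]]
  ci <- (box[["c0"]] + 1):box[["c1"]]
  canvas[ri, ci] <- patch
  canvas
}

# Bounding box (0-based half-open) of TRUE pixels of a logical matrix,
# or NULL when empty.
mask_bbox <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(NULL)
  box_new(min(idx[, 1]) - 1L, min(idx[, 2]) - 1L, max(idx[, 1]), max(idx[, 2]))
}

# Area of the union of two cropped masks positioned by their boxes on a
# common (implicit) canvas. Used by damage merging; brute-force oracle in
# the tests recomputes this on an explicit canvas.
mask_union_count <- function(mask_a, box_a, mask_b, box_b) {
  na <- sum(mask_a)
  nb <- sum(mask_b)
  r0 <- max(box_a[["r0"]], box_b[["r0"]])
  c0 <- max(box_a[["c0"]], box_b[["c0"]])
  r1 <- min(box_a[["r1"]], box_b[["r1"]])
  c1 <- min(box_a[["c1"]], box_b[["c1"]])
  inter <- 0L
  if (r1 > r0 && c1 > c0) {
    sub_a <- mask_a[(r0 - box_a[["r0"]] + 1):(r1 - box_a[["r0"]]),
                    (c0 - box_a[["c0"]] + 1):(c1 - box_a[["c0"]]), drop = FALSE]
    sub_b <- mask_b[(r0 - box_b[["r0"]] + 1):(r1 - box_b[["r0"]]),
                    (c0 - box_b[["c0"]] + 1):(c1 - box_b[["c0"]]), drop = FALSE]
    inter <- sum(sub_a & sub_b)
  }
  na + nb - inter
}

# Rec. 709 luma of an H x W x 3 array in [0, 1].
luminance <- function(px) {
  0.2126 * px[, , 1] + 0.7152 * px[, , 2] + 0.0722 * px[, , 3]
}

# Run code with a fixed RNG state, restoring the caller's state afterwards
# so seeded generators never disturb the session RNG.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Gaussian blur that tolerates sigma smaller than EBImage's minimum support.
blur2 <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  r <- max(ceiling(3 * sigma), 2)
  r <- min(r, (min(dim(mat)) - 1L) %/% 2L)   # kernel must fit the image
  if (r < 1) return(mat)
  as.matrix(EBImage::gblur(EBImage::Image(mat), sigma = sigma, radius = 2L * r + 1L))
}

# Background-normalised blur inside a mask: blur(x * m) / blur(m).
masked_blur <- function(mat, mask, sigma) {
  m <- mask * 1
  num <- blur2(mat * m, sigma)
  den <- blur2(m, sigma)
  out <- num / pmax(den, 1e-8)
  out[!mask] <- 0
  out
}

# Odd-sized disc brush with radius given in pixels (>= 1).
disc_brush <- function(radius_px) {
  size <- 2L * max(1L, as.integer(round(radius_px))) + 1L
  EBImage::makeBrush(size, shape = "disc")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
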