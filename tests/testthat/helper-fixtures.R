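# Shared fixtures: small plants are generated once per test run and the
# heavyweight benchmark is memoised so several test files can share it.

fixture_env <- new.env(parent = emptyenv())

fixture_plant <- function(key = "default", ...) {
  if (is.null(fixture_env[[key]])) {
    fixture_env[[key]] <- generate_plant(plant_spec(...))
  }
  fixture_env[[key]]
}

# a minimal uncompressed 2x2 RGB TIFF with X/YResolution tags, written
# byte-wise (the installed TIFF writer cannot emit resolution tags, so
# the reader's tag support is tested against a hand-built file)
write_tiff_with_resolution <- function(path, dpi = 8500) {
  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  entry <- function(tag, type, count, value) { w2(tag); w2(type); w4(count); w4(value) }

  writeBin(charToRaw("II"), con); w2(42L); w4(20L)          # header, IFD at 20
  writeBin(as.raw(rep(c(10, 200, 30), 4)), con)             # 2x2 RGB pixels at 8
  n_entries <- 13L
  w2(n_entries)
  extra0 <- 20L + 2L + n_entries * 12L + 4L                 # after IFD
  entry(256L, 3L, 1L, 2L)          # width
  entry(257L, 3L, 1L, 2L)          # height
  entry(258L, 3L, 3L, extra0)      # bits per sample -> offset
  entry(259L, 3L, 1L, 1L)          # no compression
  entry(262L, 3L, 1L, 2L)          # RGB
  entry(273L, 4L, 1L, 8L)          # strip offset
  entry(277L, 3L, 1L, 3L)          # samples per pixel
  entry(278L, 3L, 1L, 2L)          # rows per strip
  entry(279L, 4L, 1L, 12L)         # strip byte count
  entry(282L, 5L, 1L, extra0 + 6L) # XResolution rational
  entry(283L, 5L, 1L, extra0 + 14L)
  entry(284L, 3L, 1L, 1L)          # contiguous planes
  entry(296L, 3L, 1L, 2L)          # unit: inch
  w4(0L)                           # no next IFD
  w2(c(8L, 8L, 8L))                # bits per sample values
  w4(c(dpi, 1L))                   # XResolution = dpi / 1
  w4(c(dpi, 1L))
  invisible(path)
}

# brute-force mask area of a union placed on an explicit canvas: the
# independent oracle for merge_damage / mask_union_count
union_area_oracle <- function(mask_a, box_a, mask_b, box_b) {
  H <- max(box_a[["r1"]], box_b[["r1"]]) + 2
  W <- max(box_a[["c1"]], box_b[["c1"]]) + 2
  canvas <- matrix(FALSE, H, W)
  put <- function(canvas, mask, box) {
    for (r in seq_len(nrow(mask))) for (cc in seq_len(ncol(mask))) {
      if (mask[r, cc]) canvas[box[["r0"]] + r, box[["c0"]] + cc] <- TRUE
    }
    canvas
  }
  canvas <- put(canvas, mask_a, box_a)
  canvas <- put(canvas, mask_b, box_b)
  sum(canvas)
}

random_mask <- function(h, w, p = 0.3) matrix(stats::runif(h * w) < p, h, w)

random_box <- function(h, w, max_off = 6) {
  r0 <- sample.int(max_off, 1) - 1L
  c0 <- sample.int(max_off, 1) - 1L
  c(r0 = r0, c0 = c0, r1 = r0 + h, c1 = c0 + w)
}
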