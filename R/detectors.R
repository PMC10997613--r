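# Object detectors and the damage segmenter.
#
# The classical backend is fully deterministic: eggs are found as bright
# band-pass blobs at the egg scale, black feces as dark blobs against a
# local luminance background, damage as loss of green chroma. Each
# detector converts its filter response into a [0, 1] confidence via a
# fixed reference contrast so that user-facing significance levels have
# the same cutoff semantics as a learned model's scores.

# shape statistics of one labelled component
component_stats <- function(labm, k, um_per_px) {
  idx <- which(labm == k, arr.ind = TRUE)
  area <- nrow(idx)
  eq_d_um <- 2 * sqrt(area / pi) * um_per_px
  lab1 <- EBImage::Image((labm == k) * 1)
  sh <- EBImage::computeFeatures.shape(lab1)
  per <- sh[1, "s.perimeter"]
  circ <- if (per > 0) min(1, 4 * pi * area / per^2) else 1
  list(idx = idx, area_px = area, eq_d_um = eq_d_um, circularity = circ)
}

# embed a region's cropped mask into a padded window of the full image;
# returns the window rows/cols (1-based) and the mask on that window
region_window <- function(region, pad_px, dim_full) {
  b <- region$bbox
  r0 <- max(1L, b[["r0"]] + 1L - pad_px); r1 <- min(dim_full[1], b[["r1"]] + pad_px)
  c0 <- max(1L, b[["c0"]] + 1L - pad_px); c1 <- min(dim_full[2], b[["c1"]] + pad_px)
  mask <- matrix(FALSE, r1 - r0 + 1L, c1 - c0 + 1L)
  mask[(b[["r0"]] + 1L - r0 + 1L):(b[["r1"]] - r0 + 1L),
       (b[["c0"]] + 1L - c0 + 1L):(b[["c1"]] - c0 + 1L)] <- region$mask
  list(ri = r0:r1, ci = c0:c1, mask = mask)
}

empty_detections <- function() {
  tibble::tibble(id = character(0), klass = character(0), side = character(0),
                 leaf_index = integer(0), row = numeric(0), col = numeric(0),
                 r0 = integer(0), c0 = integer(0), r1 = integer(0), c1 = integer(0),
                 confidence = numeric(0), area_mm2 = numeric(0), source = character(0))
}

detection_row <- function(klass, side, leaf_index, ctr, box, confidence,
                          area_mm2 = NA_real_, source = "auto") {
  tibble::tibble(
    id = sprintf("%s_%s_L%d_r%dc%d", substr(klass, 1, 3), substr(side, 1, 2),
                 leaf_index, as.integer(ctr[1]), as.integer(ctr[2])),
    klass = klass, side = side, leaf_index = as.integer(leaf_index),
    row = ctr[1], col = ctr[2],
    r0 = as.integer(box[["r0"]]), c0 = as.integer(box[["c0"]]),
    r1 = as.integer(box[["r1"]]), c1 = as.integer(box[["c1"]]),
    confidence = confidence, area_mm2 = area_mm2, source = source)
}

#' Detect spider-mite eggs on one leaf
#'
#' Classical backend: a brightness + redness channel (eggs are pale to
#' orange, glossy, and brighter than the blade) is band-pass filtered
#' with a difference of Gaussians at the egg radius; hysteresis-
#' thresholded response components become candidates, kept when their
#' equivalent diameter lies within the egg size gate (70-200 um) and
#' their circularity (4*pi*A/P^2) is at least 0.6. On the adaxial side,
#' air-bubble candidates are rejected by their inverted polarity (dark
#' core, bright rim) and candidates with support outside the leaf mask
#' are dropped. The peak response is mapped to a [0, 1] confidence;
#' only candidates at or above `levels$eggs` are returned.
#'
#' @param scan a `scan_image`.
#' @param region the `leaf_region` to analyse (mask must be non-empty).
#' @param levels a [significance_levels()] object.
#' @param backend `"classical"` or a trained backend from
#'   [train_patch_model()].
#' @param config an [ms_config()] list.
#' @return a detections tibble (one row per object): class, side,
#'   leaf index, centre, half-open box, confidence.
#' @export
detect_eggs <- function(scan, region, levels = significance_levels(),
                        backend = "classical", config = ms_config()) {
  check_detector_inputs(scan, region)
  um <- scan$um_per_px
  cfg <- config$eggs
  r_px <- (cfg$typical_diameter_um / 2) / um
  win <- region_window(region, pad_px = as.integer(ceiling(3 * r_px)), dim(scan$pixels))
  px <- scan$pixels[win$ri, win$ci, , drop = FALSE]

  if (inherits(backend, "patch_model")) {
    prob <- predict_pixels(backend, px)
    prob[!win$mask] <- 0
    return(blob_detections_from_prob(prob, win, region, scan, "egg", levels$eggs,
                                     cfg$size_gate_um, cfg$min_circularity, um))
  }

  ch <- luminance(px) + 0.5 * pmax(px[, , 1] - px[, , 2], 0)
  med <- stats::median(ch[win$mask])
  chm <- ch
  chm[!win$mask] <- med
  s1 <- r_px / sqrt(2)
  fine0 <- blur2(chm, 0.8) - blur2(chm, 1.6)
  # band-pass at the egg scale, plus the smoothed specular-glint energy:
  # on chlorotic tissue the glossy highlight is the surviving egg signal
  resp <- blur2(chm, s1) - blur2(chm, 1.6 * s1) + 0.5 * blur2(pmax(fine0, 0), s1)

  t_hi <- cfg$floor_contrast
  t_lo <- 0.5 * t_hi
  cand <- resp > t_lo
  if (!any(cand)) return(empty_detections())
  # watershed on the response splits eggs merged by the low threshold
  resp_c <- resp
  resp_c[!cand] <- 0
  labm <- as.matrix(EBImage::imageData(
    EBImage::watershed(EBImage::Image(resp_c), tolerance = 0.5 * t_hi, ext = 2L)))

  chroma <- pmax(px[, , 1], px[, , 2]) - px[, , 3]
  fine <- fine0   # trichome-scale band-pass
  d <- dim(resp)
  out <- list()
  for (k in seq_len(max(labm))) {
    idx0 <- which(labm == k, arr.ind = TRUE)
    peak <- max(resp[idx0])
    if (peak < t_hi) next
    # the egg proper is the half-peak support; the low threshold only
    # delimits the watershed basin
    refined <- matrix(FALSE, nrow(labm), ncol(labm))
    refined[idx0[resp[idx0] >= 0.5 * peak, , drop = FALSE]] <- TRUE
    st <- component_stats(refined, TRUE, um)
    if (st$eq_d_um < cfg$size_gate_um[1] || st$eq_d_um > cfg$size_gate_um[2]) next
    if (st$circularity < cfg$min_circularity) next
    inside <- win$mask[st$idx]
    if (mean(inside) < 0.7) next
    pk <- st$idx[which.max(resp[st$idx]), ]
    if (!win$mask[pk[1], pk[2]]) next
    # eggs are chromatic (pale green to orange); white guanine streaks,
    # trichome glints and tape bubbles are not
    nb_r <- max(1, pk[1] - 1):min(d[1], pk[1] + 1)
    nb_c <- max(1, pk[2] - 1):min(d[2], pk[2] + 1)
    if (mean(chroma[nb_r, nb_c]) < cfg$min_chroma) next
    # eggs are smooth at the trichome scale; glint clusters are not
    fr_r <- max(1, pk[1] - 2):min(d[1], pk[1] + 2)
    fr_c <- max(1, pk[2] - 2):min(d[2], pk[2] + 2)
    if (max(abs(fine[fr_r, fr_c])) > cfg$max_fine_ratio * peak) next
    # eggs are radially symmetric; guanine streaks are strongly oriented
    if (orientation_coherence(chm, pk, as.integer(ceiling(r_px))) > cfg$max_coherence) next
    # and they match a smooth disc profile, unlike trichome glint clusters
    if (template_ncc(chm, pk, r_px) < cfg$min_template_ncc) next
    # a true blob is isolated in the band-pass response; boundary arcs of
    # large bright regions keep high response along the boundary direction
    if (ring_max(resp, pk, 2.6 * s1) > 0.55 * peak) next
    if (isTRUE(cfg$bubble_rejection) && identical(scan$side, "adaxial")) {
      if (core_vs_rim(ch, pk, r_px) < 0) next   # dark core = bubble
    }
    conf <- clamp((peak - cfg$floor_contrast) /
                    (cfg$ref_contrast - cfg$floor_contrast), 0, 1)
    if (conf < levels$eggs) next
    ctr <- c(win$ri[1] - 1L + pk[1] - 1L, win$ci[1] - 1L + pk[2] - 1L)
    half <- st$eq_d_um / 2 / um
    box <- box_new(floor(ctr[1] - half), floor(ctr[2] - half),
                   ceiling(ctr[1] + half) + 1, ceiling(ctr[2] + half) + 1)
    out[[length(out) + 1L]] <- detection_row("egg", scan$side %||% region$side,
                                             region$leaf_index, ctr, box, conf)
  }
  if (length(out)) dplyr::bind_rows(out) else empty_detections()
}

# normalised cross-correlation of a window with a Gaussian disc template
# at the egg scale: high for smooth round blobs, low for glint clusters
template_ncc <- function(map, pk, r_px) {
  d <- dim(map)
  w <- as.integer(ceiling(1.6 * r_px))
  ri <- max(1, pk[1] - w):min(d[1], pk[1] + w)
  ci <- max(1, pk[2] - w):min(d[2], pk[2] + w)
  sub <- map[ri, ci]
  dist2 <- outer((ri - pk[1])^2, (ci - pk[2])^2, "+")
  tmpl <- exp(-dist2 / (2 * (r_px / 1.3)^2))
  sv <- as.vector(sub) - mean(sub)
  tv <- as.vector(tmpl) - mean(tmpl)
  den <- sqrt(sum(sv^2) * sum(tv^2))
  if (den < 1e-12) return(0)
  sum(sv * tv) / den
}

# gradient-orientation coherence in a window around a peak: ~0 for an
# isotropic blob (radially symmetric gradients), ~1 for an oriented streak
orientation_coherence <- function(map, pk, radius) {
  d <- dim(map)
  ri <- max(2, pk[1] - radius):min(d[1] - 1, pk[1] + radius)
  ci <- max(2, pk[2] - radius):min(d[2] - 1, pk[2] + radius)
  gx <- map[ri, ci + 1] - map[ri, ci - 1]
  gy <- map[ri + 1, ci] - map[ri - 1, ci]
  jxx <- sum(gx * gx); jyy <- sum(gy * gy); jxy <- sum(gx * gy)
  den <- jxx + jyy
  if (den < 1e-12) return(0)
  sqrt((jxx - jyy)^2 + 4 * jxy^2) / den
}

# maximum of a map sampled on a ring of given radius around a peak
ring_max <- function(map, pk, radius) {
  d <- dim(map)
  ang <- seq(0, 2 * pi, length.out = 17)[-17]
  rr <- clamp(as.integer(round(pk[1] + radius * sin(ang))), 1L, d[1])
  cc <- clamp(as.integer(round(pk[2] + radius * cos(ang))), 1L, d[2])
  max(map[cbind(rr, cc)])
}

# mean channel value in the core (r < 0.5 r_px) minus an annulus at ~1.6 r_px
core_vs_rim <- function(ch, pk, r_px) {
  d <- dim(ch)
  rr <- as.integer(round(1.9 * r_px))
  ri <- max(1, pk[1] - rr):min(d[1], pk[1] + rr)
  ci <- max(1, pk[2] - rr):min(d[2], pk[2] + rr)
  sub <- ch[ri, ci, drop = FALSE]
  dist <- sqrt(outer((ri - pk[1])^2, (ci - pk[2])^2, "+"))
  core <- sub[dist <= max(1, 0.5 * r_px)]
  rim <- sub[dist >= 1.2 * r_px & dist <= 1.9 * r_px]
  if (!length(core) || !length(rim)) return(0)
  mean(core) - mean(rim)
}

#' Detect black fecal pellets on one leaf
#'
#' Classical backend: a darkness map (local background luminance minus
#' pixel luminance, the background estimated by a heavy masked blur
#' within the leaf) is thresholded; connected components with an
#' equivalent diameter in the feces size gate (40-250 um) become
#' detections. Confidence is the core darkness contrast normalised by a
#' reference contrast; per-object areas are reported in mm^2.
#'
#' @inheritParams detect_eggs
#' @return a detections tibble with `area_mm2` filled in.
#' @export
detect_feces <- function(scan, region, levels = significance_levels(),
                         backend = "classical", config = ms_config()) {
  check_detector_inputs(scan, region)
  um <- scan$um_per_px
  cfg <- config$feces
  win <- region_window(region, pad_px = 8L, dim(scan$pixels))
  px <- scan$pixels[win$ri, win$ci, , drop = FALSE]

  if (inherits(backend, "patch_model")) {
    prob <- predict_pixels(backend, px)
    prob[!win$mask] <- 0
    return(blob_detections_from_prob(prob, win, region, scan, "black_feces",
                                     levels$black_feces, cfg$size_gate_um, 0, um))
  }

  lum <- luminance(px)
  bg <- masked_blur(lum, win$mask, cfg$background_sigma_um / um)
  darkness <- (bg - lum)
  darkness[!win$mask] <- 0

  cand <- darkness > cfg$min_contrast
  if (!any(cand)) return(empty_detections())
  labm <- as.matrix(EBImage::imageData(EBImage::bwlabel(EBImage::Image(cand * 1))))

  out <- list()
  for (k in seq_len(max(labm))) {
    idx0 <- which(labm == k, arr.ind = TRUE)
    vals0 <- darkness[idx0]
    # the low threshold catches a blur halo; the pellet proper is the
    # half-peak support, which also carries the physical area
    hi <- stats::quantile(vals0, 0.9)
    idx <- idx0[vals0 >= 0.5 * hi, , drop = FALSE]
    area_px <- nrow(idx)
    eq_d_um <- 2 * sqrt(area_px / pi) * um
    if (eq_d_um < cfg$size_gate_um[1] || eq_d_um > cfg$size_gate_um[2]) next
    vals <- darkness[idx]
    core <- mean(vals[vals >= stats::median(vals)])   # core contrast
    conf <- clamp(core / cfg$ref_contrast, 0, 1)
    if (conf < levels$black_feces) next
    ctr_rc <- colMeans(idx) + c(win$ri[1], win$ci[1]) - 2
    box <- box_new(win$ri[1] - 1L + min(idx[, 1]) - 1L,
                   win$ci[1] - 1L + min(idx[, 2]) - 1L,
                   win$ri[1] - 1L + max(idx[, 1]),
                   win$ci[1] - 1L + max(idx[, 2]))
    out[[length(out) + 1L]] <- detection_row(
      "black_feces", scan$side %||% region$side, region$leaf_index,
      ctr_rc, box, conf, area_mm2 = area_px * (um / 1000)^2)
  }
  if (length(out)) dplyr::bind_rows(out) else empty_detections()
}

#' Segment chlorotic feeding damage on one leaf
#'
#' Per-pixel chlorosis score: yellowness ((R+G)/2 - B) plus half the
#' brightness deviation, both relative to the leaf's median colour.
#' The threshold is fixed (damage has no user-adjustable significance
#' level); a morphological opening at the 100 um scale removes
#' egg/pellet-sized false positives, and the mask is clipped to the
#' leaf mask.
#'
#' @inheritParams detect_eggs
#' @return a `damage_mask`: `mask` (cropped to the leaf bbox), `bbox`,
#'   `area_mm2`, `leaf_index`, `side`.
#' @export
segment_damage <- function(scan, region, backend = "classical", config = ms_config()) {
  check_detector_inputs(scan, region)
  um <- scan$um_per_px
  b <- region$bbox
  px <- box_crop(scan$pixels, b)
  mask <- region$mask

  if (inherits(backend, "patch_model")) {
    dmg <- predict_pixels(backend, px) >= backend$threshold
  } else {
    yel <- (px[, , 1] + px[, , 2]) / 2 - px[, , 3]
    lum <- luminance(px)
    score <- (yel - stats::median(yel[mask])) + 0.5 * (lum - stats::median(lum[mask]))
    dmg <- score > config$damage$threshold
  }
  dmg <- dmg & mask
  if (any(dmg)) {
    brush <- disc_brush(config$damage$opening_radius_um / um)
    dmg <- as.matrix(EBImage::imageData(EBImage::opening(EBImage::Image(dmg * 1), brush))) > 0.5
    dmg <- dmg & mask
  }
  structure(list(leaf_index = region$leaf_index, side = scan$side %||% region$side,
                 mask = dmg, bbox = b, area_mm2 = sum(dmg) * (um / 1000)^2,
                 um_per_px = um),
            class = "damage_mask")
}

check_detector_inputs <- function(scan, region) {
  stopifnot(inherits(scan, "scan_image"), inherits(region, "leaf_region"))
  if (is.null(scan$um_per_px) || !is.finite(scan$um_per_px))
    stop("scan has no physical scale (um_per_px)", call. = FALSE)
  if (!any(region$mask)) stop("leaf mask is empty", call. = FALSE)
}

# shared component labelling for trained (probability-map) backends
blob_detections_from_prob <- function(prob, win, region, scan, klass, level,
                                      size_gate_um, min_circ, um) {
  cand <- prob >= 0.5
  if (!any(cand)) return(empty_detections())
  labm <- as.matrix(EBImage::imageData(EBImage::bwlabel(EBImage::Image(cand * 1))))
  out <- list()
  for (k in seq_len(max(labm))) {
    st <- component_stats(labm, k, um)
    if (st$eq_d_um < size_gate_um[1] || st$eq_d_um > size_gate_um[2]) next
    if (st$circularity < min_circ) next
    conf <- mean(prob[st$idx])
    if (conf < level) next
    ctr_rc <- colMeans(st$idx) + c(win$ri[1], win$ci[1]) - 2
    box <- box_new(win$ri[1] - 1L + min(st$idx[, 1]) - 1L,
                   win$ci[1] - 1L + min(st$idx[, 2]) - 1L,
                   win$ri[1] - 1L + max(st$idx[, 1]),
                   win$ci[1] - 1L + max(st$idx[, 2]))
    area <- if (klass == "black_feces") st$area_px * (um / 1000)^2 else NA_real_
    out[[length(out) + 1L]] <- detection_row(klass, scan$side %||% region$side,
                                             region$leaf_index, ctr_rc, box, conf,
                                             area_mm2 = area)
  }
  if (length(out)) dplyr::bind_rows(out) else empty_detections()
}
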