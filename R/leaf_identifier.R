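#' Segment individual leaves from a plate scan
#'
#' Leaves are green, non-touching objects on the bright tape background.
#' Separation uses the excess-green index (2G - R - B) with an Otsu
#' threshold, followed by morphological closing (disc, ~150 um) and hole
#' filling, so that chlorotic damage, eggs and feces inside a blade stay
#' part of the leaf mask. Connected components whose major-axis length
#' falls below `min_leaf_length_mm` (debris, fragments) are discarded;
#' the mounting protocol only uses leaves of at least 4 mm.
#'
#' @param scan a `scan_image`.
#' @param min_leaf_length_mm minimum major-axis length to keep, mm.
#' @param config an [ms_config()] list.
#' @return list of `leaf_region` objects (unordered; see
#'   [order_leaves()]): each has `mask` (cropped), `bbox` (half-open,
#'   0-based), `centroid` (row, col), `area_mm2`, `side`, `um_per_px`,
#'   `dim` and a `leaf_index` of `NA` until ordered.
#' @export
segment_leaves <- function(scan, min_leaf_length_mm = NULL, config = ms_config()) {
  stopifnot(inherits(scan, "scan_image"))
  min_len <- min_leaf_length_mm %||% config$leaf$min_leaf_length_mm
  um <- scan$um_per_px
  px <- scan$pixels
  exg <- 2 * px[, , 2] - px[, , 1] - px[, , 3]
  exg01 <- clamp((exg + 2) / 4, 0, 1)
  th <- EBImage::otsu(EBImage::Image(exg01), range = c(0, 1))
  # absolute floor: on a leaf-free plate Otsu only splits sensor noise
  th <- max(th, (config$leaf$min_excess_green + 2) / 4)
  fg <- exg01 > th

  brush <- disc_brush(config$leaf$closing_radius_um / um)
  fg <- EBImage::closing(EBImage::Image(fg * 1), brush)
  fg <- EBImage::fillHull(fg)
  lab <- EBImage::bwlabel(fg)
  labm <- as.matrix(EBImage::imageData(lab))
  nlab <- max(labm)
  if (nlab == 0) {
    warning("no leaves found on the plate", call. = FALSE)
    return(list())
  }

  regions <- list()
  for (k in seq_len(nlab)) {
    idx <- which(labm == k, arr.ind = TRUE)
    # length = pixel extent along the first principal axis
    ctr <- colMeans(idx)
    cen <- sweep(idx, 2, ctr)
    v1 <- eigen(stats::cov(cen), symmetric = TRUE)$vectors[, 1]
    proj <- cen %*% v1
    major_mm <- (max(proj) - min(proj) + 1) * um / 1000
    if (major_mm < min_len) next
    bbox <- box_new(min(idx[, 1]) - 1L, min(idx[, 2]) - 1L,
                    max(idx[, 1]), max(idx[, 2]))
    mask <- labm[bbox[["r0"]]:(bbox[["r1"]] - 1L) + 1L,
                 bbox[["c0"]]:(bbox[["c1"]] - 1L) + 1L, drop = FALSE] == k
    regions[[length(regions) + 1L]] <- new_leaf_region(
      mask = mask, bbox = bbox, centroid = ctr - 1,
      area_mm2 = nrow(idx) * (um / 1000)^2, side = scan$side,
      um_per_px = um, dim = dim(px)[1:2])
  }
  if (!length(regions)) warning("no leaves found on the plate", call. = FALSE)
  regions
}

#' @keywords internal
new_leaf_region <- function(mask, bbox, centroid, area_mm2, side, um_per_px,
                            dim, leaf_index = NA_integer_) {
  structure(list(leaf_index = leaf_index, side = side, mask = mask,
                 bbox = bbox, centroid = centroid, area_mm2 = area_mm2,
                 um_per_px = um_per_px, dim = dim),
            class = "leaf_region")
}

#' Number leaf regions by the mounting convention
#'
#' Leaves are mounted youngest first, filling the upper row from the
#' left and continuing from the left of the lower row. Regions are split
#' into the two rows by 1-D 2-means on the centroid row coordinate
#' (collapsed to a single row when the between-row gap is smaller than
#' one mean leaf height), then numbered left-to-right within the top row
#' first. Index 0 is the youngest leaf. The assignment depends only on
#' centroid geometry, never on input order.
#'
#' @param regions list of `leaf_region`s from [segment_leaves()].
#' @return the regions, each with `leaf_index` set, sorted by index.
#' @export
order_leaves <- function(regions) {
  n <- length(regions)
  if (n == 0) return(regions)
  rows <- vapply(regions, function(r) r$centroid[1], numeric(1))
  cols <- vapply(regions, function(r) r$centroid[2], numeric(1))
  heights <- vapply(regions, function(r) r$bbox[["r1"]] - r$bbox[["r0"]], numeric(1))

  band <- rep(1L, n)
  if (n >= 2 && diff(range(rows)) > 1e-9) {
    # deterministic 1-D 2-means (Lloyd), initialised at the extremes
    c1 <- min(rows); c2 <- max(rows)
    cl <- rep(1L, n)
    for (it in 1:100) {
      cl_new <- ifelse(abs(rows - c1) <= abs(rows - c2), 1L, 2L)
      if (all(cl_new == cl) && it > 1) break
      cl <- cl_new
      if (any(cl == 1L)) c1 <- mean(rows[cl == 1L])
      if (any(cl == 2L)) c2 <- mean(rows[cl == 2L])
    }
    if (abs(c2 - c1) >= mean(heights)) band <- cl
  }
  ord <- order(band, cols, rows)
  for (i in seq_along(ord)) regions[[ord[i]]]$leaf_index <- i - 1L
  regions[ord]
}

region_iou <- function(a, b) {
  inter_union <- mask_union_count(a$mask, a$bbox, b$mask, b$bbox)
  inter <- sum(a$mask) + sum(b$mask) - inter_union
  if (inter_union == 0) return(0)
  inter / inter_union
}

mirror_region <- function(region, width_px) {
  region$mask <- region$mask[, ncol(region$mask):1, drop = FALSE]
  region$bbox <- mirror_box(region$bbox, width_px)
  region$centroid[2] <- width_px - 1 - region$centroid[2]
  region
}

#' Pair abaxial and adaxial views of each leaf
#'
#' The adaxial scan shows the plate turned over, i.e. mirrored; adaxial
#' masks are reflected about the vertical axis (or horizontal, per
#' `config$pairing$mirror_axis`) and each abaxial leaf is matched
#' greedily to the adaxial leaf of maximal mask IOU. Matching is
#' one-to-one; pairs under the IOU threshold (default 0.5) and leftover
#' leaves are flagged unpaired.
#'
#' @param abaxial,adaxial lists of ordered `leaf_region`s.
#' @param width_px plate width in pixels (for the mirror reflection).
#' @param config an [ms_config()] list.
#' @return a tibble with one row per abaxial leaf (plus rows for
#'   unmatched adaxial leaves): `abaxial_index`, `adaxial_index`, `iou`,
#'   `paired`.
#' @export
pair_sides <- function(abaxial, adaxial, width_px, config = ms_config()) {
  thr <- config$pairing$iou_threshold
  ad_m <- lapply(adaxial, function(r) {
    if (identical(config$pairing$mirror_axis, "horizontal")) {
      r$mask <- r$mask[nrow(r$mask):1, , drop = FALSE]
      h <- r$dim[1]
      r$bbox <- box_new(h - r$bbox[["r1"]], r$bbox[["c0"]], h - r$bbox[["r0"]], r$bbox[["c1"]])
      r$centroid[1] <- h - 1 - r$centroid[1]
      r
    } else mirror_region(r, width_px)
  })

  na_row <- function(ab, ad, iou) tibble::tibble(
    abaxial_index = ab, adaxial_index = ad, iou = iou,
    paired = !is.na(ab) & !is.na(ad) & iou >= thr)

  if (!length(abaxial) || !length(adaxial)) {
    out <- dplyr::bind_rows(
      lapply(abaxial, function(r) na_row(r$leaf_index, NA_integer_, NA_real_)),
      lapply(adaxial, function(r) na_row(NA_integer_, r$leaf_index, NA_real_)))
    return(out)
  }

  iou <- matrix(0, length(abaxial), length(adaxial))
  for (i in seq_along(abaxial)) for (j in seq_along(ad_m))
    iou[i, j] <- region_iou(abaxial[[i]], ad_m[[j]])

  pairs <- list()
  remaining_i <- seq_along(abaxial)
  remaining_j <- seq_along(adaxial)
  work <- iou
  while (length(remaining_i) && length(remaining_j)) {
    best <- which(work == max(work), arr.ind = TRUE)[1, ]
    if (work[best[1], best[2]] < thr) break
    i <- remaining_i[best[1]]; j <- remaining_j[best[2]]
    pairs[[length(pairs) + 1L]] <- na_row(abaxial[[i]]$leaf_index,
                                          adaxial[[j]]$leaf_index, iou[i, j])
    remaining_i <- setdiff(remaining_i, i)
    remaining_j <- setdiff(remaining_j, j)
    work <- iou[remaining_i, remaining_j, drop = FALSE]
    if (!length(work)) break
  }
  leftovers <- c(
    lapply(remaining_i, function(i) na_row(abaxial[[i]]$leaf_index, NA_integer_,
                                           if (length(adaxial)) max(iou[i, ]) else NA_real_)),
    lapply(remaining_j, function(j) na_row(NA_integer_, adaxial[[j]]$leaf_index, NA_real_)))
  dplyr::bind_rows(c(pairs, leftovers)) |> dplyr::arrange(.data$abaxial_index)
}
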