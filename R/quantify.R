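# Aggregation of detections and masks into per-leaf and per-plant results
# in physical units, including cross-side damage de-duplication.

#' Merge damage masks across the two leaf sides without double counting
#'
#' Feeding damage often shows through the blade, so the abaxial and
#' adaxial segmentations partly describe the same lesions; the merged
#' area is the area of the union, counted once. The adaxial mask is
#' first registered into the abaxial frame: mirrored about the plate's
#' vertical axis, translated so the leaf centroids coincide, and rotated
#' to align the leaf principal axes (a rigid registration — taped-down
#' leaves do not deform).
#'
#' @param damage_ab,damage_ad `damage_mask` objects from
#'   [segment_damage()]; either may be `NULL` (unpaired leaf), in which
#'   case the merged result equals the available side and is flagged.
#' @param region_ab,region_ad the corresponding `leaf_region`s; when
#'   omitted the two masks are assumed to live in the same frame already
#'   (identity registration).
#' @param width_px plate width in pixels, required for the mirror step.
#' @return list: `area_mm2`, `mask` + `bbox` (merged shape, abaxial
#'   frame), `flagged` (TRUE when one side was missing).
#' @export
merge_damage <- function(damage_ab, damage_ad, region_ab = NULL,
                         region_ad = NULL, width_px = NULL) {
  if (is.null(damage_ab) && is.null(damage_ad))
    return(list(area_mm2 = 0, mask = NULL, bbox = NULL, flagged = TRUE))
  if (is.null(damage_ad) || is.null(damage_ab)) {
    d <- damage_ab %||% damage_ad
    return(list(area_mm2 = d$area_mm2, mask = d$mask, bbox = d$bbox, flagged = TRUE))
  }
  px_area <- (damage_ab$um_per_px / 1000)^2

  mask_b <- damage_ad$mask
  bbox_b <- damage_ad$bbox
  if (!is.null(region_ab) && !is.null(region_ad)) {
    if (is.null(width_px)) stop("width_px needed to mirror the adaxial mask", call. = FALSE)
    reg <- register_adaxial(mask_b, bbox_b, region_ab, region_ad, width_px)
    mask_b <- reg$mask; bbox_b <- reg$bbox
  }

  if (!any(damage_ab$mask) && !any(mask_b))
    return(list(area_mm2 = 0, mask = damage_ab$mask, bbox = damage_ab$bbox, flagged = FALSE))

  r0 <- min(damage_ab$bbox[["r0"]], bbox_b[["r0"]])
  c0 <- min(damage_ab$bbox[["c0"]], bbox_b[["c0"]])
  r1 <- max(damage_ab$bbox[["r1"]], bbox_b[["r1"]])
  c1 <- max(damage_ab$bbox[["c1"]], bbox_b[["c1"]])
  canvas <- matrix(FALSE, r1 - r0, c1 - c0)
  place <- function(canvas, mask, bbox) {
    ri <- (bbox[["r0"]] - r0 + 1L):(bbox[["r1"]] - r0)
    ci <- (bbox[["c0"]] - c0 + 1L):(bbox[["c1"]] - c0)
    canvas[ri, ci] <- canvas[ri, ci] | mask
    canvas
  }
  canvas <- place(canvas, damage_ab$mask, damage_ab$bbox)
  canvas <- place(canvas, mask_b, bbox_b)
  list(area_mm2 = sum(canvas) * px_area, mask = canvas,
       bbox = box_new(r0, c0, r1, c1), flagged = FALSE)
}

# principal-axis angle of a leaf mask (radians, in [-pi/2, pi/2])
principal_angle <- function(region) {
  idx <- which(region$mask, arr.ind = TRUE)
  cen <- sweep(idx, 2, colMeans(idx))
  e <- eigen(stats::cov(cen), symmetric = TRUE)
  v <- e$vectors[, 1]
  atan2(v[2], v[1])
}

# mirror + translate + rotate an adaxial damage mask into the abaxial frame
register_adaxial <- function(mask, bbox, region_ab, region_ad, width_px) {
  # mirror about the vertical plate axis
  mask <- mask[, ncol(mask):1, drop = FALSE]
  bbox <- mirror_box(bbox, width_px)
  ad_centroid <- c(region_ad$centroid[1], width_px - 1 - region_ad$centroid[2])

  ang_ab <- principal_angle(region_ab)
  ad_mirrored <- mirror_region(region_ad, width_px)
  ang_ad <- principal_angle(ad_mirrored)
  dtheta <- ang_ab - ang_ad
  if (abs(dtheta) > pi / 2) dtheta <- dtheta - sign(dtheta) * pi

  if (any(mask) && abs(dtheta) > 0.005) {
    # rotate about the leaf centroid on a centred square canvas
    idx <- which(mask, arr.ind = TRUE)
    pts_r <- bbox[["r0"]] + idx[, 1] - 1 - ad_centroid[1]
    pts_c <- bbox[["c0"]] + idx[, 2] - 1 - ad_centroid[2]
    ext <- as.integer(ceiling(max(abs(c(pts_r, pts_c))))) + 2L
    canvas <- matrix(0, 2L * ext + 1L, 2L * ext + 1L)
    canvas[cbind(as.integer(round(pts_r)) + ext + 1L,
                 as.integer(round(pts_c)) + ext + 1L)] <- 1
    rot <- EBImage::rotate(EBImage::Image(canvas), -dtheta * 180 / pi,
                           output.dim = dim(canvas), output.origin = c(ext, ext))
    mask <- as.matrix(EBImage::imageData(rot)) > 0.5
    bbox <- box_new(as.integer(round(ad_centroid[1])) - ext,
                    as.integer(round(ad_centroid[2])) - ext,
                    as.integer(round(ad_centroid[1])) + ext + 1L,
                    as.integer(round(ad_centroid[2])) + ext + 1L)
  }

  # translate so the adaxial leaf centroid lands on the abaxial one
  shift <- round(region_ab$centroid - ad_centroid)
  bbox <- box_new(bbox[["r0"]] + shift[1], bbox[["c0"]] + shift[2],
                  bbox[["r1"]] + shift[1], bbox[["c1"]] + shift[2])
  list(mask = mask, bbox = bbox)
}

#' Quantify one paired leaf
#'
#' Counts and areas per side plus the merged damage area, in mm^2
#' (pixel area = (um_per_px / 1000)^2).
#'
#' @param region_ab,region_ad `leaf_region`s (either may be NULL for an
#'   unpaired leaf).
#' @param detections detections tibble covering this leaf (both sides).
#' @param damage_ab,damage_ad `damage_mask`es (may be NULL).
#' @param width_px plate width for registration.
#' @return one-row tibble (a LeafResult).
#' @export
quantify_leaf <- function(region_ab, region_ad, detections,
                          damage_ab = NULL, damage_ad = NULL, width_px = NULL) {
  if (is.null(region_ab) && is.null(region_ad)) stop("no leaf region given", call. = FALSE)
  leaf_index <- (region_ab %||% region_ad)$leaf_index
  um <- (region_ab %||% region_ad)$um_per_px
  if (is.null(um) || !is.finite(um)) stop("leaf region carries no scale", call. = FALSE)

  det <- detections[!is.na(detections$leaf_index) & detections$leaf_index == leaf_index, ]
  side_stats <- function(side) {
    d <- det[det$side == side, ]
    list(eggs = sum(d$klass == "egg"),
         feces = sum(d$klass == "black_feces"),
         feces_area = sum(d$area_mm2[d$klass == "black_feces"], na.rm = TRUE))
  }
  ab <- side_stats("abaxial"); ad <- side_stats("adaxial")
  merged <- merge_damage(damage_ab, damage_ad, region_ab, region_ad, width_px)

  tibble::tibble(
    leaf_index = leaf_index,
    leaf_area_abaxial_mm2 = if (!is.null(region_ab)) region_ab$area_mm2 else NA_real_,
    leaf_area_adaxial_mm2 = if (!is.null(region_ad)) region_ad$area_mm2 else NA_real_,
    damage_abaxial_mm2 = if (!is.null(damage_ab)) damage_ab$area_mm2 else 0,
    damage_adaxial_mm2 = if (!is.null(damage_ad)) damage_ad$area_mm2 else 0,
    merged_damage_mm2 = merged$area_mm2,
    eggs_abaxial = ab$eggs, eggs_adaxial = ad$eggs,
    feces_abaxial = ab$feces, feces_adaxial = ad$feces,
    feces_area_abaxial_mm2 = ab$feces_area, feces_area_adaxial_mm2 = ad$feces_area,
    paired = !merged$flagged)
}

#' Summarise a plant from its leaf results
#'
#' Totals over leaves plus the oviposition rate: eggs laid per female
#' over the whole infestation window (default 10 females, 72 h).
#' `additional_eggs` counts eggs shed off the leaves — visible on the
#' plate but not attributable to any leaf or side — and enters the total
#' egg count and the oviposition rate only.
#'
#' @param leaf_results tibble of rows from [quantify_leaf()], ordered by
#'   leaf index.
#' @param meta a `scan_meta` (or NULL).
#' @param detections the detections tibble backing the counts.
#' @param n_females females applied per plant (> 0).
#' @param additional_eggs off-leaf egg count (>= 0).
#' @param infestation_hours infestation window, hours (recorded only).
#' @return a `plant_result`.
#' @export
summarize_plant <- function(leaf_results, meta = NULL, detections = empty_detections(),
                            n_females = 10, additional_eggs = 0,
                            infestation_hours = 72) {
  if (n_females <= 0) stop("n_females must be > 0", call. = FALSE)
  if (additional_eggs < 0) stop("additional_eggs must be >= 0", call. = FALSE)
  lr <- leaf_results
  tot_eggs <- sum(lr$eggs_abaxial, lr$eggs_adaxial) + additional_eggs
  totals <- list(
    egg_count = tot_eggs,
    eggs_abaxial = sum(lr$eggs_abaxial), eggs_adaxial = sum(lr$eggs_adaxial),
    feces_count = sum(lr$feces_abaxial, lr$feces_adaxial),
    feces_area_mm2 = sum(lr$feces_area_abaxial_mm2, lr$feces_area_adaxial_mm2),
    feces_area_abaxial_mm2 = sum(lr$feces_area_abaxial_mm2),
    feces_area_adaxial_mm2 = sum(lr$feces_area_adaxial_mm2),
    damage_area_mm2 = sum(lr$merged_damage_mm2),
    damage_abaxial_mm2 = sum(lr$damage_abaxial_mm2),
    damage_adaxial_mm2 = sum(lr$damage_adaxial_mm2),
    leaf_area_mm2 = sum(lr$leaf_area_abaxial_mm2, na.rm = TRUE))
  structure(list(meta = meta, leaf_results = lr, detections = detections,
                 totals = totals, additional_eggs = additional_eggs,
                 n_females = n_females, infestation_hours = infestation_hours,
                 oviposition_rate = tot_eggs / n_females,
                 audit = list()),
            class = "plant_result")
}

#' @export
print.plant_result <- function(x, ...) {
  cat(sprintf("<plant_result> %s: %d leaves, %d eggs (%.1f eggs/female), %.2f mm2 damage, %.3f mm2 black feces\n",
              x$meta$raw_name %||% "unnamed", nrow(x$leaf_results),
              x$totals$egg_count, x$oviposition_rate,
              x$totals$damage_area_mm2, x$totals$feces_area_mm2))
  invisible(x)
}

#' A manual correction to the detected objects
#'
#' The file-based equivalent of clicking on the result view: removing a
#' misdiagnosed object by id, or adding a missed one by drawing its box.
#'
#' @param action `"add"` or `"remove"`.
#' @param klass `"egg"` or `"black_feces"`.
#' @param side leaf side.
#' @param leaf_index leaf ordinal.
#' @param box half-open 0-based box `c(r0, c0, r1, c1)` (for add).
#' @param id object id (for remove).
#' @return a `correction_edit` list.
#' @export
correction_edit <- function(action, klass = "egg", side = "abaxial",
                            leaf_index = 0L, box = NULL, id = NULL) {
  stopifnot(action %in% c("add", "remove"),
            klass %in% c("egg", "black_feces"),
            side %in% c("abaxial", "adaxial"))
  if (action == "add" && is.null(box)) stop("add edits need a box", call. = FALSE)
  if (action == "remove" && is.null(id)) stop("remove edits need an object id", call. = FALSE)
  structure(list(action = action, klass = klass, side = side,
                 leaf_index = as.integer(leaf_index), box = box, id = id),
            class = "correction_edit")
}

#' Apply manual corrections to a plant result
#'
#' Edits are applied in order; counts and areas are recomputed from the
#' updated detections, and every edit is appended to the result's audit
#' log. Removing an id that does not exist is an error naming the id.
#'
#' @param result a `plant_result`.
#' @param edits list of [correction_edit()]s.
#' @return the updated `plant_result`.
#' @export
apply_corrections <- function(result, edits) {
  stopifnot(inherits(result, "plant_result"))
  det <- result$detections
  for (e in edits) {
    stopifnot(inherits(e, "correction_edit"))
    if (e$action == "remove") {
      hit <- which(det$id == e$id)
      if (!length(hit)) stop(sprintf("no detected object with id '%s' to remove", e$id),
                             call. = FALSE)
      det <- det[-hit[1], ]
    } else {
      box <- e$box
      um <- attr(result$leaf_results, "um_per_px") %||% NA_real_
      area <- if (e$klass == "black_feces" && is.finite(um))
        (box[3] - box[1]) * (box[4] - box[2]) * (um / 1000)^2 else NA_real_
      ctr <- c((box[1] + box[3]) / 2, (box[2] + box[4]) / 2)
      row <- detection_row(e$klass, e$side, e$leaf_index, ctr,
                           box_new(box[1], box[2], box[3], box[4]),
                           confidence = 1, area_mm2 = area, source = "manual")
      # manual ids must be unique even for identical boxes
      row$id <- paste0(row$id, "_m", nrow(det) + length(result$audit) + 1L)
      det <- dplyr::bind_rows(det, row)
    }
    result$audit[[length(result$audit) + 1L]] <-
      c(unclass(e)[c("action", "klass", "side", "leaf_index", "id")],
        time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  }

  lr <- result$leaf_results
  for (i in seq_len(nrow(lr))) {
    li <- lr$leaf_index[i]
    d <- det[!is.na(det$leaf_index) & det$leaf_index == li, ]
    for (side in c("abaxial", "adaxial")) {
      ds <- d[d$side == side, ]
      pre <- if (side == "abaxial") "abaxial" else "adaxial"
      lr[[paste0("eggs_", pre)]][i] <- sum(ds$klass == "egg")
      lr[[paste0("feces_", pre)]][i] <- sum(ds$klass == "black_feces")
      lr[[paste0("feces_area_", pre, "_mm2")]][i] <-
        sum(ds$area_mm2[ds$klass == "black_feces"], na.rm = TRUE)
    }
  }
  out <- summarize_plant(lr, result$meta, det, result$n_females,
                         result$additional_eggs, result$infestation_hours)
  out$audit <- result$audit
  out
}

#' Write the audit log of manual corrections as JSONL
#' @param result a `plant_result`.
#' @param path output file (appended).
#' @export
write_audit_log <- function(result, path) {
  con <- file(path, open = "a")
  on.exit(close(con))
  for (e in result$audit)
    writeLines(jsonlite::toJSON(e, auto_unbox = TRUE), con)
  invisible(path)
}
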