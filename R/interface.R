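# End-to-end pipeline driver, CSV export in the assay's schema, and the
# file-based correction workflow.

#' Analyse one plant from its paired scans
#'
#' Runs the full chain on an abaxial/adaxial scan pair: leaf
#' segmentation, ordering, side pairing, egg and feces detection, damage
#' segmentation, cross-side damage merging and per-plant summary.
#'
#' @param abaxial,adaxial `scan_image`s of the two plate sides.
#' @param levels [significance_levels()].
#' @param backend `"classical"` or a `patch_model`.
#' @param config an [ms_config()] list.
#' @return a `plant_result`.
#' @export
analyze_plant <- function(abaxial, adaxial, levels = significance_levels(),
                          backend = "classical", config = ms_config()) {
  reg_ab <- order_leaves(segment_leaves(abaxial, config = config))
  reg_ad <- order_leaves(segment_leaves(adaxial, config = config))
  width_px <- dim(abaxial$pixels)[2]
  pairing <- pair_sides(reg_ab, reg_ad, width_px, config)

  n_found <- length(reg_ab)
  declared <- abaxial$meta$declared_leaf_count
  if (!is.null(declared) && !is.na(declared) && declared != n_found)
    warning(sprintf("found %d leaves but the filename declares %d", n_found, declared),
            call. = FALSE)

  by_index <- function(regions) {
    out <- list()
    for (r in regions) out[[as.character(r$leaf_index)]] <- r
    out
  }
  ab_ix <- by_index(reg_ab); ad_ix <- by_index(reg_ad)

  dets <- list(); leaf_rows <- list()
  for (r in seq_len(nrow(pairing))) {
    ia <- pairing$abaxial_index[r]; ja <- pairing$adaxial_index[r]
    region_ab <- if (!is.na(ia)) ab_ix[[as.character(ia)]] else NULL
    region_ad <- if (!is.na(ja)) ad_ix[[as.character(ja)]] else NULL
    if (!is.null(region_ad) && !is.null(region_ab))
      region_ad$leaf_index <- region_ab$leaf_index   # report under abaxial numbering

    d_ab <- d_ad <- NULL
    det_r <- empty_detections()
    if (!is.null(region_ab)) {
      det_r <- dplyr::bind_rows(det_r,
                                detect_eggs(abaxial, region_ab, levels, backend, config),
                                detect_feces(abaxial, region_ab, levels, backend, config))
      d_ab <- segment_damage(abaxial, region_ab, backend, config)
    }
    if (!is.null(region_ad)) {
      det_r <- dplyr::bind_rows(det_r,
                                detect_eggs(adaxial, region_ad, levels, backend, config),
                                detect_feces(adaxial, region_ad, levels, backend, config))
      d_ad <- segment_damage(adaxial, region_ad, backend, config)
    }
    dets[[length(dets) + 1L]] <- det_r
    leaf_rows[[length(leaf_rows) + 1L]] <-
      quantify_leaf(region_ab, region_ad, det_r, d_ab, d_ad, width_px)
  }
  detections <- dplyr::bind_rows(dets)
  leaf_results <- dplyr::bind_rows(leaf_rows) |> dplyr::arrange(.data$leaf_index)
  attr(leaf_results, "um_per_px") <- abaxial$um_per_px
  summarize_plant(leaf_results, abaxial$meta, detections)
}

#' Run the pipeline over a directory of scan pairs
#'
#' Scans are grouped into plants by their filename metadata (ecotype,
#' replicate, batch); each complete abaxial/adaxial pair is analysed and
#' written as a per-plant JSON result plus a cumulative CSV. Plants with
#' an existing result file are skipped unless `force`; unmatched scans
#' are listed and skipped; a corrupt image fails only its own plant.
#'
#' @param input a directory containing TIFF scans (or a character vector
#'   of paths).
#' @param out_dir output directory (created).
#' @param levels [significance_levels()].
#' @param backend `"classical"` or a `patch_model`.
#' @param force recompute plants with existing results.
#' @param config an [ms_config()] list.
#' @return invisibly, a list of `plant_result`s (named by plant key).
#' @export
run_pipeline <- function(input, out_dir = file.path(input, "results"),
                         levels = significance_levels(), backend = "classical",
                         force = FALSE, config = ms_config()) {
  paths <- if (length(input) == 1 && dir.exists(input))
    list.files(input, pattern = "\\.(tif|tiff)$", full.names = TRUE, ignore.case = TRUE)
  else input
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  metas <- lapply(paths, function(p)
    tryCatch(parse_scan_filename(basename(p), config), error = function(e) NULL))
  ok <- !vapply(metas, is.null, logical(1))
  for (p in paths[!ok]) message("skipping unparseable scan name: ", basename(p))
  paths <- paths[ok]; metas <- metas[ok]

  key <- vapply(metas, function(m)
    paste(m$ecotype_label, m$ecotype_index, m$replicate, m$batch, sep = "_"), "")
  results <- list()
  for (k in unique(key)) {
    grp <- which(key == k)
    sides <- vapply(metas[grp], function(m) m$side, "")
    if (!all(c("abaxial", "adaxial") %in% sides)) {
      message("skipping plant ", k, ": missing ",
              setdiff(c("abaxial", "adaxial"), sides), " scan")
      next
    }
    res_path <- file.path(out_dir, paste0(k, ".json"))
    if (file.exists(res_path) && !force) {
      message("plant ", k, " already analysed; skipping (use force = TRUE to redo)")
      next
    }
    res <- tryCatch({
      ab <- read_scan(paths[grp][sides == "abaxial"][1], config = config)
      ad <- read_scan(paths[grp][sides == "adaxial"][1], config = config)
      analyze_plant(ab, ad, levels, backend, config)
    }, error = function(e) {
      message("plant ", k, " failed: ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) next
    write_plant_json(res, res_path)
    results[[k]] <- res
  }
  if (length(results))
    export_csv(results, file.path(out_dir, "results.csv"))
  invisible(results)
}

#' @keywords internal
write_plant_json <- function(result, path) {
  out <- list(meta = unclass(result$meta),
              totals = result$totals,
              oviposition_rate = result$oviposition_rate,
              additional_eggs = result$additional_eggs,
              n_females = result$n_females,
              leaf_results = result$leaf_results,
              detections = result$detections)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Export plant results as the assay's CSV schema
#'
#' One row per leaf per side carrying leaf area, damage area, egg count
#' and black-feces count and area; plus one summary row per plant
#' (`leaf_side = "plant"`) adding the oviposition rate, off-leaf
#' additional eggs and the de-duplicated merged damage total. The file
#' is locale-independent: comma-delimited, period decimal separator,
#' UTF-8, full numeric precision.
#'
#' @param results a `plant_result` or list of them.
#' @param path output CSV path.
#' @return the tibble written, invisibly.
#' @export
export_csv <- function(results, path) {
  if (inherits(results, "plant_result")) results <- list(results)
  rows <- list()
  for (res in results) {
    meta <- res$meta
    eco <- if (!is.null(meta)) paste0(meta$ecotype_label, "-", meta$ecotype_index) else NA_character_
    plant_no <- if (!is.null(meta)) meta$replicate else NA_integer_
    lr <- res$leaf_results
    for (i in seq_len(nrow(lr))) {
      for (side in c("abaxial", "adaxial")) {
        s <- if (side == "abaxial") "abaxial" else "adaxial"
        rows[[length(rows) + 1L]] <- tibble::tibble(
          ecotype = eco, plant_number = plant_no,
          leaf_index = lr$leaf_index[i], leaf_side = side,
          leaf_area_mm2 = lr[[paste0("leaf_area_", s, "_mm2")]][i],
          damage_area_mm2 = lr[[paste0("damage_", s, "_mm2")]][i],
          egg_count = lr[[paste0("eggs_", s)]][i],
          feces_count = lr[[paste0("feces_", s)]][i],
          feces_area_mm2 = lr[[paste0("feces_area_", s, "_mm2")]][i],
          oviposition_rate = NA_real_, additional_eggs = NA_integer_,
          merged_damage_area_mm2 = NA_real_)
      }
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      ecotype = eco, plant_number = plant_no,
      leaf_index = NA_integer_, leaf_side = "plant",
      leaf_area_mm2 = res$totals$leaf_area_mm2,
      damage_area_mm2 = res$totals$damage_area_mm2,
      egg_count = res$totals$egg_count,
      feces_count = res$totals$feces_count,
      feces_area_mm2 = res$totals$feces_area_mm2,
      oviposition_rate = res$oviposition_rate,
      additional_eggs = res$additional_eggs,
      merged_damage_area_mm2 = res$totals$damage_area_mm2)
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else tibble::tibble(
    ecotype = character(0), plant_number = integer(0), leaf_index = integer(0),
    leaf_side = character(0), leaf_area_mm2 = numeric(0), damage_area_mm2 = numeric(0),
    egg_count = integer(0), feces_count = integer(0), feces_area_mm2 = numeric(0),
    oviposition_rate = numeric(0), additional_eggs = integer(0),
    merged_damage_area_mm2 = numeric(0))
  readr::write_csv(out, path)
  invisible(out)
}

#' @rdname export_csv
#' @export
read_results_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    ecotype = readr::col_character(),
    plant_number = readr::col_integer(),
    leaf_index = readr::col_integer(),
    leaf_side = readr::col_character(),
    leaf_area_mm2 = readr::col_double(),
    damage_area_mm2 = readr::col_double(),
    egg_count = readr::col_integer(),
    feces_count = readr::col_integer(),
    feces_area_mm2 = readr::col_double(),
    oviposition_rate = readr::col_double(),
    additional_eggs = readr::col_integer(),
    merged_damage_area_mm2 = readr::col_double()))
}

#' Read correction edits from a JSONL file
#'
#' Each line is one edit object with the fields of [correction_edit()];
#' the file-based replacement for interactive result correction.
#'
#' @param path JSONL file.
#' @return list of `correction_edit`s.
#' @export
read_corrections <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(ln) {
    e <- jsonlite::fromJSON(ln)
    correction_edit(action = e$action, klass = e$klass %||% "egg",
                    side = e$side %||% "abaxial",
                    leaf_index = e$leaf_index %||% 0L,
                    box = if (!is.null(e$box)) as.numeric(e$box) else NULL,
                    id = e$id)
  })
}

#' Build a plant-level trait table from pipeline results
#'
#' Collapses `plant_result`s to the one-row-per-plant table consumed by
#' the susceptibility statistics layer ([relative_values()],
#' [anova_cld()], [leaf_distribution()], [side_distribution()]).
#'
#' @param results list of `plant_result`s.
#' @return a tibble with plant-level totals, per-side totals and
#'   per-leaf trait vectors as list-columns.
#' @export
trait_table <- function(results) {
  rows <- lapply(results, function(res) {
    lr <- res$leaf_results
    tibble::tibble(
      ecotype = if (!is.null(res$meta)) res$meta$ecotype_label else NA_character_,
      batch = if (!is.null(res$meta)) res$meta$batch else "K1",
      replicate = if (!is.null(res$meta)) res$meta$replicate else NA_integer_,
      n_leaves = nrow(lr),
      damage_area_mm2 = res$totals$damage_area_mm2,
      oviposition_rate = res$oviposition_rate,
      egg_count = res$totals$egg_count,
      eggs_abaxial = res$totals$eggs_abaxial,
      eggs_adaxial = res$totals$eggs_adaxial,
      feces_count = res$totals$feces_count,
      feces_area_mm2 = res$totals$feces_area_mm2,
      feces_area_abaxial = res$totals$feces_area_abaxial_mm2,
      feces_area_adaxial = res$totals$feces_area_adaxial_mm2,
      per_leaf_damage = list(lr$merged_damage_mm2),
      per_leaf_eggs = list(lr$eggs_abaxial + lr$eggs_adaxial),
      per_leaf_feces_area = list(lr$feces_area_abaxial_mm2 + lr$feces_area_adaxial_mm2))
  })
  dplyr::bind_rows(rows)
}
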