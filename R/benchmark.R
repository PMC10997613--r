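#' Default synthetic detection benchmark
#'
#' Generates seeded plants (default-noise conditions) until at least
#' `n_leaves` leaves exist, runs the full pipeline on every scan pair,
#' and scores it against the generator's ground truth:
#' object-level egg precision/recall/F1 (matching by centre distance
#' within two egg radii, one-to-one), relative errors of the total
#' black-feces and damage areas, and per-plant egg-count efficiency
#' (program / truth x 100, as in expert validation).
#'
#' @param n_leaves minimum number of leaves across all plants.
#' @param leaves_per_plant leaves per generated plant.
#' @param seed integer seed; plant `i` uses `seed * 1000 + i`.
#' @param levels [significance_levels()].
#' @param backend detector backend.
#' @param dpi rendering dpi.
#' @param config an [ms_config()] list.
#' @return list of metrics plus the `per_plant` tibble.
#' @export
synthetic_benchmark <- function(n_leaves = 100, leaves_per_plant = 8, seed = 1L,
                                levels = significance_levels(),
                                backend = "classical", dpi = NULL,
                                config = ms_config()) {
  n_plants <- ceiling(n_leaves / leaves_per_plant)
  tp <- fp <- fn <- 0
  feces_det <- feces_tr <- 0
  dmg_det <- dmg_tr <- 0
  rows <- list()
  for (i in seq_len(n_plants)) {
    sp <- plant_spec(n_leaves = leaves_per_plant, seed = seed * 1000L + i)
    pl <- generate_plant(sp, dpi = dpi, config = config)
    res <- analyze_plant(pl$abaxial, pl$adaxial, levels, backend, config)

    tr <- pl$truth
    for (side in c("abaxial", "adaxial")) {
      te <- tr$objects[tr$objects$side == side & tr$objects$class == "egg", ]
      de <- res$detections[res$detections$side == side & res$detections$klass == "egg", ]
      m <- match_objects(de, te, tol_um = 150, um = tr$um_per_px)
      tp <- tp + m[["tp"]]; fp <- fp + m[["fp"]]; fn <- fn + m[["fn"]]
    }
    feces_det <- feces_det + res$totals$feces_area_mm2
    feces_tr <- feces_tr + tr$totals$feces_area_mm2
    dmg_det <- dmg_det + res$totals$damage_area_mm2
    dmg_tr <- dmg_tr + tr$totals$merged_damage_area_mm2
    rows[[i]] <- tibble::tibble(
      plant = i, n_leaves = sp$n_leaves,
      eggs_detected = res$totals$egg_count, eggs_true = tr$totals$egg_count,
      feces_area_detected = res$totals$feces_area_mm2,
      feces_area_true = tr$totals$feces_area_mm2,
      damage_detected = res$totals$damage_area_mm2,
      damage_true = tr$totals$merged_damage_area_mm2)
  }
  per_plant <- dplyr::bind_rows(rows)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  eff <- object_efficiency(per_plant$eggs_detected, per_plant$eggs_true,
                           trait = "egg_count")
  list(
    n_plants = n_plants, n_leaves = sum(per_plant$n_leaves),
    egg_tp = tp, egg_fp = fp, egg_fn = fn,
    egg_precision = precision, egg_recall = recall,
    egg_f1 = 2 * precision * recall / (precision + recall),
    egg_efficiency = eff,
    feces_area_error_pct = 100 * abs(feces_det - feces_tr) / feces_tr,
    damage_area_error_pct = 100 * abs(dmg_det - dmg_tr) / dmg_tr,
    per_plant = per_plant)
}

# one-to-one greedy matching of detections to reference objects by
# centre distance
match_objects <- function(det, ref, tol_um, um) {
  used <- rep(FALSE, nrow(ref))
  tp <- 0
  for (i in seq_len(nrow(det))) {
    if (!nrow(ref)) break
    dd <- sqrt((ref$row - det$row[i])^2 + (ref$col - det$col[i])^2) * um
    dd[used] <- Inf
    j <- which.min(dd)
    if (length(j) && dd[j] <= tol_um) {
      used[j] <- TRUE
      tp <- tp + 1
    }
  }
  c(tp = tp, fp = nrow(det) - tp, fn = nrow(ref) - tp)
}
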