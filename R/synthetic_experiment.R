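#' Design table for a synthetic susceptibility experiment
#'
#' One row per ecotype with the mean symptom levels its plants are drawn
#' from. Egg and feces counts per leaf are negative-binomially
#' distributed around their means; damage fractions are beta-distributed
#' around theirs. A weight profile over leaf age (zero on the two
#' youngest leaves, rising with age) shapes the within-plant
#' distribution.
#'
#' @param ecotype character vector of ecotype labels.
#' @param eggs_per_leaf_mean,feces_per_leaf_mean,damage_fraction_mean
#'   numeric vectors (recycled) of per-leaf symptom means.
#' @param p_adaxial_egg adaxial egg probability per ecotype.
#' @param dispersion negative-binomial size parameter for count noise.
#' @return a tibble usable as the `design` of [generate_experiment()].
#' @export
experiment_design <- function(ecotype,
                              eggs_per_leaf_mean = 5,
                              feces_per_leaf_mean = 4,
                              damage_fraction_mean = 0.04,
                              p_adaxial_egg = 1 / 6,
                              dispersion = 5) {
  tibble::tibble(
    ecotype = ecotype,
    eggs_per_leaf_mean = rep_len(eggs_per_leaf_mean, length(ecotype)),
    feces_per_leaf_mean = rep_len(feces_per_leaf_mean, length(ecotype)),
    damage_fraction_mean = rep_len(damage_fraction_mean, length(ecotype)),
    p_adaxial_egg = rep_len(p_adaxial_egg, length(ecotype)),
    dispersion = rep_len(dispersion, length(ecotype)))
}

# leaf-age weights: two youngest leaves symptom-free, then rising with
# age; normalised to mean 1 over all leaves so per-leaf means are kept.
age_weights <- function(n_leaves) {
  w <- c(rep(0, min(2L, n_leaves)),
         seq(0.6, 1.6, length.out = max(0L, n_leaves - 2L)))
  if (sum(w) == 0) return(w)
  w * n_leaves / sum(w)
}

#' Generate a multi-ecotype synthetic experiment
#'
#' Draws per-plant symptom loads for each ecotype of a design, in one or
#' more repetition batches each containing its own group of reference
#' plants (used downstream for relative values). The master truth table
#' records exact per-plant trait values; with `render = TRUE` every
#' plant is also rendered with [generate_plant()] and written as a TIFF
#' pair named with the filename dialect.
#'
#' @param design an [experiment_design()] tibble; must contain
#'   `reference_label`.
#' @param n_plants_per_ecotype plants per non-reference ecotype (>= 2),
#'   split evenly over batches.
#' @param reference_label the reference ecotype, present in every batch
#'   with `n_reference` plants.
#' @param n_reference reference plants per batch.
#' @param n_batches repetition batches.
#' @param seed integer seed.
#' @param render render and write plate scans (slow); otherwise only the
#'   truth table and plant specs are produced.
#' @param out_dir directory for rendered TIFF pairs.
#' @param dpi rendering dpi when `render = TRUE`.
#' @param config an [ms_config()] list.
#' @return list with `plants` (master truth table, one row per plant,
#'   with per-leaf trait vectors as list-columns), `specs` (the
#'   [plant_spec()]s), and `files` (paths, when rendered).
#' @export
generate_experiment <- function(design, n_plants_per_ecotype = 6,
                                reference_label = "Col-0",
                                n_reference = 6, n_batches = 1,
                                seed = 1L, render = FALSE, out_dir = NULL,
                                dpi = NULL, config = ms_config()) {
  if (!reference_label %in% design$ecotype)
    stop(sprintf("design must include the reference ecotype '%s'", reference_label),
         call. = FALSE)
  if (n_plants_per_ecotype < 2)
    stop("n_plants_per_ecotype must be >= 2 (statistics need replication)", call. = FALSE)

  rows <- list()
  specs <- list()
  with_seed(seed, {
    for (e in seq_len(nrow(design))) {
      des <- design[e, ]
      is_ref <- des$ecotype == reference_label
      per_batch <- if (is_ref) rep(n_reference, n_batches) else {
        base <- n_plants_per_ecotype %/% n_batches
        extra <- n_plants_per_ecotype %% n_batches
        base + as.integer(seq_len(n_batches) <= extra)
      }
      rep_counter <- 0L
      for (b in seq_len(n_batches)) {
        for (p in seq_len(per_batch[b])) {
          rep_counter <- rep_counter + 1L
          n_leaves <- sample(7:10, 1)
          lengths <- seq(4, stats::runif(1, 11, 15), length.out = n_leaves)
          w <- age_weights(n_leaves)
          eggs <- stats::rnbinom(n_leaves, mu = des$eggs_per_leaf_mean * w,
                                 size = des$dispersion)
          feces <- stats::rnbinom(n_leaves, mu = des$feces_per_leaf_mean * w,
                                  size = des$dispersion)
          m <- pmin(des$damage_fraction_mean * w, 0.45)
          frac <- vapply(m, function(mi) {
            if (mi <= 0) return(0)
            stats::rbeta(1, 2, 2 * (1 - mi) / mi)
          }, numeric(1))
          frac <- pmin(frac, 0.5)

          blade <- blade_area_mm2(lengths)
          dmg_leaf <- frac * blade
          ov <- 0.6
          eggs_ad <- stats::rbinom(1, sum(eggs), des$p_adaxial_egg)
          feces_ad <- stats::rbinom(1, sum(feces), 0.5)
          pellet_d <- if (sum(feces) > 0)
            stats::runif(sum(feces), config$synth$feces_diameter_um[1],
                         config$synth$feces_diameter_um[2]) else numeric(0)
          pellet_area <- sum(pi * (pellet_d / 2000)^2)   # mm^2
          pellet_leaf <- if (sum(feces) > 0)
            vapply(split(pi * (pellet_d / 2000)^2,
                         rep(seq_len(n_leaves), feces)), sum, numeric(1)) else numeric(0)
          feces_area_leaf <- numeric(n_leaves)
          if (sum(feces) > 0) feces_area_leaf[as.integer(names(pellet_leaf))] <- pellet_leaf

          plant_seed <- sample.int(.Machine$integer.max / 2, 1)
          sp <- plant_spec(
            n_leaves = n_leaves, leaf_lengths_mm = lengths,
            eggs_per_leaf = eggs, p_adaxial_egg = des$p_adaxial_egg,
            feces_per_leaf = feces, damage_fraction_per_leaf = frac,
            damage_side_overlap = ov, seed = plant_seed)
          specs[[length(specs) + 1L]] <- sp

          rows[[length(rows) + 1L]] <- tibble::tibble(
            ecotype = des$ecotype, ecotype_index = e, batch = paste0("K", b),
            replicate = rep_counter, n_leaves = n_leaves,
            damage_area_mm2 = sum(dmg_leaf),
            damage_abaxial_mm2 = sum(dmg_leaf) * (ov + (1 - ov) / 2),
            damage_adaxial_mm2 = sum(dmg_leaf) * (ov + (1 - ov) / 2),
            egg_count = sum(eggs), eggs_adaxial = eggs_ad,
            eggs_abaxial = sum(eggs) - eggs_ad,
            oviposition_rate = sum(eggs) / 10,
            feces_count = sum(feces), feces_area_mm2 = pellet_area,
            feces_area_adaxial = pellet_area * (if (sum(feces) > 0) feces_ad / sum(feces) else 0),
            feces_area_abaxial = pellet_area * (if (sum(feces) > 0) 1 - feces_ad / sum(feces) else 0),
            per_leaf_damage = list(dmg_leaf),
            per_leaf_eggs = list(as.numeric(eggs)),
            per_leaf_feces_area = list(feces_area_leaf))
        }
      }
    }
  })
  plants <- dplyr::bind_rows(rows)

  files <- NULL
  if (render) {
    if (is.null(out_dir)) stop("render = TRUE needs out_dir", call. = FALSE)
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- character(0)
    for (k in seq_len(nrow(plants))) {
      pl <- generate_plant(specs[[k]], dpi = dpi, config = config)
      for (side in c("abaxial", "adaxial")) {
        meta <- new_scan_meta(side, plants$ecotype[k], plants$ecotype_index[k],
                              plants$replicate[k], plants$batch[k], plants$n_leaves[k])
        path <- file.path(out_dir, paste0(encode_scan_filename(meta, config), ".tiff"))
        write_scan(pl[[side]], path)
        files <- c(files, path)
      }
    }
  }
  list(design = design, plants = plants, specs = specs, files = files)
}
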