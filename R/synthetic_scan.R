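#' Specification of one synthetic mite-infested plant
#'
#' Describes the plant whose detached rosette leaves are mounted on a
#' plate and scanned from both sides: leaf sizes, symptom loads (eggs,
#' black feces, chlorotic feeding damage), the side preference of eggs
#' and feces, and the confounders added to the adaxial scan (air bubbles
#' in the tape glue, white guanine feces, blur). Leaves are indexed from
#' the youngest (index 0), matching the mounting convention; defaults
#' put no eggs or damage on the two youngest leaves, whose dense
#' trichome coating deters mites.
#'
#' @param n_leaves number of leaves (>= 1).
#' @param leaf_lengths_mm leaf lengths, youngest first, each >= 4 mm
#'   (smaller leaves are not mounted).
#' @param eggs_per_leaf,feces_per_leaf non-negative integer counts per
#'   leaf.
#' @param p_adaxial_egg,p_adaxial_feces probability that an object lies
#'   on the adaxial (upper) side; the default 1/6 for eggs matches the
#'   roughly 1:5 adaxial:abaxial ratio typical of this mite.
#' @param damage_fraction_per_leaf fraction of blade area damaged per
#'   leaf, each in [0, 0.5].
#' @param damage_side_overlap fraction of damage shared between the two
#'   sides (damage often shows through the blade only partially).
#' @param bubble_density air-bubble confounders per cm^2 on the adaxial
#'   scan.
#' @param white_feces_per_leaf white guanine-feces confounders per leaf
#'   on the adaxial scan (rendered, never quantified).
#' @param trichome_density_gradient multiplier of trichome density on
#'   the youngest leaf relative to the oldest.
#' @param seed integer seed; the same spec and seed give bit-identical
#'   scans and ground truth.
#' @return a validated list of class `plant_spec`.
#' @export
#' @examples
#' sp <- plant_spec(n_leaves = 4, seed = 7)
#' sp$eggs_per_leaf
plant_spec <- function(n_leaves = 8,
                       leaf_lengths_mm = NULL,
                       eggs_per_leaf = NULL,
                       p_adaxial_egg = 1 / 6,
                       feces_per_leaf = NULL,
                       p_adaxial_feces = 0.5,
                       damage_fraction_per_leaf = NULL,
                       damage_side_overlap = 0.6,
                       bubble_density = 2,
                       white_feces_per_leaf = NULL,
                       trichome_density_gradient = 3,
                       seed = 1L) {
  stopifnot(n_leaves >= 1)
  n <- as.integer(n_leaves)
  if (is.null(leaf_lengths_mm)) leaf_lengths_mm <- seq(4.5, max(4.5, 4.5 + 1.1 * (n - 1)), length.out = n)
  if (is.null(eggs_per_leaf)) eggs_per_leaf <- c(rep(0L, min(2L, n)), rep(5L, max(0L, n - 2L)))
  if (is.null(feces_per_leaf)) feces_per_leaf <- c(rep(0L, min(2L, n)), rep(4L, max(0L, n - 2L)))
  if (is.null(damage_fraction_per_leaf))
    damage_fraction_per_leaf <- c(rep(0, min(2L, n)), rep(0.04, max(0L, n - 2L)))
  if (is.null(white_feces_per_leaf)) white_feces_per_leaf <- rep(1L, n)

  for (nm in c("leaf_lengths_mm", "eggs_per_leaf", "feces_per_leaf",
               "damage_fraction_per_leaf", "white_feces_per_leaf")) {
    v <- get(nm)
    if (length(v) != n) stop(sprintf("`%s` must have length n_leaves (%d)", nm, n), call. = FALSE)
  }
  if (any(leaf_lengths_mm < 4)) stop("all leaf lengths must be >= 4 mm", call. = FALSE)
  if (any(eggs_per_leaf < 0) || any(feces_per_leaf < 0))
    stop("symptom counts must be non-negative", call. = FALSE)
  for (p in c(p_adaxial_egg, p_adaxial_feces, damage_side_overlap))
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (any(damage_fraction_per_leaf < 0) || any(damage_fraction_per_leaf > 0.5))
    stop("damage fractions must lie in [0, 0.5]", call. = FALSE)

  structure(list(
    n_leaves = n,
    leaf_lengths_mm = as.numeric(leaf_lengths_mm),
    eggs_per_leaf = as.integer(eggs_per_leaf),
    p_adaxial_egg = p_adaxial_egg,
    feces_per_leaf = as.integer(feces_per_leaf),
    p_adaxial_feces = p_adaxial_feces,
    damage_fraction_per_leaf = as.numeric(damage_fraction_per_leaf),
    damage_side_overlap = damage_side_overlap,
    bubble_density = bubble_density,
    white_feces_per_leaf = as.integer(white_feces_per_leaf),
    trichome_density_gradient = trichome_density_gradient,
    seed = as.integer(seed)
  ), class = "plant_spec")
}

# Blade ellipse semi-axes from leaf length; blade spans ~70% of the leaf,
# the petiole the remaining ~30%, so blade + petiole measure the stated
# leaf length.
blade_axes_mm <- function(length_mm) {
  c(along = 0.35 * length_mm, across = 0.20 * length_mm)
}

#' Analytic blade area for a leaf length
#' @param length_mm leaf length in mm.
#' @return blade area in mm^2 (ellipse model).
#' @keywords internal
blade_area_mm2 <- function(length_mm) {
  pi * (0.35 * length_mm) * (0.20 * length_mm)
}

# ---------------------------------------------------------------------------
# Stage 1: seeded physical layout, all in mm/um. Pure RNG; no raster.
# Separating layout from rasterisation makes ground-truth physical values
# independent of the rendering dpi (up to rasterisation error).
# ---------------------------------------------------------------------------
build_layout <- function(spec, config = ms_config()) {
  n <- spec$n_leaves
  spacing <- config$synth$spacing_mm
  margin <- config$synth$margin_mm

  axes <- t(vapply(spec$leaf_lengths_mm, blade_axes_mm, numeric(2)))
  pet_len <- 0.28 * spec$leaf_lengths_mm
  pet_w <- 0.4
  leaf_h <- 2 * axes[, "along"] + pet_len     # blade + petiole, mm
  leaf_w <- 2 * axes[, "across"]

  n_top <- ceiling(n / 2)
  rows <- ifelse(seq_len(n) <= n_top, 1L, 2L)
  # slot positions left-to-right within each row, youngest first
  x_centers <- numeric(n)
  for (r in 1:2) {
    idx <- which(rows == r)
    if (!length(idx)) next
    x <- margin
    for (i in idx) {
      x_centers[i] <- x + leaf_w[i] / 2
      x <- x + leaf_w[i] + spacing
    }
  }
  row_h <- vapply(1:2, function(r) {
    idx <- which(rows == r)
    if (length(idx)) max(leaf_h[idx]) else 0
  }, numeric(1))
  y_blade_center <- numeric(n)
  for (i in seq_len(n)) {
    top <- margin + if (rows[i] == 2L) row_h[1] + spacing else 0
    y_blade_center[i] <- top + axes[i, "along"]
  }
  plate_w <- max(x_centers + leaf_w / 2) + margin
  plate_h <- margin + row_h[1] + (if (any(rows == 2L)) spacing + row_h[2] else 0) + margin
  if (plate_w > 100 || plate_h > 100)
    stop(sprintf("plate layout (%.1f x %.1f mm) exceeds the 10 x 10 cm scan field", plate_w, plate_h),
         call. = FALSE)

  jitter_xy <- matrix(stats::runif(2 * n, -0.4, 0.4), ncol = 2)
  theta <- stats::runif(n, -8, 8) * pi / 180
  leaves <- lapply(seq_len(n), function(i) {
    list(index = i - 1L,
         cx = x_centers[i] + jitter_xy[i, 1],
         cy = y_blade_center[i] + jitter_xy[i, 2],
         a_along = unname(axes[i, "along"]), a_across = unname(axes[i, "across"]),
         theta = theta[i], pet_len = pet_len[i], pet_w = pet_w,
         wobble_phase = stats::runif(2, 0, 2 * pi),
         wobble_amp = c(0.05, 0.03) * stats::runif(2, 0.6, 1.4),
         shade = stats::runif(1, -0.03, 0.03))
  })

  # uniform sample inside the safe interior of a blade (scaled ellipse)
  sample_in_blade <- function(lf, scale = 0.78) {
    repeat {
      u <- stats::runif(1, -1, 1); v <- stats::runif(1, -1, 1)
      if (u^2 + v^2 <= 1) break
    }
    xa <- u * lf$a_across * scale
    ya <- v * lf$a_along * scale
    c(x = lf$cx + xa * cos(lf$theta) - ya * sin(lf$theta),
      y = lf$cy + xa * sin(lf$theta) + ya * cos(lf$theta))
  }

  place_objects <- function(counts, diam_range_um, existing, scale = 0.78) {
    out <- list()
    for (i in seq_len(n)) {
      k <- counts[i]
      if (k == 0) next
      lf <- leaves[[i]]
      for (j in seq_len(k)) {
        d_um <- stats::runif(1, diam_range_um[1], diam_range_um[2])
        ok <- FALSE
        for (try in 1:400) {
          p <- sample_in_blade(lf, scale)
          min_sep <- (d_um / 1000 + 0.15)
          clear <- TRUE
          for (e in c(existing, out)) {
            if (abs(e$x - p[["x"]]) < 1.5 && abs(e$y - p[["y"]]) < 1.5) {
              if (sqrt((e$x - p[["x"]])^2 + (e$y - p[["y"]])^2) <
                  (min_sep + e$d_um / 2000)) { clear <- FALSE; break }
            }
          }
          if (clear) { ok <- TRUE; break }
        }
        if (!ok) stop(sprintf("cannot fit requested objects on leaf %d (%.1f mm): reduce counts or enlarge the leaf",
                              i - 1L, spec$leaf_lengths_mm[i]), call. = FALSE)
        out[[length(out) + 1L]] <- list(leaf = i - 1L, x = p[["x"]], y = p[["y"]],
                                        d_um = d_um, orient = stats::runif(1, 0, pi),
                                        aspect = 1, tint = NA_character_)
      }
    }
    out
  }

  synth <- config$synth
  eggs <- place_objects(spec$eggs_per_leaf, synth$egg_diameter_um, list())
  for (k in seq_along(eggs)) {
    eggs[[k]]$aspect <- stats::runif(1, 1.0, 1.25)
    eggs[[k]]$tint <- sample(c("transparent", "straw", "orange"), 1)
    eggs[[k]]$side <- if (stats::runif(1) < spec$p_adaxial_egg) "adaxial" else "abaxial"
  }
  feces <- place_objects(spec$feces_per_leaf, synth$feces_diameter_um, eggs)
  for (k in seq_along(feces)) {
    feces[[k]]$aspect <- stats::runif(1, 1.0, 1.8)
    feces[[k]]$side <- if (stats::runif(1) < spec$p_adaxial_feces) "adaxial" else "abaxial"
  }
  white <- place_objects(spec$white_feces_per_leaf, c(150, 350), c(eggs, feces))
  for (k in seq_along(white)) {
    white[[k]]$aspect <- stats::runif(1, 4, 6)   # elongated streaks
    # sampled diameter is the streak length; width = length / aspect
    white[[k]]$d_um <- white[[k]]$d_um / sqrt(white[[k]]$aspect)
    white[[k]]$side <- "adaxial"
  }

  # damage: per-leaf irregular blobs, each assigned to one visibility class
  damage <- list()
  for (i in seq_len(n)) {
    frac <- spec$damage_fraction_per_leaf[i]
    if (frac <= 0) next
    lf <- leaves[[i]]
    target <- frac * blade_area_mm2(spec$leaf_lengths_mm[i])
    r_typ <- min(0.45, 0.35 * lf$a_across)
    n_blob <- max(1L, ceiling(target / (pi * r_typ^2)))
    r0 <- sqrt(target / (n_blob * pi))
    for (b in seq_len(n_blob)) {
      p <- sample_in_blade(lf, 0.70)
      u <- stats::runif(1)
      ov <- spec$damage_side_overlap
      cls <- if (u < ov) "both" else if (u < ov + (1 - ov) / 2) "abaxial" else "adaxial"
      damage[[length(damage) + 1L]] <-
        list(leaf = i - 1L, x = p[["x"]], y = p[["y"]], r = r0 * stats::runif(1, 0.85, 1.15),
             phase = stats::runif(2, 0, 2 * pi), amp = c(0.30, 0.18), class = cls)
    }
  }

  # trichomes: density gradient from youngest to oldest
  trich <- list()
  base_density <- 3  # per mm^2 on the oldest leaf
  g <- spec$trichome_density_gradient
  for (i in seq_len(n)) {
    lf <- leaves[[i]]
    rel_age <- if (n > 1) (i - 1) / (n - 1) else 1   # 0 = youngest
    dens <- base_density * g^(1 - rel_age)
    k <- stats::rpois(1, dens * blade_area_mm2(spec$leaf_lengths_mm[i]))
    if (k > 0) {
      pts <- t(vapply(seq_len(k), function(j) sample_in_blade(lf, 0.95), numeric(2)))
      trich[[i]] <- cbind(leaf = i - 1L, x = pts[, 1], y = pts[, 2])
    }
  }
  trich <- do.call(rbind, trich)

  n_bub <- stats::rpois(1, spec$bubble_density * plate_w * plate_h / 100)
  bubbles <- if (n_bub > 0) {
    data.frame(x = stats::runif(n_bub, 0.5, plate_w - 0.5),
               y = stats::runif(n_bub, 0.5, plate_h - 0.5),
               d_um = stats::runif(n_bub, config$synth$bubble_diameter_um[1],
                                   config$synth$bubble_diameter_um[2]))
  } else data.frame(x = numeric(0), y = numeric(0), d_um = numeric(0))

  list(plate_w = plate_w, plate_h = plate_h, leaves = leaves,
       eggs = eggs, feces = feces, white = white, damage = damage,
       trichomes = trich, bubbles = bubbles,
       noise_seed = sample.int(.Machine$integer.max / 2, 1))
}
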