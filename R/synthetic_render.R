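# Stage 2 of the generator: deterministic rasterisation of a physical
# layout at a chosen dpi. All randomness lives in build_layout() (seeded
# from the plant spec); rendering the same layout at two resolutions
# yields the same physical ground truth up to rasterisation error.

# window of pixel indices (1-based) covering [x0,x1] x [y0,y1] mm
px_window <- function(x0, x1, y0, y1, um, W, H) {
  c0 <- max(1L, floor(x0 * 1000 / um) - 1L)
  c1 <- min(W, ceiling(x1 * 1000 / um) + 2L)
  r0 <- max(1L, floor(y0 * 1000 / um) - 1L)
  r1 <- min(H, ceiling(y1 * 1000 / um) + 2L)
  if (c1 < c0 || r1 < r0) return(NULL)
  list(ri = r0:r1, ci = c0:c1)
}

# pixel-centre coordinate grids (mm) for a window
grid_mm <- function(win, um) {
  list(x = matrix((win$ci - 0.5) * um / 1000, nrow = length(win$ri),
                  ncol = length(win$ci), byrow = TRUE),
       y = matrix((win$ri - 0.5) * um / 1000, nrow = length(win$ri),
                  ncol = length(win$ci)))
}

# leaf-frame coordinates of a grid relative to an object centre/orientation
to_frame <- function(g, cx, cy, theta) {
  dx <- g$x - cx
  dy <- g$y - cy
  list(xa = dx * cos(theta) + dy * sin(theta),
       ya = -dx * sin(theta) + dy * cos(theta))
}

leaf_window <- function(lf, um, W, H, pad_mm = 0.5) {
  ext <- max(lf$a_along, lf$a_across) + lf$pet_len + pad_mm
  px_window(lf$cx - ext, lf$cx + ext, lf$cy - ext, lf$cy + ext, um, W, H)
}

# blade + petiole mask of one leaf on its window grid
leaf_mask_local <- function(lf, g) {
  f <- to_frame(g, lf$cx, lf$cy, lf$theta)
  xn <- f$xa / lf$a_across
  yn <- f$ya / lf$a_along
  phi <- atan2(yn, xn)
  wob <- 1 + lf$wobble_amp[1] * sin(3 * phi + lf$wobble_phase[1]) +
    lf$wobble_amp[2] * sin(7 * phi + lf$wobble_phase[2])
  blade <- (xn^2 + yn^2) <= wob^2
  pet <- abs(f$xa) <= lf$pet_w / 2 &
    f$ya >= lf$a_along * 0.80 & f$ya <= lf$a_along * 0.85 + lf$pet_len
  list(mask = blade | pet, blade = blade, frame = f)
}

# alpha-blend a colour into a window of the canvas
blend <- function(imgwin, alpha, rgb) {
  for (ch in 1:3) imgwin[, , ch] <- imgwin[, , ch] * (1 - alpha) + rgb[ch] * alpha
  imgwin
}

egg_tint_rgb <- function(tint, leaf_rgb) {
  switch(tint,
         transparent = 0.45 * leaf_rgb + 0.55 * c(0.92, 0.93, 0.85),
         straw = c(0.86, 0.79, 0.48),
         orange = c(0.90, 0.57, 0.25))
}

DAMAGE_RGB <- c(0.82, 0.74, 0.34)
FECES_RGB <- c(0.07, 0.06, 0.05)
WHITE_RGB <- c(0.94, 0.94, 0.88)
TAPE_RGB <- c(0.93, 0.93, 0.90)

# irregular round blob support (damage / feces) on a frame
blob_support <- function(f, r, phase, amp) {
  rr <- sqrt(f$xa^2 + f$ya^2)
  phi <- atan2(f$ya, f$xa)
  rloc <- r * (1 + amp[1] * sin(2 * phi + phase[1]) + amp[2] * sin(5 * phi + phase[2]))
  rr <= rloc
}

render_side <- function(layout, spec, dpi, side, config) {
  um <- dpi_to_um_per_px(dpi)
  W <- as.integer(ceiling(layout$plate_w * 1000 / um))
  H <- as.integer(ceiling(layout$plate_h * 1000 / um))
  img <- array(rep(TAPE_RGB, each = H * W), dim = c(H, W, 3))

  leaf_rgb_base <- if (side == "abaxial") c(0.44, 0.63, 0.36) else c(0.31, 0.53, 0.26)

  leaf_masks <- vector("list", spec$n_leaves)
  damage_masks <- vector("list", spec$n_leaves)
  per_leaf <- data.frame(leaf_index = seq_len(spec$n_leaves) - 1L,
                         leaf_area_px = 0, damage_area_px = 0,
                         egg_count = 0L, feces_count = 0L, feces_area_px = 0)
  objects <- list()

  for (i in seq_len(spec$n_leaves)) {
    lf <- layout$leaves[[i]]
    win <- leaf_window(lf, um, W, H)
    g <- grid_mm(win, um)
    lm <- leaf_mask_local(lf, g)
    leaf_rgb <- clamp(leaf_rgb_base + lf$shade, 0, 1)

    # radial shading makes the blade slightly darker toward the rim
    rr <- sqrt((lm$frame$xa / lf$a_across)^2 + (lm$frame$ya / lf$a_along)^2)
    shade <- 1 - 0.08 * clamp(rr, 0, 1)
    imgwin <- img[win$ri, win$ci, , drop = FALSE]
    a <- lm$mask * 1
    for (ch in 1:3) imgwin[, , ch] <- imgwin[, , ch] * (1 - a) + leaf_rgb[ch] * shade * a

    # damage blobs of this leaf visible on this side, clipped to the blade
    blobs <- Filter(function(d) d$leaf == i - 1L && d$class %in% c("both", side),
                    layout$damage)
    dmask <- matrix(FALSE, length(win$ri), length(win$ci))
    for (d in blobs) {
      f <- to_frame(g, d$x, d$y, 0)
      dmask <- dmask | blob_support(f, d$r, d$phase, d$amp)
    }
    dmask <- dmask & lm$blade
    if (any(dmask)) {
      alpha <- 0.9 * blur2(dmask * 1, 0.8)
      alpha[!lm$mask] <- 0
      imgwin <- blend(imgwin, alpha, DAMAGE_RGB)
    }

    img[win$ri, win$ci, ] <- imgwin

    bbox <- box_new(win$ri[1] - 1L, win$ci[1] - 1L,
                    win$ri[length(win$ri)], win$ci[length(win$ci)])
    leaf_masks[[i]] <- list(bbox = bbox, mask = lm$mask)
    damage_masks[[i]] <- list(bbox = bbox, mask = dmask)
    per_leaf$leaf_area_px[i] <- sum(lm$mask)
    per_leaf$damage_area_px[i] <- sum(dmask)
  }

  # trichomes: small bright bumps
  if (!is.null(layout$trichomes) && nrow(layout$trichomes) > 0) {
    sig <- 18 / um   # ~18 um wide
    for (k in seq_len(nrow(layout$trichomes))) {
      tx <- layout$trichomes[k, "x"]; ty <- layout$trichomes[k, "y"]
      win <- px_window(tx - 0.06, tx + 0.06, ty - 0.06, ty + 0.06, um, W, H)
      if (is.null(win)) next
      g <- grid_mm(win, um)
      dd <- ((g$x - tx)^2 + (g$y - ty)^2) / (0.018^2)
      alpha <- 0.45 * exp(-dd)
      imgwin <- img[win$ri, win$ci, , drop = FALSE]
      for (ch in 1:3) imgwin[, , ch] <- clamp(imgwin[, , ch] + 0.25 * alpha, 0, 1)
      img[win$ri, win$ci, ] <- imgwin
    }
  }

  paint_object <- function(ob, kind) {
    # d_um is the equivalent diameter; aspect deforms at constant area
    d_mm <- ob$d_um / 1000
    a_mm <- d_mm / 2 * sqrt(ob$aspect)
    b_mm <- d_mm / 2 / sqrt(ob$aspect)
    ext <- a_mm + 3 * um / 1000
    win <- px_window(ob$x - ext, ob$x + ext, ob$y - ext, ob$y + ext, um, W, H)
    if (is.null(win)) return(0L)
    g <- grid_mm(win, um)
    f <- to_frame(g, ob$x, ob$y, ob$orient)
    rr <- sqrt((f$xa / a_mm)^2 + (f$ya / b_mm)^2)
    imgwin <- img[win$ri, win$ci, , drop = FALSE]
    support <- rr <= 1
    if (kind == "egg") {
      lf_rgb <- clamp(leaf_rgb_base + layout$leaves[[ob$leaf + 1L]]$shade, 0, 1)
      tint <- egg_tint_rgb(ob$tint, lf_rgb)
      alpha <- clamp((1.08 - rr) / 0.16, 0, 1)
      imgwin <- blend(imgwin, alpha, tint)
      hl <- clamp((0.45 - rr) / 0.45, 0, 1) * 0.20   # glossy highlight
      for (ch in 1:3) imgwin[, , ch] <- clamp(imgwin[, , ch] + hl, 0, 1)
    } else if (kind == "feces") {
      phi <- atan2(f$ya, f$xa)
      rr2 <- rr / (1 + 0.20 * sin(3 * phi + ob$orient))
      support <- rr2 <= 1
      alpha <- clamp((1.06 - rr2) / 0.12, 0, 1)
      imgwin <- blend(imgwin, alpha, FECES_RGB)
    } else if (kind == "white_feces") {
      alpha <- clamp((1.05 - rr) / 0.15, 0, 1)
      imgwin <- blend(imgwin, 0.9 * alpha, WHITE_RGB)
    } else if (kind == "bubble") {
      ring <- clamp(1 - abs(rr - 0.9) / 0.22, 0, 1)
      core <- clamp((0.65 - rr) / 0.65, 0, 1)
      for (ch in 1:3) imgwin[, , ch] <-
          clamp(imgwin[, , ch] + 0.16 * ring - 0.14 * core, 0, 1)
    }
    img[win$ri, win$ci, ] <<- imgwin
    sum(support)
  }

  obs <- c(lapply(layout$eggs, function(o) c(o, kind = "egg")),
           lapply(layout$feces, function(o) c(o, kind = "feces")),
           lapply(layout$white, function(o) c(o, kind = "white_feces")))
  for (ob in obs) {
    if (ob$side != side) next
    npx <- paint_object(ob, ob$kind)
    cls <- switch(ob$kind, egg = "egg", feces = "black_feces", white_feces = "white_feces")
    r_ctr <- ob$y * 1000 / um
    c_ctr <- ob$x * 1000 / um
    half <- ob$d_um / 2 * sqrt(ob$aspect) / um
    objects[[length(objects) + 1L]] <- data.frame(
      class = cls, side = side, leaf_index = ob$leaf,
      row = r_ctr, col = c_ctr, diameter_um = ob$d_um,
      support_px = npx,
      r0 = floor(r_ctr - half), c0 = floor(c_ctr - half),
      r1 = ceiling(r_ctr + half), c1 = ceiling(c_ctr + half))
    li <- ob$leaf + 1L
    if (cls == "egg") per_leaf$egg_count[li] <- per_leaf$egg_count[li] + 1L
    if (cls == "black_feces") {
      per_leaf$feces_count[li] <- per_leaf$feces_count[li] + 1L
      per_leaf$feces_area_px[li] <- per_leaf$feces_area_px[li] + npx
    }
  }

  if (side == "adaxial") {
    for (k in seq_len(nrow(layout$bubbles))) {
      b <- layout$bubbles[k, ]
      paint_object(list(x = b$x, y = b$y, d_um = b$d_um, aspect = 1, orient = 0,
                        leaf = NA_integer_, side = "adaxial"), "bubble")
      r_ctr <- b$y * 1000 / um; c_ctr <- b$x * 1000 / um; half <- b$d_um / 2 / um
      objects[[length(objects) + 1L]] <- data.frame(
        class = "bubble", side = "adaxial", leaf_index = NA_integer_,
        row = r_ctr, col = c_ctr, diameter_um = b$d_um, support_px = NA_integer_,
        r0 = floor(r_ctr - half), c0 = floor(c_ctr - half),
        r1 = ceiling(r_ctr + half), c1 = ceiling(c_ctr + half))
    }
  }

  objects <- if (length(objects)) do.call(rbind, objects) else
    data.frame(class = character(0), side = character(0), leaf_index = integer(0),
               row = numeric(0), col = numeric(0), diameter_um = numeric(0),
               support_px = integer(0), r0 = numeric(0), c0 = numeric(0),
               r1 = numeric(0), c1 = numeric(0))

  list(img = img, W = W, H = H, um = um, objects = objects,
       leaf_masks = leaf_masks, damage_masks = damage_masks, per_leaf = per_leaf)
}

mirror_box <- function(box, W) {
  box_new(box[["r0"]], W - box[["c1"]], box[["r1"]], W - box[["c0"]])
}

#' Generate one synthetic plant: paired plate scans plus ground truth
#'
#' Renders the detached leaves of one plant on a plate, imaged from the
#' abaxial side and — after turning the plate over, which mirrors the
#' image left-right — from the adaxial side. The adaxial scan passes
#' through plate and tape, so it is blurred, noisier and carries air
#' bubbles and white guanine feces as confounders. All randomness is
#' drawn from `spec$seed` in physical units, so the same spec renders to
#' the same ground truth at any dpi (up to rasterisation error).
#'
#' @param spec a [plant_spec()].
#' @param dpi rendering resolution (default `config$synth$dpi`, 1200 dpi
#'   for desk-scale work; 8500 dpi matches the real scanner).
#' @param config an [ms_config()] list.
#' @return list with `abaxial` and `adaxial` (`scan_image`s) and `truth`
#'   (a `ground_truth` list: `objects` table in each side's own pixel
#'   frame, per-leaf/per-side masks, `per_leaf` truth table in mm^2, and
#'   `totals`).
#' @export
#' @examples
#' pl <- generate_plant(plant_spec(n_leaves = 2, seed = 3), dpi = 600)
#' pl$truth$totals$egg_count
generate_plant <- function(spec, dpi = NULL, config = ms_config()) {
  stopifnot(inherits(spec, "plant_spec"))
  dpi <- dpi %||% config$synth$dpi
  layout <- with_seed(spec$seed, build_layout(spec, config))

  ab <- render_side(layout, spec, dpi, "abaxial", config)
  ad <- render_side(layout, spec, dpi, "adaxial", config)
  um <- ab$um
  W <- ab$W

  # plate turned over: mirror the adaxial rendering left-right
  ad$img <- ad$img[, W:1, , drop = FALSE]
  if (nrow(ad$objects)) {
    ad$objects$col <- W - ad$objects$col
    c0 <- ad$objects$c0
    ad$objects$c0 <- W - ad$objects$c1
    ad$objects$c1 <- W - c0
  }
  for (i in seq_along(ad$leaf_masks)) {
    ad$leaf_masks[[i]]$mask <- ad$leaf_masks[[i]]$mask[, ncol(ad$leaf_masks[[i]]$mask):1, drop = FALSE]
    ad$leaf_masks[[i]]$bbox <- mirror_box(ad$leaf_masks[[i]]$bbox, W)
    ad$damage_masks[[i]]$mask <- ad$damage_masks[[i]]$mask[, ncol(ad$damage_masks[[i]]$mask):1, drop = FALSE]
    ad$damage_masks[[i]]$bbox <- mirror_box(ad$damage_masks[[i]]$bbox, W)
  }

  # merged damage (union over sides, shared portion counted once), in the
  # abaxial frame: both sides were rasterised on the same plate grid
  merged <- vector("list", spec$n_leaves)
  merged_px <- numeric(spec$n_leaves)
  ab_frame_ad <- render_side_damage_only(layout, spec, dpi, config)
  for (i in seq_len(spec$n_leaves)) {
    m <- ab$damage_masks[[i]]$mask | ab_frame_ad[[i]]$mask
    merged[[i]] <- list(bbox = ab$damage_masks[[i]]$bbox, mask = m)
    merged_px[i] <- sum(m)
  }

  px_area <- (um / 1000)^2
  per_leaf <- rbind(
    cbind(ab$per_leaf, side = "abaxial"),
    cbind(ad$per_leaf, side = "adaxial"))
  per_leaf <- tibble::tibble(
    leaf_index = per_leaf$leaf_index, side = per_leaf$side,
    leaf_area_mm2 = per_leaf$leaf_area_px * px_area,
    damage_area_mm2 = per_leaf$damage_area_px * px_area,
    egg_count = per_leaf$egg_count,
    feces_count = per_leaf$feces_count,
    feces_area_mm2 = per_leaf$feces_area_px * px_area)
  per_leaf_merged <- tibble::tibble(
    leaf_index = seq_len(spec$n_leaves) - 1L,
    merged_damage_area_mm2 = merged_px * px_area)

  objects <- tibble::as_tibble(rbind(ab$objects, ad$objects))
  objects$area_mm2 <- objects$support_px * px_area

  totals <- list(
    egg_count = sum(per_leaf$egg_count),
    feces_count = sum(per_leaf$feces_count),
    feces_area_mm2 = sum(per_leaf$feces_area_mm2),
    damage_area_mm2 = sum(per_leaf$damage_area_mm2),
    merged_damage_area_mm2 = sum(per_leaf_merged$merged_damage_area_mm2),
    leaf_area_mm2 = sum(per_leaf$leaf_area_mm2[per_leaf$side == "abaxial"]))

  truth <- structure(list(
    objects = objects, per_leaf = per_leaf, per_leaf_merged = per_leaf_merged,
    totals = totals, um_per_px = um, dim = c(ab$H, ab$W),
    leaf_masks = list(abaxial = ab$leaf_masks, adaxial = ad$leaf_masks),
    damage_masks = list(abaxial = ab$damage_masks, adaxial = ad$damage_masks,
                        merged = merged),
    plate_mm = c(layout$plate_w, layout$plate_h)), class = "ground_truth")

  noisy <- function(r, img, blur_sigma) {
    with_seed(layout$noise_seed + r, {
      if (blur_sigma > 0) for (ch in 1:3) img[, , ch] <- blur2(img[, , ch], blur_sigma)
      img + array(stats::rnorm(length(img), 0, config$synth$noise_sd), dim = dim(img))
    })
  }
  ab_img <- quantize8(noisy(0L, ab$img, 0))
  ad_img <- quantize8(noisy(1L, ad$img, config$synth$blur_sigma_px))

  list(
    abaxial = new_scan_image(ab_img, um, "abaxial"),
    adaxial = new_scan_image(ad_img, um, "adaxial"),
    truth = truth)
}

# adaxial-side damage rasterised in the (unmirrored) abaxial plate frame,
# for the merged-damage ground truth
render_side_damage_only <- function(layout, spec, dpi, config) {
  um <- dpi_to_um_per_px(dpi)
  W <- as.integer(ceiling(layout$plate_w * 1000 / um))
  H <- as.integer(ceiling(layout$plate_h * 1000 / um))
  out <- vector("list", spec$n_leaves)
  for (i in seq_len(spec$n_leaves)) {
    lf <- layout$leaves[[i]]
    win <- leaf_window(lf, um, W, H)
    g <- grid_mm(win, um)
    lm <- leaf_mask_local(lf, g)
    blobs <- Filter(function(d) d$leaf == i - 1L && d$class %in% c("both", "adaxial"),
                    layout$damage)
    dmask <- matrix(FALSE, length(win$ri), length(win$ci))
    for (d in blobs) {
      f <- to_frame(g, d$x, d$y, 0)
      dmask <- dmask | blob_support(f, d$r, d$phase, d$amp)
    }
    dmask <- dmask & lm$blade
    out[[i]] <- list(bbox = box_new(win$ri[1] - 1L, win$ci[1] - 1L,
                                    win$ri[length(win$ri)], win$ci[length(win$ci)]),
                     mask = dmask)
  }
  out
}
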