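eggs_on_leaf <- function(pl, scan, regs, levels = significance_levels()) {
  dplyr::bind_rows(lapply(regs, function(r) detect_eggs(scan, r, levels)))
}

test_that("eggs are recovered with full precision and recall on a clean leaf", {
  sp <- plant_spec(n_leaves = 1, leaf_lengths_mm = 12, eggs_per_leaf = 5L,
                   feces_per_leaf = 0L, damage_fraction_per_leaf = 0,
                   p_adaxial_egg = 0, bubble_density = 0,
                   white_feces_per_leaf = 0L, seed = 61)
  pl <- generate_plant(sp)
  regs <- order_leaves(segment_leaves(pl$abaxial))
  det <- eggs_on_leaf(pl, pl$abaxial, regs)
  te <- pl$truth$objects[pl$truth$objects$class == "egg", ]
  expect_equal(nrow(det), 5)
  m <- mitescan:::match_objects(det, te, tol_um = 150, um = pl$truth$um_per_px)
  expect_equal(unname(m), c(5, 0, 0))
})

test_that("adaxial air bubbles are not reported as eggs", {
  sp <- plant_spec(n_leaves = 2, leaf_lengths_mm = c(10, 12),
                   eggs_per_leaf = c(0L, 0L), feces_per_leaf = c(0L, 0L),
                   damage_fraction_per_leaf = c(0, 0), bubble_density = 40,
                   white_feces_per_leaf = c(0L, 0L), seed = 62)
  pl <- generate_plant(sp)
  expect_gte(sum(pl$truth$objects$class == "bubble"), 10)
  regs <- order_leaves(segment_leaves(pl$adaxial))
  det <- eggs_on_leaf(pl, pl$adaxial, regs)
  expect_equal(nrow(det), 0)
})

test_that("egg and feces counts are monotone in the significance level", {
  pl <- fixture_plant("plate5", n_leaves = 5, seed = 31)
  regs <- order_leaves(segment_leaves(pl$abaxial))
  egg_lvls <- c(0.8, 0.85, 0.9, 0.95)
  counts <- vapply(egg_lvls, function(lv) {
    nrow(eggs_on_leaf(pl, pl$abaxial, regs, significance_levels(eggs = lv)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))

  feces_lvls <- c(0.5, 0.65, 0.8, 0.95)
  fcounts <- vapply(feces_lvls, function(lv) {
    lev <- significance_levels(black_feces = lv)
    sum(vapply(regs, function(r) nrow(detect_feces(pl$abaxial, r, lev)), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(fcounts) <= 0))
})

test_that("significance levels outside the legal ranges are rejected", {
  expect_error(significance_levels(eggs = 0.7), "0.8, 0.95")
  expect_error(significance_levels(black_feces = 0.3), "0.5, 0.95")
  expect_s3_class(significance_levels(eggs = 0.95, black_feces = 0.5),
                  "significance_levels")
})

test_that("black feces are counted and measured on a synthetic leaf", {
  sp <- plant_spec(n_leaves = 1, leaf_lengths_mm = 13, eggs_per_leaf = 0L,
                   feces_per_leaf = 7L, damage_fraction_per_leaf = 0,
                   p_adaxial_feces = 0, bubble_density = 0,
                   white_feces_per_leaf = 0L, seed = 63)
  pl <- generate_plant(sp)
  regs <- order_leaves(segment_leaves(pl$abaxial))
  det <- dplyr::bind_rows(lapply(regs, function(r) detect_feces(pl$abaxial, r)))
  expect_equal(nrow(det), 7)
  truth_area <- pl$truth$totals$feces_area_mm2
  expect_lt(abs(sum(det$area_mm2) - truth_area) / truth_area, 0.10)
  expect_true(all(det$area_mm2 > 0))
})

test_that("a clean leaf yields no feces detections", {
  sp <- plant_spec(n_leaves = 1, leaf_lengths_mm = 10, eggs_per_leaf = 0L,
                   feces_per_leaf = 0L, damage_fraction_per_leaf = 0,
                   bubble_density = 0, white_feces_per_leaf = 0L, seed = 64)
  pl <- generate_plant(sp)
  regs <- order_leaves(segment_leaves(pl$abaxial))
  det <- dplyr::bind_rows(lapply(regs, function(r) detect_feces(pl$abaxial, r)))
  expect_equal(nrow(det), 0)
})

test_that("damage segmentation recovers patch areas and respects the leaf mask", {
  sp <- plant_spec(n_leaves = 1, leaf_lengths_mm = 14, eggs_per_leaf = 0L,
                   feces_per_leaf = 0L, damage_fraction_per_leaf = 0.13,
                   damage_side_overlap = 1, bubble_density = 0,
                   white_feces_per_leaf = 0L, seed = 65)
  pl <- generate_plant(sp)
  regs <- order_leaves(segment_leaves(pl$abaxial))
  dm <- segment_damage(pl$abaxial, regs[[1]])
  truth <- pl$truth$per_leaf$damage_area_mm2[pl$truth$per_leaf$side == "abaxial"]
  expect_gt(truth, 0.5)
  expect_equal(dm$area_mm2 / truth, 1, tolerance = 0.15)
  expect_true(all(regs[[1]]$mask[dm$mask]))   # mask strictly inside the leaf

  # pristine leaf: zero damage
  sp0 <- plant_spec(n_leaves = 1, leaf_lengths_mm = 10, eggs_per_leaf = 0L,
                    feces_per_leaf = 0L, damage_fraction_per_leaf = 0,
                    bubble_density = 0, white_feces_per_leaf = 0L, seed = 66)
  pl0 <- generate_plant(sp0)
  regs0 <- order_leaves(segment_leaves(pl0$abaxial))
  expect_equal(segment_damage(pl0$abaxial, regs0[[1]])$area_mm2, 0)
})

test_that("classical detectors are deterministic", {
  pl <- fixture_plant("plate5", n_leaves = 5, seed = 31)
  regs <- order_leaves(segment_leaves(pl$abaxial))
  r <- regs[[4]]
  expect_identical(detect_eggs(pl$abaxial, r), detect_eggs(pl$abaxial, r))
  expect_identical(detect_feces(pl$abaxial, r), detect_feces(pl$abaxial, r))
  expect_identical(segment_damage(pl$abaxial, r)$mask,
                   segment_damage(pl$abaxial, r)$mask)
})

test_that("detector input contracts are enforced", {
  pl <- fixture_plant("plate5", n_leaves = 5, seed = 31)
  regs <- order_leaves(segment_leaves(pl$abaxial))
  bad <- regs[[1]]
  bad$mask[] <- FALSE
  expect_error(detect_eggs(pl$abaxial, bad), "empty")
  bad_scan <- pl$abaxial
  bad_scan$um_per_px <- NA_real_
  expect_error(detect_eggs(bad_scan, regs[[1]]), "scale")
})

test_that("patch tiling pads by reflection and standardises channels", {
  img <- array(runif(256 * 256 * 3), c(256, 256, 3))
  p <- make_patches(img, patch_px = 128L)
  expect_length(p, 4)
  for (q in p) {
    for (ch in 1:3) {
      expect_equal(mean(q$patch[, , ch]), 0, tolerance = 1e-8)
      expect_equal(stats::sd(q$patch[, , ch]), 1, tolerance = 1e-6)
    }
  }
  # remainder tiling: 300 x 200 -> 3 x 2 patches
  img2 <- array(runif(300 * 200 * 3), c(300, 200, 3))
  expect_length(make_patches(img2, patch_px = 128L), 6)
})

test_that("mask dilation matches a brute-force oracle", {
  brute_dilate <- function(mask, iters) {
    for (i in seq_len(iters)) {
      out <- mask
      H <- nrow(mask); W <- ncol(mask)
      for (r in 1:H) for (cc in 1:W) {
        if (!mask[r, cc]) next
        for (dr in -1:1) for (dc in -1:1) {
          rr <- r + dr; ccc <- cc + dc
          if (rr >= 1 && rr <= H && ccc >= 1 && ccc <= W) out[rr, ccc] <- TRUE
        }
      }
      mask <- out
    }
    mask
  }
  # single centred pixel: five unit dilations give an 11 x 11 square
  img <- array(0, c(32, 32, 3))
  mask <- matrix(FALSE, 32, 32); mask[16, 16] <- TRUE
  p <- make_patches(img, mask, patch_px = 32L, dilation_iters = 5L,
                    standardize = FALSE)
  expect_equal(sum(p[[1]]$mask), 121)
  expect_equal(p[[1]]$mask, brute_dilate(mask, 5))

  # random masks against the oracle
  set.seed(7)
  for (k in 1:5) {
    m <- matrix(runif(32 * 32) < 0.05, 32, 32)
    it <- sample(0:3, 1)
    p <- make_patches(img, m, patch_px = 32L, dilation_iters = it,
                      standardize = FALSE)
    expect_equal(p[[1]]$mask, brute_dilate(m, it))
  }
  # all-zero mask stays all-zero
  p0 <- make_patches(img, matrix(FALSE, 32, 32), patch_px = 32L)
  expect_equal(sum(p0[[1]]$mask), 0)
})

test_that("dataset splitting follows the 80-10-10 rule deterministically", {
  s <- split_dataset(as.list(1:100), seed = 5)
  expect_equal(lengths(s), c(train = 80L, val = 10L, test = 10L))
  s10 <- split_dataset(as.list(1:10), seed = 5)
  expect_equal(lengths(s10), c(train = 8L, val = 1L, test = 1L))
  # disjoint and exhaustive
  all_items <- sort(unname(unlist(s)))
  expect_equal(all_items, 1:100)
  # remainder assigned train-first
  s12 <- split_dataset(as.list(1:12), seed = 5)
  expect_equal(lengths(s12), c(train = 10L, val = 1L, test = 1L))
  # determinism
  expect_identical(split_dataset(as.list(1:100), seed = 5), s)
  expect_false(identical(split_dataset(as.list(1:100), seed = 6), s))
  expect_error(split_dataset(as.list(1:2)), "3 items")
  expect_error(split_dataset(as.list(1:10), ratios = c(0.5, 0.3, 0.1)), "sum to 1")
})
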