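make_damage_mask <- function(mask, bbox, um = 21, leaf_index = 0L, side = "abaxial") {
  structure(list(leaf_index = leaf_index, side = side, mask = mask, bbox = bbox,
                 area_mm2 = sum(mask) * (um / 1000)^2, um_per_px = um),
            class = "damage_mask")
}

test_that("damage merging equals the set-arithmetic oracle", {
  # the worked example: |A| = 10, |B| = 8, |A n B| = 5 -> union 13
  a <- matrix(FALSE, 3, 5); a[1:2, ] <- TRUE                       # 10 px
  b <- matrix(FALSE, 3, 5); b[1, ] <- TRUE; b[3, 1:3] <- TRUE      # 8 px
  expect_equal(sum(a), 10); expect_equal(sum(b), 8); expect_equal(sum(a & b), 5)
  box <- c(r0 = 0, c0 = 0, r1 = 3, c1 = 5)
  um <- 1000   # 1 px = 1 mm^2 for easy reading
  m <- merge_damage(make_damage_mask(a, box, um), make_damage_mask(b, box, um))
  expect_equal(m$area_mm2, 13)
  expect_false(m$flagged)

  # randomized masks at random offsets vs the brute-force canvas oracle
  set.seed(8)
  for (k in 1:60) {
    h1 <- sample(3:8, 1); w1 <- sample(3:8, 1)
    h2 <- sample(3:8, 1); w2 <- sample(3:8, 1)
    ma <- random_mask(h1, w1); mb <- random_mask(h2, w2)
    ba <- random_box(h1, w1); bb <- random_box(h2, w2)
    got <- merge_damage(make_damage_mask(ma, ba, um), make_damage_mask(mb, bb, um))
    expect_equal(got$area_mm2, union_area_oracle(ma, ba, mb, bb))
  }
})

test_that("damage merging is commutative, idempotent, and handles empties", {
  um <- 1000
  box <- c(r0 = 2, c0 = 3, r1 = 8, c1 = 9)
  set.seed(9)
  a <- make_damage_mask(random_mask(6, 6), box, um)
  b <- make_damage_mask(random_mask(6, 6), box, um)
  expect_equal(merge_damage(a, b)$area_mm2, merge_damage(b, a)$area_mm2)
  expect_equal(merge_damage(a, a)$area_mm2, a$area_mm2)
  empty <- make_damage_mask(matrix(FALSE, 6, 6), box, um)
  expect_equal(merge_damage(a, empty)$area_mm2, a$area_mm2)
  # unpaired leaf: merged falls back to the present side, flagged
  unp <- merge_damage(a, NULL)
  expect_equal(unp$area_mm2, a$area_mm2)
  expect_true(unp$flagged)
})

test_that("registered merging de-duplicates cross-side damage on real pairs", {
  pl <- fixture_plant("plate5", n_leaves = 5, seed = 31)
  ab <- order_leaves(segment_leaves(pl$abaxial))
  ad <- order_leaves(segment_leaves(pl$adaxial))
  W <- dim(pl$abaxial$pixels)[2]
  pairs <- pair_sides(ab, ad, W)
  pr <- pairs[pairs$paired, ][1:3, ]
  for (k in seq_len(nrow(pr))) {
    r_ab <- ab[[pr$abaxial_index[k] + 1]]
    r_ad <- ad[[which(vapply(ad, function(r) r$leaf_index, integer(1)) ==
                        pr$adaxial_index[k])]]
    d_ab <- segment_damage(pl$abaxial, r_ab)
    d_ad <- segment_damage(pl$adaxial, r_ad)
    m <- merge_damage(d_ab, d_ad, r_ab, r_ad, W)
    truth <- pl$truth$per_leaf_merged$merged_damage_area_mm2[r_ab$leaf_index + 1]
    expect_lte(m$area_mm2, d_ab$area_mm2 + d_ad$area_mm2 + 1e-9)
    expect_gte(m$area_mm2, max(d_ab$area_mm2, d_ad$area_mm2) - 1e-9)
    if (truth > 0.3) expect_equal(m$area_mm2 / truth, 1, tolerance = 0.15)
  }
})

test_that("leaf quantification aggregates detections and areas per side", {
  pl <- fixture_plant("plate5", n_leaves = 5, seed = 31)
  res <- analyze_plant(pl$abaxial, pl$adaxial)
  lr <- res$leaf_results
  truth <- pl$truth$per_leaf
  expect_equal(nrow(lr), 5)
  # counts recovered (totals across the plant)
  expect_equal(res$totals$egg_count, pl$truth$totals$egg_count, tolerance = 0.11)
  expect_equal(res$totals$feces_count, pl$truth$totals$feces_count, tolerance = 0.11)
  # leaf areas track the truth within rasterisation slack
  ab_truth <- truth[truth$side == "abaxial", ]
  expect_equal(lr$leaf_area_abaxial_mm2, ab_truth$leaf_area_mm2, tolerance = 0.02)
  expect_true(all(lr$merged_damage_mm2 <=
                    lr$damage_abaxial_mm2 + lr$damage_adaxial_mm2 + 1e-9))
})

test_that("plant summaries respect oviposition-rate arithmetic", {
  lr <- tibble::tibble(
    leaf_index = 0:2,
    leaf_area_abaxial_mm2 = c(10, 12, 14), leaf_area_adaxial_mm2 = c(10, 12, 14),
    damage_abaxial_mm2 = c(1, 0, 2), damage_adaxial_mm2 = c(0.5, 0, 1),
    merged_damage_mm2 = c(1.2, 0, 2.5),
    eggs_abaxial = c(30L, 40L, 25L), eggs_adaxial = c(10L, 5L, 5L),
    feces_abaxial = c(3L, 0L, 2L), feces_adaxial = c(1L, 1L, 0L),
    feces_area_abaxial_mm2 = c(0.05, 0, 0.04), feces_area_adaxial_mm2 = c(0.01, 0.02, 0),
    paired = TRUE)
  res <- summarize_plant(lr, n_females = 10)
  expect_equal(res$totals$egg_count, 115)
  expect_equal(res$oviposition_rate, 11.5)
  # off-leaf eggs enter the total and the rate, not any leaf
  res2 <- summarize_plant(lr, n_females = 10, additional_eggs = 5)
  expect_equal(res2$totals$egg_count, 120)
  expect_equal(res2$oviposition_rate, 12.0)
  expect_equal(sum(res2$leaf_results$eggs_abaxial + res2$leaf_results$eggs_adaxial), 115)
  expect_error(summarize_plant(lr, n_females = 0), "n_females")
  # empty plant
  res0 <- summarize_plant(lr[0, ])
  expect_equal(res0$totals$egg_count, 0)
  expect_equal(res0$oviposition_rate, 0)
})

test_that("manual corrections update counts, conserve totals, and audit", {
  pl <- fixture_plant("plate5", n_leaves = 5, seed = 31)
  res <- analyze_plant(pl$abaxial, pl$adaxial)
  n0 <- res$totals$egg_count

  add1 <- correction_edit("add", "egg", "abaxial", 2L, box = c(100, 100, 106, 106))
  add2 <- correction_edit("add", "egg", "abaxial", 2L, box = c(120, 120, 126, 126))
  res2 <- apply_corrections(res, list(add1, add2))
  expect_equal(res2$totals$egg_count, n0 + 2)
  expect_length(res2$audit, 2)

  # remove one of the originals: net +1
  victim <- res$detections$id[res$detections$klass == "egg"][1]
  res3 <- apply_corrections(res2, list(correction_edit("remove", id = victim)))
  expect_equal(res3$totals$egg_count, n0 + 1)

  # conservation after every operation
  for (rr in list(res, res2, res3)) {
    expect_equal(rr$totals$egg_count,
                 sum(rr$leaf_results$eggs_abaxial + rr$leaf_results$eggs_adaxial) +
                   rr$additional_eggs)
  }

  # involution: adding then removing the added object restores the counts
  res4 <- apply_corrections(res, list(add1))
  added_id <- setdiff(res4$detections$id, res$detections$id)
  res5 <- apply_corrections(res4, list(correction_edit("remove", id = added_id)))
  expect_equal(res5$totals$egg_count, res$totals$egg_count)
  expect_equal(res5$leaf_results$eggs_abaxial, res$leaf_results$eggs_abaxial)

  expect_error(apply_corrections(res, list(correction_edit("remove", id = "nope"))),
               "nope")

  # audit log serialises as JSONL
  log_path <- withr::local_tempfile(fileext = ".jsonl")
  write_audit_log(res3, log_path)
  lines <- readLines(log_path)
  expect_length(lines, 3)
  expect_true(all(vapply(lines, function(l) jsonlite::validate(l), logical(1))))
})

test_that("area scaling follows the pixel-size arithmetic", {
  # doubling um_per_px at fixed pixel counts multiplies areas by 4
  mask <- matrix(TRUE, 5, 5)
  box <- c(r0 = 0, c0 = 0, r1 = 5, c1 = 5)
  d1 <- make_damage_mask(mask, box, um = 10)
  d2 <- make_damage_mask(mask, box, um = 20)
  expect_equal(d2$area_mm2 / d1$area_mm2, 4)
})
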