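test_that("plant specs are validated", {
  sp <- plant_spec(n_leaves = 4, seed = 1)
  expect_s3_class(sp, "plant_spec")
  expect_length(sp$eggs_per_leaf, 4)
  expect_error(plant_spec(4, leaf_lengths_mm = c(3, 5, 6, 7)), ">= 4 mm")
  expect_error(plant_spec(4, eggs_per_leaf = c(1, 2, 3)), "length")
  expect_error(plant_spec(4, p_adaxial_egg = 1.2), "probabilities")
  expect_error(plant_spec(4, damage_fraction_per_leaf = rep(0.7, 4)), "0, 0.5")
})

test_that("a symptom-free spec yields empty ground truth", {
  pl <- generate_plant(plant_spec(
    n_leaves = 2, seed = 5, eggs_per_leaf = c(0L, 0L), feces_per_leaf = c(0L, 0L),
    damage_fraction_per_leaf = c(0, 0), bubble_density = 0,
    white_feces_per_leaf = c(0L, 0L)), dpi = 600)
  expect_equal(nrow(pl$truth$objects), 0)
  expect_equal(pl$truth$totals$egg_count, 0)
  expect_equal(pl$truth$totals$damage_area_mm2, 0)
  expect_equal(pl$truth$totals$merged_damage_area_mm2, 0)
})

test_that("generation is deterministic given the seed", {
  sp <- plant_spec(n_leaves = 3, seed = 99)
  a <- generate_plant(sp, dpi = 600)
  b <- generate_plant(sp, dpi = 600)
  expect_identical(a$abaxial$pixels, b$abaxial$pixels)
  expect_identical(a$adaxial$pixels, b$adaxial$pixels)
  expect_identical(a$truth$objects, b$truth$objects)
  expect_identical(a$truth$per_leaf, b$truth$per_leaf)
})

test_that("degenerate side preference puts every egg abaxial", {
  sp <- plant_spec(n_leaves = 4, seed = 3, eggs_per_leaf = c(0L, 0L, 10L, 10L),
                   p_adaxial_egg = 0)
  pl <- generate_plant(sp, dpi = 600)
  eggs <- pl$truth$objects[pl$truth$objects$class == "egg", ]
  expect_equal(nrow(eggs), 20)
  expect_true(all(eggs$side == "abaxial"))
})

test_that("ground-truth bookkeeping: per-leaf sums equal plant totals", {
  for (seed in c(2, 8)) {
    pl <- generate_plant(plant_spec(n_leaves = 5, seed = seed), dpi = 600)
    pleaf <- pl$truth$per_leaf
    expect_equal(sum(pleaf$egg_count), pl$truth$totals$egg_count)
    expect_equal(sum(pleaf$feces_count), pl$truth$totals$feces_count)
    expect_equal(sum(pleaf$feces_area_mm2), pl$truth$totals$feces_area_mm2)
    expect_equal(sum(pleaf$damage_area_mm2), pl$truth$totals$damage_area_mm2)
    expect_equal(sum(pl$truth$per_leaf_merged$merged_damage_area_mm2),
                 pl$truth$totals$merged_damage_area_mm2)
    # merged damage is a union: bounded by the per-side sum and below by each side
    merged <- pl$truth$per_leaf_merged$merged_damage_area_mm2
    ab <- pleaf$damage_area_mm2[pleaf$side == "abaxial"]
    ad <- pleaf$damage_area_mm2[pleaf$side == "adaxial"]
    expect_true(all(merged <= ab + ad + 1e-9))
    expect_true(all(merged >= pmax(ab, ad) - 1e-9))
    # every on-leaf object centre lies inside its leaf mask
    obj <- pl$truth$objects
    for (k in seq_len(nrow(obj))) {
      if (is.na(obj$leaf_index[k])) next
      lm <- pl$truth$leaf_masks[[obj$side[k]]][[obj$leaf_index[k] + 1]]
      rr <- round(obj$row[k]) - lm$bbox[["r0"]]
      cc <- round(obj$col[k]) - lm$bbox[["c0"]]
      expect_true(lm$mask[rr + 1, cc + 1])
    }
  }
})

test_that("egg side assignment follows the Bernoulli preference", {
  # >= 1000 eggs across several seeded plants at p = 1/6
  sides <- character(0)
  for (seed in 1:6) {
    sp <- plant_spec(n_leaves = 4, leaf_lengths_mm = c(14, 15, 16, 17),
                     eggs_per_leaf = rep(45L, 4), feces_per_leaf = rep(0L, 4),
                     damage_fraction_per_leaf = rep(0, 4), seed = seed)
    layout <- mitescan:::with_seed(sp$seed, mitescan:::build_layout(sp, ms_config()))
    sides <- c(sides, vapply(layout$eggs, function(e) e$side, ""))
  }
  n <- length(sides)
  expect_gte(n, 1000)
  ci <- stats::binom.test(sum(sides == "adaxial"), n, p = 1 / 6,
                          conf.level = 0.99)$conf.int
  expect_true(ci[1] <= 1 / 6 && 1 / 6 <= ci[2])
})

test_that("rendering is scale-consistent across dpi", {
  # enough damage area that rasterisation error stays well under 1%
  sp <- plant_spec(n_leaves = 3, leaf_lengths_mm = c(12, 14, 16),
                   damage_fraction_per_leaf = rep(0.12, 3), seed = 17)
  lo <- generate_plant(sp, dpi = 600)
  hi <- generate_plant(sp, dpi = 1200)
  expect_equal(dim(hi$abaxial$pixels)[1] / dim(lo$abaxial$pixels)[1], 2, tolerance = 0.01)
  # physical truth is unchanged within 1%
  expect_equal(hi$truth$totals$leaf_area_mm2, lo$truth$totals$leaf_area_mm2,
               tolerance = 0.01)
  expect_equal(hi$truth$totals$damage_area_mm2, lo$truth$totals$damage_area_mm2,
               tolerance = 0.01)
  expect_equal(hi$truth$totals$egg_count, lo$truth$totals$egg_count)
})

test_that("infeasible symptom loads fail with a diagnostic", {
  expect_error(
    generate_plant(plant_spec(n_leaves = 1, leaf_lengths_mm = 4,
                              eggs_per_leaf = 400L, feces_per_leaf = 0L,
                              damage_fraction_per_leaf = 0, seed = 1), dpi = 600),
    "cannot fit")
})

test_that("experiment generation draws per-ecotype symptom levels", {
  des <- experiment_design(c("Col-0", "Stp-0"),
                           damage_fraction_mean = c(0.02, 0.08))
  ex <- generate_experiment(des, n_plants_per_ecotype = 6, seed = 4)
  expect_equal(nrow(ex$plants), 12)
  expect_setequal(unique(ex$plants$ecotype), c("Col-0", "Stp-0"))
  # determinism
  ex2 <- generate_experiment(des, n_plants_per_ecotype = 6, seed = 4)
  expect_identical(ex$plants, ex2$plants)
  # per-plant truth is internally consistent
  expect_equal(ex$plants$egg_count, ex$plants$eggs_abaxial + ex$plants$eggs_adaxial)
  expect_equal(ex$plants$oviposition_rate, ex$plants$egg_count / 10)
  expect_equal(ex$plants$damage_area_mm2,
               vapply(ex$plants$per_leaf_damage, sum, numeric(1)))
  expect_error(generate_experiment(des, n_plants_per_ecotype = 1), ">= 2")
  expect_error(generate_experiment(des, reference_label = "Xx-9"), "reference")
})

test_that("under identical parameters two ecotypes differ only by noise", {
  # equality not rejected in >= 90% of seeded runs at alpha 0.05
  des <- experiment_design(c("Col-0", "B"))
  rejected <- 0
  for (s in 1:40) {
    ex <- generate_experiment(des, n_plants_per_ecotype = 6, seed = 100 + s)
    p <- stats::t.test(damage_area_mm2 ~ ecotype, data = ex$plants)$p.value
    if (p < 0.05) rejected <- rejected + 1
  }
  expect_lte(rejected / 40, 0.10)
})

test_that("experiment means converge to the design (law of large numbers)", {
  des <- experiment_design("Col-0", damage_fraction_mean = 0.05)
  ex <- generate_experiment(des, n_plants_per_ecotype = 60, n_reference = 60,
                            seed = 9)
  x <- ex$plants$damage_area_mm2
  # expected per-plant damage: fraction x blade area, averaged over the
  # leaf-count/length distribution; compare against its own SE
  se <- stats::sd(x) / sqrt(length(x))
  # independent expectation from a much larger draw
  big <- generate_experiment(des, n_plants_per_ecotype = 300, n_reference = 300,
                             seed = 10)
  expect_lt(abs(mean(x) - mean(big$plants$damage_area_mm2)), 3 * se)
})
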