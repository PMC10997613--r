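# Susceptibility statistics across genotypes: reference-normalised
# relative values, one-way ANOVA + Tukey HSD with a compact letter
# display, dynamic ranges, and symptom distributions over consecutive
# leaves and leaf sides.

#' Normalise traits to the reference ecotype within each batch
#'
#' Each plant's trait value is divided by the mean of the reference
#' plants measured in the same repetition batch, removing between-batch
#' drift (measurements repeated weeks apart). By construction the
#' reference plants of a batch average to 1.0.
#'
#' @param table plant-level trait table with `ecotype` and `batch`
#'   columns (e.g. the `plants` table of [generate_experiment()] or
#'   [trait_table()] output).
#' @param traits columns to normalise.
#' @param reference_label reference ecotype, required in every batch.
#' @param n_reference reference plants expected per batch (fewer raises
#'   a warning; zero is an error naming the batch).
#' @return the table with the trait columns replaced by relative values.
#' @export
relative_values <- function(table,
                            traits = c("damage_area_mm2", "oviposition_rate",
                                       "feces_area_mm2"),
                            reference_label = "Col-0", n_reference = 6) {
  stopifnot(all(c("ecotype", "batch") %in% names(table)))
  traits <- intersect(traits, names(table))
  for (b in unique(table$batch)) {
    ref <- table$ecotype == reference_label & table$batch == b
    if (!any(ref))
      stop(sprintf("batch '%s' contains no '%s' reference plants", b, reference_label),
           call. = FALSE)
    if (sum(ref) < n_reference)
      warning(sprintf("batch '%s' has %d reference plants (expected %d)",
                      b, sum(ref), n_reference), call. = FALSE)
    for (tr in traits) {
      m <- mean(table[[tr]][ref])
      if (m == 0) stop(sprintf("reference mean of '%s' in batch '%s' is zero", tr, b),
                       call. = FALSE)
      table[[tr]][table$batch == b] <- table[[tr]][table$batch == b] / m
    }
  }
  table
}

# Insert-and-absorb compact letter display. `sig` is a logical matrix
# (TRUE = pair significantly different) over groups in display order.
# Returns a list of letter index sets, one per group, forming a minimal
# cover in which two groups share a letter iff they are NOT
# significantly different.
cld_letters <- function(sig) {
  k <- nrow(sig)
  # after deduplication, containment with inequality is proper subset
  absorb <- function(cols) {
    cols <- unique(lapply(cols, sort))
    drop <- rep(FALSE, length(cols))
    for (a in seq_along(cols)) for (b in seq_along(cols)) {
      if (a != b && !drop[b] && !identical(cols[[a]], cols[[b]]) &&
          all(cols[[a]] %in% cols[[b]])) drop[a] <- TRUE
    }
    cols[!drop]
  }
  cols <- list(seq_len(k))
  for (i in seq_len(max(0, k - 1))) for (j in seq_len(k)[-seq_len(i)]) {
    if (!sig[i, j]) next
    hit <- vapply(cols, function(col) i %in% col && j %in% col, logical(1))
    if (!any(hit)) next
    split_cols <- unlist(lapply(cols[hit], function(col)
      list(setdiff(col, i), setdiff(col, j))), recursive = FALSE)
    cols <- absorb(c(cols[!hit], split_cols))
  }
  cols <- cols[order(vapply(cols, min, numeric(1)))]
  lapply(seq_len(k), function(g) which(vapply(cols, function(col) g %in% col, logical(1))))
}

#' One-way ANOVA with Tukey HSD and a compact letter display
#'
#' Fits `trait ~ group`, and when the ANOVA F-test is significant at
#' `alpha`, runs all pairwise Tukey HSD comparisons; groups are then
#' lettered by the insert-and-absorb algorithm so that two groups share
#' a letter exactly when their pairwise comparison is not significant.
#' A non-significant ANOVA yields a single shared letter.
#'
#' @param table data frame with the trait and grouping columns.
#' @param trait trait column name.
#' @param group grouping column name (default `"ecotype"`).
#' @param alpha significance level for both the F-test and Tukey.
#' @return a `cld_result`: `groups` tibble (group, n, mean, se,
#'   letters), `anova_p`, `tukey` tibble (pair, p_adj, significant),
#'   `alpha`.
#' @export
anova_cld <- function(table, trait, group = "ecotype", alpha = 0.05) {
  df <- data.frame(y = table[[trait]], g = factor(table[[group]]))
  df <- df[stats::complete.cases(df), ]
  counts <- table(df$g)
  if (length(counts) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(counts < 2)) stop("every group needs at least 2 observations", call. = FALSE)

  fit <- stats::aov(y ~ g, data = df)
  anova_p <- summary(fit)[[1]][["Pr(>F)"]][1]

  lev <- levels(df$g)
  means <- tapply(df$y, df$g, mean)
  ses <- tapply(df$y, df$g, function(v) stats::sd(v) / sqrt(length(v)))
  ord <- order(-means)          # display order: most susceptible first
  lev_o <- lev[ord]
  k <- length(lev)

  sig <- matrix(FALSE, k, k, dimnames = list(lev_o, lev_o))
  tukey_tab <- tibble::tibble(group1 = character(0), group2 = character(0),
                              diff = numeric(0), p_adj = numeric(0),
                              significant = logical(0))
  if (!is.na(anova_p) && anova_p <= alpha) {
    tk <- stats::TukeyHSD(fit)$g
    # rows follow combn(levels, 2) as "second-first"; reconstructing the
    # pairs avoids parsing rownames (level names may contain hyphens)
    cmb <- utils::combn(lev, 2)
    stopifnot(nrow(tk) == ncol(cmb))
    tukey_tab <- tibble::tibble(
      group1 = cmb[2, ], group2 = cmb[1, ],
      diff = unname(tk[, "diff"]), p_adj = unname(tk[, "p adj"]),
      significant = unname(tk[, "p adj"] <= alpha))
    for (r in seq_len(nrow(tukey_tab))) {
      if (tukey_tab$significant[r]) {
        sig[tukey_tab$group1[r], tukey_tab$group2[r]] <- TRUE
        sig[tukey_tab$group2[r], tukey_tab$group1[r]] <- TRUE
      }
    }
  }
  lets <- cld_letters(sig)
  letter_str <- vapply(lets, function(ix) paste(letters[ix], collapse = ""), "")

  groups <- tibble::tibble(
    group = lev_o,
    n = as.integer(counts[lev_o]),
    mean = as.numeric(means[lev_o]),
    se = as.numeric(ses[lev_o]),
    letters = letter_str)
  structure(list(groups = groups, anova_p = anova_p, tukey = tukey_tab,
                 alpha = alpha, trait = trait),
            class = "cld_result")
}

#' @export
print.cld_result <- function(x, ...) {
  cat(sprintf("<cld_result> %s: one-way ANOVA p = %.3g (alpha %.2f)\n",
              x$trait, x$anova_p, x$alpha))
  print(as.data.frame(x$groups), row.names = FALSE)
  invisible(x)
}

#' Dynamic range of a trait across ecotypes
#'
#' Ratio of the highest to the lowest ecotype mean — the fold-spread of
#' susceptibility across the panel.
#'
#' @param table plant-level trait table.
#' @param trait trait column.
#' @param group grouping column.
#' @return the max/min ratio of group means (Inf, with a warning, when
#'   the smallest mean is zero).
#' @export
dynamic_range <- function(table, trait, group = "ecotype") {
  m <- tapply(table[[trait]], table[[group]], mean)
  if (length(m) < 2) stop("need at least 2 ecotypes", call. = FALSE)
  if (min(m) == 0) {
    warning("smallest ecotype mean is 0; dynamic range is infinite", call. = FALSE)
    return(Inf)
  }
  max(m) / min(m)
}

#' Trait distribution over consecutive leaves
#'
#' Per-leaf trait vectors (stored youngest-first, as mounted) are
#' re-indexed from the oldest leaf — the order used when inspecting
#' rosette-level symptom waves — and summarised position-wise across
#' plants. Plants with fewer leaves simply contribute nothing at the
#' positions they lack. An ANOVA + CLD across positions flags where
#' symptom load differs.
#'
#' @param table plant table with a `per_leaf_<x>` list-column.
#' @param trait one of `"damage"`, `"eggs"`, `"feces_area"` (expects the
#'   matching `per_leaf_*` column).
#' @param alpha significance level.
#' @return list: `positions` tibble (position 1 = oldest leaf, n, mean,
#'   se, letters), `cld` (the full `cld_result`, NULL if every position
#'   has < 2 plants), `profiles` (long per-plant table).
#' @export
leaf_distribution <- function(table, trait = "damage", alpha = 0.05) {
  colname <- paste0("per_leaf_", trait)
  if (!colname %in% names(table))
    stop(sprintf("table lacks the '%s' list-column", colname), call. = FALSE)
  rows <- lapply(seq_len(nrow(table)), function(i) {
    v <- rev(table[[colname]][[i]])   # oldest first
    if (!length(v)) return(NULL)
    tibble::tibble(plant = i, position = seq_along(v), value = v)
  })
  long <- dplyr::bind_rows(rows)
  pos <- dplyr::summarise(
    dplyr::group_by(long, .data$position),
    n = dplyr::n(), mean = mean(.data$value),
    se = ifelse(dplyr::n() > 1, stats::sd(.data$value) / sqrt(dplyr::n()), NA_real_),
    .groups = "drop")
  single <- is.na(pos$se)
  if (any(single))
    pos$flag <- ifelse(single, "single-plant", "")

  usable <- pos$position[pos$n >= 2]
  cld <- NULL
  if (length(usable) >= 2) {
    sub <- long[long$position %in% usable, ]
    cld <- anova_cld(sub, "value", "position", alpha)
    pos$letters <- cld$groups$letters[match(as.character(pos$position), cld$groups$group)]
  }
  list(positions = pos, cld = cld, profiles = long)
}

#' Leaf-side distribution of eggs or feces across ecotypes
#'
#' Per plant, the adaxial fraction of the trait (adaxial /
#' (adaxial + abaxial)); plants with a zero total are excluded with a
#' warning. Ecotype means ± SE plus an ANOVA + CLD across ecotypes.
#'
#' @param table plant table with per-side totals (`eggs_abaxial`/
#'   `eggs_adaxial` or `feces_area_abaxial`/`feces_area_adaxial`).
#' @param trait `"egg_count"` or `"feces_area"`.
#' @param alpha significance level.
#' @return list: `plants` (per-plant fractions), `ecotypes` tibble
#'   (mean, se, letters), `cld`.
#' @export
side_distribution <- function(table, trait = c("egg_count", "feces_area"),
                              alpha = 0.05) {
  trait <- match.arg(trait)
  cols <- if (trait == "egg_count") c("eggs_adaxial", "eggs_abaxial")
  else c("feces_area_adaxial", "feces_area_abaxial")
  stopifnot(all(cols %in% names(table)))
  tot <- table[[cols[1]]] + table[[cols[2]]]
  if (any(tot == 0))
    warning(sprintf("%d plant(s) with zero %s total excluded", sum(tot == 0), trait),
            call. = FALSE)
  keep <- tot > 0
  plants <- tibble::tibble(ecotype = table$ecotype[keep],
                           adaxial_fraction = table[[cols[1]]][keep] / tot[keep])
  eco <- dplyr::summarise(
    dplyr::group_by(plants, .data$ecotype),
    n = dplyr::n(), mean = mean(.data$adaxial_fraction),
    se = stats::sd(.data$adaxial_fraction) / sqrt(dplyr::n()), .groups = "drop")
  cld <- if (length(unique(plants$ecotype)) >= 2 && all(eco$n >= 2))
    anova_cld(plants, "adaxial_fraction", "ecotype", alpha) else NULL
  if (!is.null(cld))
    eco$letters <- cld$groups$letters[match(eco$ecotype, cld$groups$group)]
  list(plants = plants, ecotypes = eco, cld = cld)
}
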