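#' Pipeline configuration
#'
#' A single nested list drives every tunable parameter of the pipeline:
#' the filename dialect, the physical scale fallback, leaf segmentation,
#' the classical detectors and the synthetic generator. All lengths are in
#' micrometres unless the name says otherwise. `ms_config()` returns the
#' defaults, optionally overridden by named arguments (nested lists are
#' merged element-wise).
#'
#' Key entries:
#' \describe{
#'   \item{dpi}{fallback scan resolution when neither an explicit scale,
#'     a TIFF resolution tag nor a sidecar is available (default 8500,
#'     i.e. about 3 um per pixel).}
#'   \item{filename}{the underscore dialect: `tokens` names each
#'     position, `side_codes` maps the side token to abaxial/adaxial.}
#'   \item{leaf}{excess-green segmentation: morphological closing radius
#'     and the minimum leaf major-axis length in mm.}
#'   \item{eggs,feces,damage}{classical detector parameters: size gates,
#'     reference contrasts that map filter responses to [0, 1]
#'     confidences, and the fixed damage threshold.}
#'   \item{pairing}{mirror axis and the IOU threshold below which an
#'     abaxial/adaxial leaf pair is flagged unpaired.}
#' }
#'
#' @param ... named overrides, e.g. `ms_config(eggs = list(level = 0.85))`.
#' @return a named list of class `ms_config`.
#' @export
#' @examples
#' cfg <- ms_config(dpi = 1200)
#' cfg$eggs$size_gate_um
ms_config <- function(...) {
  base <- list(
    dpi = 8500,
    filename = list(
      tokens = c("side", "ecotype_label", "ecotype_index",
                 "rep_tag", "replicate", "batch", "leaf_count"),
      side_codes = c(D = "abaxial", G = "adaxial"),
      rep_tag = "I",
      batch_prefix = "K"
    ),
    leaf = list(
      min_leaf_length_mm = 4,
      closing_radius_um = 150,
      min_excess_green = 0.2
    ),
    eggs = list(
      size_gate_um = c(70, 200),
      typical_diameter_um = 125,
      min_circularity = 0.6,
      level = 0.90,
      level_range = c(0.8, 0.95),
      ref_contrast = 0.033,
      floor_contrast = 0.02,
      min_chroma = 0.10,
      max_fine_ratio = 2.2,
      max_coherence = 0.6,
      min_template_ncc = 0.55,
      bubble_rejection = TRUE
    ),
    feces = list(
      size_gate_um = c(40, 250),
      level = 0.75,
      level_range = c(0.5, 0.95),
      min_contrast = 0.10,
      ref_contrast = 0.38,
      background_sigma_um = 600
    ),
    damage = list(
      threshold = 0.11,
      opening_radius_um = 100
    ),
    pairing = list(
      mirror_axis = "vertical",
      iou_threshold = 0.5
    ),
    synth = list(
      dpi = 1200,
      egg_diameter_um = c(100, 150),
      feces_diameter_um = c(80, 250),
      bubble_diameter_um = c(80, 200),
      blur_sigma_px = 0.7,
      noise_sd = 0.008,
      spacing_mm = 2,
      margin_mm = 2
    )
  )
  modifyList(base, list(...))
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys present in the file override the defaults of [ms_config()];
#' everything else keeps its default.
#'
#' @param path path to a YAML file.
#' @return a list of class `ms_config`.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  do.call(ms_config, user)
}

#' Detector significance levels
#'
#' Confidence cutoffs for the object detectors. Eggs accept levels in
#' [0.8, 0.95] and black feces in [0.5, 0.95] — the adjustable operating
#' range of the tool; the damage segmenter has a fixed threshold and no
#' user level.
#'
#' @param eggs egg confidence cutoff in [0.8, 0.95].
#' @param black_feces black-feces confidence cutoff in [0.5, 0.95].
#' @return list of class `significance_levels`.
#' @export
#' @examples
#' significance_levels(eggs = 0.85, black_feces = 0.6)
significance_levels <- function(eggs = 0.90, black_feces = 0.75) {
  if (!is.numeric(eggs) || length(eggs) != 1 || eggs < 0.8 || eggs > 0.95)
    stop("`eggs` significance level must lie in [0.8, 0.95]", call. = FALSE)
  if (!is.numeric(black_feces) || length(black_feces) != 1 ||
      black_feces < 0.5 || black_feces > 0.95)
    stop("`black_feces` significance level must lie in [0.5, 0.95]", call. = FALSE)
  structure(list(eggs = eggs, black_feces = black_feces, damage = "fixed"),
            class = "significance_levels")
}
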