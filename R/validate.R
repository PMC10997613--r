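# Validation against reference (expert or ground-truth) annotations:
# pixel-level overlap metrics and object-level efficiency percentages.

#' Pixel-level mask agreement
#'
#' `pixel_iou()` is the Jaccard index |A ∩ B| / |A ∪ B|; two empty masks
#' agree perfectly (1.0). `pixel_accuracy()` is the fraction of pixels
#' classified identically. Both are reported by the validation layer
#' because published pixel-agreement figures do not always say which of
#' the two they are.
#'
#' @param pred,ref logical masks of identical shape.
#' @return a fraction in [0, 1].
#' @export
#' @examples
#' pixel_iou(matrix(c(TRUE, TRUE, FALSE), 1), matrix(c(TRUE, FALSE, FALSE), 1))
pixel_iou <- function(pred, ref) {
  if (!identical(dim(pred), dim(ref)))
    stop("mask shapes differ: ", paste(dim(pred), collapse = "x"), " vs ",
         paste(dim(ref), collapse = "x"), call. = FALSE)
  uni <- sum(pred | ref)
  if (uni == 0) return(1.0)
  sum(pred & ref) / uni
}

#' @rdname pixel_iou
#' @export
pixel_accuracy <- function(pred, ref) {
  if (!identical(dim(pred), dim(ref)))
    stop("mask shapes differ", call. = FALSE)
  mean(pred == ref)
}

#' Object-level efficiency of program measurements against a reference
#'
#' For each item (a leaf or plant), efficiency = program value divided
#' by the reference value, times 100. The report carries per-item
#' efficiencies, their mean and range, and a paired two-sided t-test of
#' program vs reference values at `alpha` — the conventional check that
#' the program does not differ systematically from the expert.
#' Items whose reference value is 0 are excluded with a warning
#' (efficiency is undefined there).
#'
#' @param program,expert paired numeric vectors.
#' @param ids optional item labels.
#' @param trait label stored in the report.
#' @param alpha significance level of the paired test.
#' @return an `efficiency_report`: `per_item` tibble, `mean_efficiency`,
#'   `range`, `p_value`, `significant`.
#' @export
#' @examples
#' object_efficiency(c(61, 50), c(60, 50))$per_item$efficiency
object_efficiency <- function(program, expert, ids = NULL,
                              trait = "egg_count", alpha = 0.05) {
  if (length(program) != length(expert))
    stop("program and expert series must be paired (equal length)", call. = FALSE)
  ids <- ids %||% as.character(seq_along(program))
  zero <- expert == 0
  if (any(zero)) {
    warning(sprintf("%d item(s) with reference value 0 excluded from efficiency", sum(zero)),
            call. = FALSE)
    program <- program[!zero]; expert <- expert[!zero]; ids <- ids[!zero]
  }
  if (!length(program)) stop("no items with non-zero reference value", call. = FALSE)
  eff <- program / expert * 100
  diffs <- program - expert
  p <- if (length(diffs) < 2) {
    NA_real_   # a single pair cannot support a paired test
  } else if (stats::sd(diffs) == 0) {
    if (all(diffs == 0)) 1.0 else 0.0   # constant non-zero offset
  } else stats::t.test(program, expert, paired = TRUE)$p.value
  structure(list(
    trait = trait,
    per_item = tibble::tibble(id = ids, program = program, expert = expert,
                              efficiency = eff),
    mean_efficiency = mean(eff),
    range = c(min = min(eff), max = max(eff)),
    p_value = p, alpha = alpha, significant = isTRUE(p <= alpha)),
    class = "efficiency_report")
}

#' @export
print.efficiency_report <- function(x, ...) {
  cat(sprintf("<efficiency_report> %s: mean %.2f%% (%.2f%% - %.2f%%), n = %d; paired t-test p = %.3g (%s at alpha %.2f)\n",
              x$trait, x$mean_efficiency, x$range[["min"]], x$range[["max"]],
              nrow(x$per_item), x$p_value,
              if (x$significant) "program differs from reference" else "no significant difference",
              x$alpha))
  invisible(x)
}
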