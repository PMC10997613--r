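#' Bar plot of group means with SE bars and compact letters
#'
#' The conventional susceptibility figure: one bar per ecotype (mean ±
#' SE), annotated with the compact letter display, ordered most
#' susceptible first.
#'
#' @param cld a `cld_result` from [anova_cld()].
#' @param ylab y-axis label (trait and unit).
#' @return a ggplot object.
#' @export
plot_cld <- function(cld, ylab = cld$trait) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_cld needs the ggplot2 package", call. = FALSE)
  g <- cld$groups
  g$group <- factor(g$group, levels = g$group)
  ggplot2::ggplot(g, ggplot2::aes(x = .data$group, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey70", colour = "grey30") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$se,
                                        ymax = .data$mean + .data$se),
                           width = 0.25) +
    ggplot2::geom_text(ggplot2::aes(y = .data$mean + .data$se, label = .data$letters),
                       vjust = -0.6) +
    ggplot2::labs(x = NULL, y = ylab) +
    ggplot2::theme_classic()
}
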