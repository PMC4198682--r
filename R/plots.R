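# ggplot2 autoplot methods for the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_line geom_hline
#'   facet_wrap labs theme_minimal scale_fill_manual
#' @export
ggplot2::autoplot

#' Plot a TE-subfamily enrichment report
#'
#' Bar chart of enrichment scores per subfamily and change direction; the
#' 5-fold display threshold is drawn as a dashed line and flagged subfamilies
#' are filled.
#'
#' @param object A `te_enrichment` from [te_enrichment_report()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot te_enrichment
#' @export
autoplot.te_enrichment <- function(object, ...) {
  df <- object$by_subfamily
  ggplot(df, aes(x = .data$subfamily, y = .data$es, fill = .data$flag_5fold)) +
    geom_col() +
    geom_hline(yintercept = 5, linetype = "dashed") +
    facet_wrap(~direction) +
    scale_fill_manual(values = c(`TRUE` = "firebrick", `FALSE` = "grey60"),
                      name = "> 5-fold & significant") +
    labs(x = "TE subfamily", y = "enrichment score") +
    theme_minimal()
}

#' Plot a chromosome-scale log2 fold-change profile
#'
#' @param object An `rpkm_profile` from [binned_rpkm_profile()].
#' @param ... Unused.
#' @return A ggplot object (one panel per chromosome x assay, line per type).
#' @method autoplot rpkm_profile
#' @export
autoplot.rpkm_profile <- function(object, ...) {
  stopifnot(!is.null(object$log2fc))
  ggplot(object$log2fc,
         aes(x = (.data$bin_start + .data$bin_end) / 2e6, y = .data$log2fc,
             color = .data$type)) +
    geom_line() +
    geom_hline(yintercept = 0, linetype = "dashed") +
    facet_wrap(.data$chrom ~ .data$assay, scales = "free_x") +
    labs(x = "position (Mb)", y = "log2 fold change (tumor/normal)") +
    theme_minimal()
}

#' Plot per-class DMR direction fractions
#'
#' @param object A tibble from [summarize_dmr_classes()] /
#'   [direction_fractions()].
#' @param ... Unused.
#' @return A stacked bar chart of hyper/hypo percentages per class.
#' @export
plot_direction_fractions <- function(object, ...) {
  df <- object |>
    tidyr::pivot_longer(c("pct_hyper", "pct_hypo"), names_to = "direction",
                        values_to = "pct") |>
    mutate(direction = sub("pct_", "", .data$direction))
  ggplot(df, aes(x = .data$class, y = .data$pct, fill = .data$direction)) +
    geom_col() +
    scale_fill_manual(values = c(hyper = "grey25", hypo = "grey70")) +
    labs(x = NULL, y = "% of DMRs") +
    theme_minimal()
}
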