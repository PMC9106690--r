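#' Boxplots of per-compound RSDs by condition
#'
#' One box per condition, faceted by measurement type, with the
#' repeatability threshold drawn as a dashed line.
#'
#' @param object A `repeatability_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot repeatability_summary
#' @export
autoplot.repeatability_summary <- function(object, ...) {
  d <- mutate(object$rsd,
              condition = factor(.data$condition, levels = object$conditions))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$condition, y = .data$rsd_pct)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, fill = "grey90") +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = "dashed",
                        colour = "red3") +
    ggplot2::facet_wrap(~measurement_type, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "RSD [%]",
                  title = "Per-compound repeatability by condition") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Dilution-series response curves
#'
#' Level mean response versus relative concentration on log-log axes, one
#' panel per compound, with the levels inside the linear range highlighted.
#'
#' @param object A `dilution_assessment`.
#' @param compounds Optional subset of compounds to show (default: first 12).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dilution_assessment
#' @export
autoplot.dilution_assessment <- function(object, compounds = NULL, ...) {
  d <- object$levels %>% filter(.data$surviving)
  if (is.null(compounds)) compounds <- head(unique(d$compound), 12)
  d <- filter(d, .data$compound %in% !!compounds)
  ranges <- object$assessments %>%
    select("compound", "range_min_factor", "range_max_factor")
  d <- d %>%
    left_join(ranges, by = "compound") %>%
    mutate(in_range = !is.na(.data$range_min_factor) &
             .data$dilution_factor >= .data$range_min_factor &
             .data$dilution_factor <= .data$range_max_factor)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rel_conc,
                                  y = .data$mean_response)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$in_range), size = 1.6) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "steelblue4",
                                            `FALSE` = "grey40"),
                                 name = "in linear range") +
    ggplot2::facet_wrap(~compound, scales = "free_y") +
    ggplot2::labs(x = "relative concentration (1/dilution factor)",
                  y = "mean response") +
    ggplot2::theme_bw()
}

#' Audit overview of a QC run
#'
#' Counts of removed values per filter rule and condition.
#'
#' @param object A `qc_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot qc_result
#' @export
autoplot.qc_result <- function(object, ...) {
  d <- qc_audit(object) %>% count(.data$condition, .data$rule)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$condition, y = .data$n,
                                  fill = .data$rule)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "values removed", fill = "rule",
                  title = "Filter-cascade audit") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
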