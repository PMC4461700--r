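#' Bar plot of methylation and dosage values
#'
#' The screen's standard visual: per sample and locus, paired bars for the
#' control-normalized methylation value M and dosage value D, with the
#' normal-range band drawn at `low` and `high`.
#'
#' @param measurements Output of [measure_loci()].
#' @param range A [normal_range()].
#' @param samples Optional subset of sample ids to show.
#' @return A ggplot object.
#' @export
plot_measurements <- function(measurements, range = normal_range(),
                              samples = NULL) {
  if (!is.null(samples)) {
    measurements <- measurements %>% filter(.data$sample_id %in% samples)
  }
  long <- measurements %>%
    select("sample_id", "locus", "M", "D") %>%
    tidyr::pivot_longer(c("M", "D"), names_to = "value_type",
                        values_to = "value") %>%
    mutate(value_type = factor(
      ifelse(.data$value_type == "M", "methylation", "dosage"),
      levels = c("methylation", "dosage")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$locus, y = .data$value,
                                     fill = .data$value_type)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = c(range$low, range$high),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::facet_wrap(~sample_id) +
    ggplot2::labs(x = NULL, y = "relative value (control-normalized)",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_measurements
#' @param object An `imprint_screen`.
#' @param ... Passed to [plot_measurements()].
#' @export
autoplot.imprint_screen <- function(object, ...) {
  plot_measurements(object$measurements,
                    range = do.call(normal_range, object$range), ...)
}
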