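# ggplot2 views of the validation analyses.

#' Plot a dilution series: expected vs observed VAF
#'
#' Grouped bars per dilution step, mirroring the usual limit-of-detection
#' figure of assay validations.
#'
#' @param x A `kd_dilution` from [dilution_analysis()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_dilution <- function(x, ...) {
  long <- tidyr::pivot_longer(as_tibble(x), c("expected", "observed"),
                              names_to = "series", values_to = "vaf")
  ggplot2::ggplot(long, ggplot2::aes(
    x = factor(.data$step), y = .data$vaf, fill = .data$series
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "1:1 dilution step", y = "VAF (%)", fill = NULL,
                  title = "Dilution series: expected vs observed VAF") +
    ggplot2::theme_minimal()
}

#' @rdname plot_dilution
#' @param object A `kd_dilution`.
#' @method autoplot kd_dilution
#' @export
autoplot.kd_dilution <- function(object, ...) plot_dilution(object, ...)

#' Plot replicate reproducibility
#'
#' Scatter of run-2 against run-1 VAFs with the identity line and the OLS fit.
#'
#' @param x A `kd_repro` from [reproducibility_stats()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_reproducibility <- function(x, ...) {
  ggplot2::ggplot(as_tibble(x), ggplot2::aes(.data$vaf_run1, .data$vaf_run2)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_abline(slope = attr(x, "slope"), intercept = attr(x, "intercept"),
                         colour = "steelblue") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = "VAF run 1 (%)", y = "VAF run 2 (%)",
      title = "Replicate reproducibility",
      subtitle = sprintf("slope %.4f, R² %.3f",
                         attr(x, "slope"), attr(x, "r_squared"))
    ) +
    ggplot2::theme_minimal()
}

#' @rdname plot_reproducibility
#' @param object A `kd_repro`.
#' @method autoplot kd_repro
#' @export
autoplot.kd_repro <- function(object, ...) plot_reproducibility(object, ...)

#' Plot the cohort mutation spectrum
#'
#' Bar chart of variant counts (share of all detected variants).
#'
#' @param x A `kd_cohort` from [cohort_summary()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_vaf_spectrum <- function(x, ...) {
  spec <- mutate(x$spectrum,
                 protein_change = factor(.data$protein_change,
                                         levels = rev(x$spectrum$protein_change)))
  ggplot2::ggplot(spec, ggplot2::aes(.data$protein_change, .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "variants (n)",
      title = sprintf("Mutation spectrum: %d variants in %d positive samples",
                      x$n_variants_total, x$n_positive)
    ) +
    ggplot2::theme_minimal()
}

#' @rdname plot_vaf_spectrum
#' @param object A `kd_cohort`.
#' @method autoplot kd_cohort
#' @export
autoplot.kd_cohort <- function(object, ...) plot_vaf_spectrum(object, ...)
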