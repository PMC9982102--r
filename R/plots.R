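#' Scatter plot of a heterosis predictor against heterosis
#'
#' One point per cross (or per parent mean), with the least-squares line and
#' its R-squared in the subtitle — the standard way these predictor-response
#' relationships are displayed.
#'
#' @param data Tibble holding both columns (e.g. [score_all()] joined to
#'   [compute_heterosis()], or an [aggregate_by_parent()] table).
#' @param predictor,response Column names (strings), e.g. `"n_het_peus"` and
#'   `"mph"`.
#' @return A ggplot object.
#' @export
plot_predictor <- function(data, predictor = "n_het_peus", response = "mph") {
  data <- as_tibble(data)
  stopifnot(all(c(predictor, response) %in% names(data)))
  ok <- complete.cases(data[[predictor]], data[[response]])
  fit <- regress(data[[predictor]][ok], data[[response]][ok])
  ggplot2::ggplot(data[ok, ],
                  ggplot2::aes(x = .data[[predictor]], y = .data[[response]])) +
    ggplot2::geom_point(colour = "grey30") +
    ggplot2::geom_abline(slope = fit$slope, intercept = fit$intercept,
                         colour = "firebrick") +
    ggplot2::labs(
      subtitle = sprintf("R² = %.2f", fit$r_squared),
      x = predictor, y = response
    ) +
    ggplot2::theme_minimal()
}

#' Bar plot of PEUS SNP counts by category
#'
#' @param ann Annotation tibble from [annotate_matrix()].
#' @return A ggplot object.
#' @export
plot_category_counts <- function(ann) {
  counts <- peus_category_counts(ann) |>
    filter(.data$category != "is_peus")
  ggplot2::ggplot(counts,
                  ggplot2::aes(x = stats::reorder(.data$category, -.data$n_snps),
                               y = .data$n_snps)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "PEUS SNPs") +
    ggplot2::theme_minimal()
}

#' Per-location correlation coefficients of both predictors
#'
#' Dot plot comparing, by location and heterosis type, the correlation with
#' heterosis of the heterozygous PEUS SNP count versus genetic distance.
#'
#' @param per_location Per-location correlation tibble as produced by
#'   [run_pipeline()] (columns `location`, `predictor`, `response`, `r`).
#' @return A ggplot object.
#' @export
plot_correlation_comparison <- function(per_location) {
  ggplot2::ggplot(per_location,
                  ggplot2::aes(x = .data$location, y = .data$r,
                               colour = .data$predictor,
                               shape = .data$response)) +
    ggplot2::geom_point(size = 3,
                        position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::labs(y = "Pearson r with heterosis", x = NULL) +
    ggplot2::theme_minimal()
}
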