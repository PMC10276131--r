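#' Plot barcode frequency trajectories from a simulation
#'
#' One line per lineage on a log10 frequency axis, coloured by genotype and
#' facetted by batch/replicate — the standard view of a pooled competition,
#' where adaptive lineages rise and the references are diluted out.
#'
#' @param object A `competition_sim`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot competition_sim
#' @export
autoplot.competition_sim <- function(object, ...) {
  dat <- dplyr::left_join(
    object$trajectories,
    object$pool[, c("barcode_id", "genotype_label")],
    by = "barcode_id"
  )
  ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$timepoint, y = .data$frequency,
    group = .data$barcode_id, colour = .data$genotype_label
  )) +
    ggplot2::geom_line(alpha = 0.5, linewidth = 0.3) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$batch_id),
      cols = ggplot2::vars(.data$replicate_id)
    ) +
    ggplot2::labs(x = "time (transfer intervals)", y = "barcode frequency",
                  colour = "genotype") +
    ggplot2::theme_minimal()
}

#' Plot fitness estimates with uncertainty
#'
#' Lineages ranked by estimated fitness, with +/- 2 SE intervals; reference
#' lineages highlighted.
#'
#' @param object A `fitness_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fitness_fit
#' @export
autoplot.fitness_fit <- function(object, ...) {
  est <- dplyr::arrange(object$estimates, .data$s_hat)
  est$rank <- seq_len(nrow(est))
  ggplot2::ggplot(est, ggplot2::aes(x = .data$rank, y = .data$s_hat,
                                    colour = .data$is_reference)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$s_hat - 2 * .data$std_error,
      ymax = .data$s_hat + 2 * .data$std_error
    ), size = 0.2) +
    ggplot2::labs(x = "lineage (ranked)", y = "fitness (log slope / interval)",
                  colour = "reference") +
    ggplot2::theme_minimal()
}

#' Plot the three variance-decomposition categories
#'
#' Notched boxplots of the SD observations in the within-experiment,
#' across-replicate, and across-batch categories.
#'
#' @param object A `variance_decomposition`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot variance_decomposition
#' @export
autoplot.variance_decomposition <- function(object, ...) {
  dat <- tidy(object)
  dat$category <- factor(dat$category, levels = c(
    "within_experiment", "across_replicate", "across_batch"))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$category, y = .data$sd)) +
    ggplot2::geom_boxplot(notch = TRUE, outlier.size = 0.5) +
    ggplot2::labs(x = NULL, y = "SD of fitness measurements") +
    ggplot2::theme_minimal()
}

#' Plot a misassignment report as stacked proportions
#'
#' Two bars: correct vs misassigned over mapped reads, and the mechanism
#' breakdown within misassigned reads.
#'
#' @param object A `misassignment_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot misassignment_report
#' @export
autoplot.misassignment_report <- function(object, ...) {
  top <- tibble::tibble(
    panel = "all mapped reads",
    class = c("correct", "misassigned"),
    fraction = c(object$correct_fraction, object$misassigned_fraction)
  )
  bottom <- tibble::tibble(
    panel = "misassigned reads",
    class = object$breakdown$swap_class,
    fraction = object$breakdown$fraction_of_misassigned
  )
  dat <- dplyr::bind_rows(top, bottom)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$panel, y = .data$fraction,
                                    fill = .data$class)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = NULL, y = "proportion", fill = NULL) +
    ggplot2::theme_minimal()
}
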