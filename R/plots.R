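# ggplot2 summaries of the pipeline's result tables.

#' Plot the F_ROH distribution by phenotype
#'
#' Histogram of the genomic inbreeding coefficient with the consanguinity
#' cut-off (0.0156) marked.
#'
#' @param metrics tibble from [summarize_roh()].
#' @param sample_sheet optional sheet supplying `phenotype` fill groups.
#' @return A ggplot object.
#' @export
plot_froh <- function(metrics, sample_sheet = NULL) {
  df <- metrics
  if (!is.null(sample_sheet)) {
    df <- left_join(df, sample_sheet[c("sample_id", "phenotype")],
                    by = "sample_id")
  } else {
    df$phenotype <- "all"
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$f_roh, fill = .data$phenotype)) +
    ggplot2::geom_histogram(bins = 40, position = "identity", alpha = 0.6) +
    ggplot2::geom_vline(xintercept = CONSANGUINITY_F_ROH, linetype = "dashed") +
    ggplot2::labs(x = expression(F[ROH]), y = "individuals",
                  title = "Genomic inbreeding coefficient",
                  subtitle = "dashed line: consanguinity cut-off 0.0156") +
    ggplot2::theme_minimal()
}

#' Plot ROH segment positions along chromosomes
#'
#' One horizontal bar per segment, faceted by chromosome.
#'
#' @param segments segment tibble from [call_roh_cohort()].
#' @return A ggplot object.
#' @export
plot_roh_segments <- function(segments) {
  df <- mutate(segments, sample = factor(.data$sample_id))
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(ggplot2::aes(
      x = .data$start_bp / 1e6, xend = .data$end_bp / 1e6,
      y = .data$sample, yend = .data$sample
    ), linewidth = 1.5) +
    ggplot2::facet_wrap(~chrom, scales = "free_x", labeller = ggplot2::label_both) +
    ggplot2::labs(x = "position (Mb)", y = NULL,
                  title = "Runs of homozygosity") +
    ggplot2::theme_minimal()
}

#' Forest plot of an association battery
#'
#' Coefficient and 95% Wald interval per contrast, faceted by predictor.
#'
#' @param object a `roh_battery` tibble from [run_association_battery()].
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot roh_battery
#' @export
autoplot.roh_battery <- function(object, ...) {
  df <- filter(object, !is.na(.data$beta))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$beta, y = .data$contrast,
    xmin = .data$beta - 1.96 * .data$se, xmax = .data$beta + 1.96 * .data$se,
    colour = .data$excl_recessive
  )) +
    ggplot2::geom_pointrange(position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::facet_wrap(~predictor, scales = "free_x") +
    ggplot2::labs(x = "coefficient (95% Wald CI)", y = NULL,
                  colour = "recessive genes\nexcluded",
                  title = "Homozygosity burden association") +
    ggplot2::theme_minimal()
}
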