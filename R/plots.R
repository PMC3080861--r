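#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the admixture-LD decay curve and fitted exponential
#'
#' @param object A `rolloff_date` object.
#' @param ... Unused.
#' @return A ggplot: binned correlation against genetic distance (cM),
#'   the fitted `A exp(-n d)` curve, and the lower fit bound.
#' @method autoplot rolloff_date
#' @export
autoplot.rolloff_date <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_cm, y = .data$corr)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8, na.rm = TRUE) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "firebrick") +
    ggplot2::geom_vline(xintercept = object$fit_range_cm[1],
                        linetype = "dashed", colour = "grey50") +
    ggplot2::labs(
      x = "genetic distance (cM)",
      y = "correlation of LD score with weight product",
      title = sprintf("Admixture LD decay: %.1f ± %.1f generations",
                      object$date, object$se)
    ) +
    ggplot2::theme_minimal()
}

#' Plot true local-ancestry tracts of a simulated cohort
#'
#' One horizontal lane per admixed haploid chromosome copy, coloured by
#' donor-pool ancestry — a direct picture of the mosaic the simulator
#' built.
#'
#' @param cohort An `admix_cohort` object.
#' @param chrom Chromosome to draw (default: first).
#' @return A ggplot.
#' @export
plot_tracts <- function(cohort, chrom = NULL) {
  chrom <- chrom %||% cohort$tracts$chrom[1]
  df <- cohort$tracts %>% filter(.data$chrom == !!chrom)
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$start_m * 100, xend = .data$end_m * 100,
                   y = .data$haploid, yend = .data$haploid,
                   colour = .data$ancestry),
      linewidth = 3
    ) +
    ggplot2::scale_colour_manual(values = c(A = "#1b9e77", B = "#7570b3")) +
    ggplot2::labs(x = "genetic position (cM)", y = "admixed haploid",
                  title = sprintf("True ancestry tracts, chromosome %s", chrom)) +
    ggplot2::theme_minimal()
}

#' Forest-style plot of admixture dates by group
#'
#' @param data Date table with `population`, `date`, `se` and a grouping
#'   column (e.g. [west_eurasian_dates()]).
#' @param group Grouping column name (default `"group"`).
#' @return A ggplot of dates with +/- 1 SE bars, facetted by group.
#' @export
plot_date_table <- function(data, group = "group") {
  df <- data %>% filter(!is.na(.data[[group]]))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$date, y = stats::reorder(.data$population, .data$date)
  )) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$date - .data$se, xmax = .data$date + .data$se),
      height = 0.2
    ) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data[[group]]),
                        scales = "free_y", space = "free_y") +
    ggplot2::labs(x = "admixture date (generations)", y = NULL) +
    ggplot2::theme_minimal()
}
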