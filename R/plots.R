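#' Plot mean site rates with replicate spread
#'
#' Column chart of mean N2-fixation rate per station with +/- 1 sd error
#' bars, the standard presentation for triplicate bottle incubations.
#'
#' @param site_rates Tibble from [site_summary()].
#' @return A ggplot object.
#' @export
plot_site_rates <- function(site_rates) {
  ggplot2::ggplot(site_rates,
                  ggplot2::aes(x = .data$station, y = .data$mean_rate)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(.data$mean_rate - .data$sd_rate, 0),
                   ymax = .data$mean_rate + .data$sd_rate),
      width = 0.25, na.rm = TRUE) +
    ggplot2::labs(x = NULL,
                  y = expression(N[2]~fixation~(nmol~N~L^-1~d^-1))) +
    ggplot2::theme_minimal()
}

#' Stacked relative-abundance profile
#'
#' Community composition per sample as stacked proportions; pair with the
#' `other_threshold` argument of [relative_abundance()] to collapse rare
#' OTUs first.
#'
#' @param rel Tibble from [relative_abundance()].
#' @param taxonomy Optional taxonomy sidecar (`otu_id`, `cluster`): when
#'   given, fill is by nifH cluster rather than OTU.
#' @return A ggplot object.
#' @export
plot_relative_abundance <- function(rel, taxonomy = NULL) {
  long <- tidyr::pivot_longer(rel, -"sample_id", names_to = "otu_id",
                              values_to = "proportion")
  if (!is.null(taxonomy)) {
    long <- dplyr::left_join(long, taxonomy[c("otu_id", "cluster")],
                             by = "otu_id") |>
      dplyr::mutate(fill_by = dplyr::coalesce(.data$cluster, "Other"))
  } else {
    long$fill_by <- long$otu_id
  }
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample_id,
                                     y = .data$proportion,
                                     fill = .data$fill_by)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = NULL, y = "Relative abundance", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot per-sample Shannon diversity
#'
#' @param diversity Tibble from [shannon_diversity()].
#' @return A ggplot object.
#' @export
plot_diversity <- function(diversity) {
  ggplot2::ggplot(diversity, ggplot2::aes(x = .data$sample_id,
                                          y = .data$shannon)) +
    ggplot2::geom_point(size = 3, colour = "darkgreen") +
    ggplot2::labs(x = NULL, y = "Shannon diversity (H')") +
    ggplot2::theme_minimal()
}

#' @describeIn distlm Bar chart of the proportion of community variation
#'   explained by each predictor, annotated with permutation significance.
#' @param object A `distlm` object.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.distlm <- function(object, ...) {
  d <- tidy(object) |>
    dplyr::mutate(significant = .data$p_value < 0.05)
  ggplot2::ggplot(d, ggplot2::aes(
    x = stats::reorder(.data$term, .data$prop_explained),
    y = .data$prop_explained, fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "firebrick",
                                          `FALSE` = "grey60"),
                               name = "p < 0.05") +
    ggplot2::labs(x = NULL, y = "Proportion of variation explained") +
    ggplot2::theme_minimal()
}

#' @describeIn fit_standard_curve Standard-curve diagnostic: the fitted
#'   log-linear response with its efficiency annotation.
#' @param object A `qpcr_curve`.
#' @exportS3Method ggplot2::autoplot
autoplot.qpcr_curve <- function(object, ...) {
  lg <- seq(0, 8, length.out = 50)
  line <- tibble::tibble(log10_copies = lg,
                         cq = object$intercept + object$slope * lg)
  ggplot2::ggplot(line, ggplot2::aes(x = .data$log10_copies, y = .data$cq)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_hline(yintercept = object$cq_limit, linetype = "dashed") +
    ggplot2::labs(
      title = sprintf("%s: efficiency %.2f%%, R² = %.4f",
                      object$target, object$efficiency, object$r_squared),
      x = "log10(copies per reaction)", y = "Cq (cycles)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
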