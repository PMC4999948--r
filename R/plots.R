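#' Plot called DMRs along the genome
#'
#' Candidate regions drawn at their log2 depth ratio versus genomic
#' position, reported DMRs highlighted by direction.
#'
#' @param object a `dmr_result`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot dmr_result
#' @export
autoplot.dmr_result <- function(object, ...) {
  cand <- tidy(object, all = TRUE)
  cfg <- attr(object, "config")
  if (!nrow(cand)) {
    return(ggplot2::ggplot() +
             ggplot2::annotate("text", x = 0, y = 0,
                               label = "no candidate regions") +
             ggplot2::theme_void())
  }
  cand$called <- cand$q < cfg$fdr_threshold
  ggplot2::ggplot(cand,
                  ggplot2::aes(x = (.data$start + .data$end) / 2,
                               y = .data$log2_ratio)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$direction,
                                     alpha = .data$called)) +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.25),
                                guide = "none") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "log2(B / A) mean depth",
                  colour = NULL,
                  title = sprintf("%d DMRs at q < %g", nrow(object),
                                  cfg$fdr_threshold)) +
    ggplot2::theme_minimal()
}

#' Plot a windowed chromosome profile
#'
#' @param profile output of [windowed_profile()].
#' @param metrics columns to facet over.
#' @return a ggplot.
#' @export
plot_windowed_profile <- function(profile,
                                  metrics = c("mean_norm_depth",
                                              "gene_density",
                                              "cgi_density")) {
  metrics <- intersect(metrics, names(profile))
  long <- profile |>
    tidyr::pivot_longer(all_of(metrics), names_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$start / 1e6,
                                     y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(metric ~ chrom, scales = "free_y") +
    ggplot2::labs(x = "position (Mb)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot subtelomeric vs non-subtelomeric methylation
#'
#' @param zones output of [zone_methylation()].
#' @return a ggplot.
#' @export
plot_zone_methylation <- function(zones) {
  long <- zones |>
    tidyr::pivot_longer(c("mean_a", "mean_b"), names_to = "group",
                        values_to = "mean_norm_depth") |>
    mutate(group = toupper(sub("mean_", "", .data$group)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$chrom,
                                     y = .data$mean_norm_depth,
                                     fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~zone, ncol = 1) +
    ggplot2::labs(x = NULL, y = "mean normalized depth", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Scatter of methylation vs expression differences
#'
#' @param fm [feature_methylation()] output.
#' @param de [differential_expression()] output.
#' @param compartment compartment of `fm` to plot.
#' @return a ggplot.
#' @export
plot_meth_expr <- function(fm, de, compartment = "promoter") {
  d <- fm |>
    filter(.data$compartment == .env$compartment, .data$n_cpgs > 0) |>
    inner_join(de, by = "feature_id")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$meth_diff, y = .data$lfc)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick") +
    ggplot2::labs(x = "methylation difference (B - A)",
                  y = "log2 fold change (B - A)",
                  title = compartment) +
    ggplot2::theme_minimal()
}
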