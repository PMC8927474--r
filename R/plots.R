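# ggplot2 visualizations for depth profiles and evaluation reports.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Plot a depth profile against a reference panel
#'
#' Interval depths per contig, with the panel mean and a two-standard-
#' deviation band when a panel is supplied, and candidate regions shaded.
#'
#' @param profile a `depth_profile`.
#' @param panel optional `reference_panel` with matching binning.
#' @param regions optional region tibble (`chrom`, `start`, `end`) to
#'   highlight.
#' @return A ggplot object.
#' @export
plot_depth_profile <- function(profile, panel = NULL, regions = NULL) {
  df <- as_tibble(profile)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$start / 1e6,
                                        y = .data$depth)) +
    ggplot2::geom_step(linewidth = 0.3, colour = "grey30") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mbp)", y = "depth (fold coverage)") +
    ggplot2::theme_minimal()
  if (!is.null(panel)) {
    pdf_ <- as_tibble(panel)
    pdf_$chrom <- df$chrom
    pdf_$start <- df$start
    p <- p +
      ggplot2::geom_ribbon(data = pdf_,
                           ggplot2::aes(x = .data$start / 1e6,
                                        ymin = pmax(0, .data$mu - 2 * .data$sigma),
                                        ymax = .data$mu + 2 * .data$sigma),
                           inherit.aes = FALSE, alpha = 0.2, fill = "steelblue") +
      ggplot2::geom_line(data = pdf_,
                         ggplot2::aes(x = .data$start / 1e6, y = .data$mu),
                         inherit.aes = FALSE, colour = "steelblue",
                         linewidth = 0.3)
  }
  if (!is.null(regions) && nrow(regions) > 0) {
    p <- p + ggplot2::geom_rect(data = regions,
                                ggplot2::aes(xmin = .data$start / 1e6,
                                             xmax = .data$end / 1e6),
                                ymin = -Inf, ymax = Inf, inherit.aes = FALSE,
                                alpha = 0.15, fill = "firebrick")
  }
  p
}

#' Autoplot per-type evaluation results
#'
#' Bars of true positives and false negatives per SV type at the report's
#' breakpoint allowance.
#'
#' @param object an `sv_eval` from [match_calls()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.sv_eval <- function(object, ...) {
  df <- tidyr::pivot_longer(object$summary, c("tp", "fn"),
                            names_to = "outcome", values_to = "n")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$svtype, y = .data$n,
                                   fill = .data$outcome)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(tp = "seagreen", fn = "firebrick")) +
    ggplot2::labs(x = NULL, y = "truth SVs",
                  title = sprintf("breakpoint allowance %d bp", object$max_dist)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
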