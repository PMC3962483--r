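# ggplot2 visualizations for the main result types.

#' @export
autoplot.het_profile <- function(object, threshold = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = (.data$start + .data$end) / 2,
                                            y = .data$het)) +
    ggplot2::geom_step() +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "heterozygous sites per bp")
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = 2)
  }
  p
}

#' @export
autoplot.ehh_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$pos, y = .data$ehh)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(xintercept = object$pos[object$direction == 0],
                        linetype = 3) +
    ggplot2::labs(x = "position (bp)", y = "EHH",
                  title = sprintf("EHH, %s core allele",
                                  attr(object, "core_allele")))
}

#' @export
autoplot.ihs_scan <- function(object, ...) {
  y <- if ("std_ihs" %in% names(object)) "std_ihs" else "ihs_unstd"
  ggplot2::ggplot(object, ggplot2::aes(x = .data$pos, y = .data[[y]])) +
    ggplot2::geom_point(alpha = 0.5, size = 0.6) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (bp)",
                  y = if (y == "std_ihs") "standardized iHS" else "unstandardized iHS")
}

#' @export
autoplot.ld_decay <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$bin_mid, y = .data$median_r2)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "pair distance (bp)", y = expression(median ~ r^2))
  plateau <- attr(object, "plateau_bp")
  if (!is.null(plateau) && !is.na(plateau)) {
    p <- p + ggplot2::geom_vline(xintercept = plateau, linetype = 2)
  }
  p
}

#' Plot binned population-size trajectories
#'
#' @param binned Output of [bin_and_combine()].
#' @return A ggplot.
#' @export
plot_ne_trajectory <- function(binned) {
  ggplot2::ggplot(binned, ggplot2::aes(x = .data$years, y = .data$median_ne)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q25, ymax = .data$q75),
                         alpha = 0.3) +
    ggplot2::geom_step() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "years before present", y = "effective population size (diploid)")
}
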