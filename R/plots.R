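#' Plot a coverage or composite depth track
#'
#' Depth against genomic position, with optional locus annotation: the
#' transcript span is shaded and the SNP marked with a vertical line, the
#' layout used for composite-signal figures.
#'
#' @param cov Coverage tibble ([compute_depth()]) or composite
#'   ([collapse_coverage()]).
#' @param locus Optional [locus_annotation()] (or [simulated_locus()]) to
#'   overlay.
#' @return A ggplot object.
#' @export
plot_coverage <- function(cov, locus = NULL) {
  depth_col <- if ("total_depth" %in% names(cov)) "total_depth" else "depth"
  p <- ggplot2::ggplot(cov, ggplot2::aes(x = .data$pos, y = .data[[depth_col]])) +
    ggplot2::geom_area(fill = "grey35") +
    ggplot2::labs(x = paste0("position on ", cov$chrom[1]),
                  y = "depth of coverage") +
    ggplot2::theme_minimal()
  if (!is.null(locus)) {
    if (inherits(locus, "simulated_locus")) {
      tx <- transcript_region(locus)
      snp <- locus$transcript_start + locus$snp_offset - 1L
    } else {
      tx <- locus$transcript
      snp <- locus$snp_pos
    }
    p <- p +
      ggplot2::annotate("rect", xmin = tx$start, xmax = tx$end - 1L,
                        ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "orange") +
      ggplot2::geom_vline(xintercept = snp, colour = "red", linewidth = 0.3)
  }
  p
}

#' Plot a two-group coverage comparison
#'
#' Mirrored normalized depth tracks (group b drawn downward) from
#' [compare_groups()].
#'
#' @param comparison Tibble from [compare_groups()].
#' @return A ggplot object.
#' @export
plot_group_comparison <- function(comparison) {
  norm_cols <- grep("^norm_", names(comparison), value = TRUE)
  stopifnot(length(norm_cols) == 2)
  labels <- sub("^norm_", "", norm_cols)
  df <- tibble::tibble(
    pos = rep(comparison$pos, 2),
    depth = c(comparison[[norm_cols[1]]], -comparison[[norm_cols[2]]]),
    group = rep(labels, each = nrow(comparison))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$depth,
                                   fill = .data$group)) +
    ggplot2::geom_area(position = "identity") +
    ggplot2::labs(x = paste0("position on ", comparison$chrom[1]),
                  y = "normalized depth (per million, group b mirrored)") +
    ggplot2::theme_minimal()
}

#' Plot a detection-power curve
#'
#' Detection probability against the number of collapsed datasets, with
#' binomial standard-error ribbons, from [power_experiment()].
#'
#' @param power Tibble from [power_experiment()].
#' @return A ggplot object.
#' @export
plot_power_curve <- function(power) {
  p <- power$detection_probability
  se <- sqrt(pmax(p * (1 - p), 0) / power$reps)
  df <- dplyr::mutate(power, lo = pmax(0, p - 1.96 * se), hi = pmin(1, p + 1.96 * se))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_datasets,
                                   y = .data$detection_probability)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.2) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "datasets collapsed", y = "detection probability") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Standard-curve plot for an amplification-efficiency fit
#'
#' @param object An `amp_efficiency` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot amp_efficiency
#' @export
autoplot.amp_efficiency <- function(object, ...) {
  df <- object$fit$model
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log10_input, y = .data$ct)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::labs(
      x = "log10 relative input", y = "Ct",
      subtitle = sprintf("slope %.3f, efficiency %.1f%%",
                         object$slope, object$efficiency_percent)) +
    ggplot2::theme_minimal()
}
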