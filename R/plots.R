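#' Plot PCA scores colored by condition
#'
#' @param object A `qc_pca` from [pca_scores()].
#' @param design Optional sample-design tibble for coloring.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot qc_pca
#' @export
autoplot.qc_pca <- function(object, design = NULL, ...) {
  df <- tidy(object)
  if (!is.null(design)) {
    df <- dplyr::left_join(df, design, by = "sample_id") |>
      dplyr::mutate(condition = as.character(condition_labels(design)))
  } else {
    df$condition <- "sample"
  }
  vf <- object$variance_fraction
  ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2,
                                   colour = .data$condition)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", 100 * vf[1]),
                  y = sprintf("PC2 (%.1f%%)", 100 * vf[2])) +
    ggplot2::theme_minimal()
}

#' Plot the per-exon log2-ratio profile of one transcript
#'
#' Probesets along the 5'-to-3' axis, one line per timepoint; the ratio is
#' mean(kainate at t) minus mean(pooled controls). A splice event shows as a
#' single probeset deviating from an otherwise flat (or uniformly shifted)
#' profile.
#'
#' @param profiles Tibble from [exon_profiles()].
#' @param transcript_id Transcript to draw.
#' @return A ggplot.
#' @export
plot_exon_profile <- function(profiles, transcript_id) {
  df <- profiles |>
    dplyr::filter(.data$transcript_id == !!transcript_id) |>
    tidyr::pivot_longer(dplyr::starts_with("ratio_"),
                        names_to = "timepoint", values_to = "log2_ratio") |>
    dplyr::mutate(timepoint = sub("^ratio_", "", .data$timepoint))
  if (nrow(df) == 0) stop("unknown transcript: ", transcript_id)
  ggplot2::ggplot(df, ggplot2::aes(.data$probeset_order, .data$log2_ratio,
                                   colour = .data$timepoint)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = unique(df$probeset_order)) +
    ggplot2::labs(x = "probeset (5' to 3')",
                  y = "log2 ratio (kainate - pooled controls)",
                  title = transcript_id) +
    ggplot2::theme_minimal()
}

#' Volcano-style view of FIRMA probeset scores
#'
#' Sample-distribution all-sample score against the empirical FDR, called
#' probesets highlighted.
#'
#' @param object A `firma_result` from [run_firma()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot firma_result
#' @export
autoplot.firma_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$F_s, .data$fdr,
                                       colour = .data$call)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = attr(object, "cutoff"),
                        linetype = 2, colour = "grey40") +
    ggplot2::labs(x = "all-sample score (sample distribution)",
                  y = "empirical FDR") +
    ggplot2::theme_minimal()
}
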