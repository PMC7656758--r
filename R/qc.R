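#' Sample correlation over the most variable transcripts
#'
#' Selects the `top_n` transcripts with the highest standard deviation across
#' samples (ties broken by transcript id, lexicographically, for determinism)
#' and returns the sample-pairwise Pearson correlation matrix over those rows.
#' A sample with zero variance over the selected rows gets `NA` correlations.
#'
#' @param transcript_expr Transcripts x samples log2 expression matrix.
#' @param top_n Number of transcripts to use (default 1000); all are used when
#'   fewer are available.
#' @return Symmetric samples x samples correlation matrix.
#' @export
top_sd_correlation <- function(transcript_expr, top_n = 1000L) {
  stopifnot(is.matrix(transcript_expr), ncol(transcript_expr) >= 2, top_n >= 2)
  sds <- apply(transcript_expr, 1L, stats::sd)
  ord <- order(-sds, rownames(transcript_expr))
  keep <- ord[seq_len(min(top_n, nrow(transcript_expr)))]
  sub <- transcript_expr[keep, , drop = FALSE]
  suppressWarnings(stats::cor(sub, method = "pearson"))
}

#' Principal-component scores of samples
#'
#' Singular value decomposition of the row-centered transcripts x samples
#' matrix (samples as observations). Components are ordered by variance and
#' signed so that the first nonzero loading of each component is positive.
#'
#' @param expr_subset Transcripts x samples log2 expression matrix; typically
#'   restricted to a significant or high-variance transcript set.
#' @return Object of class `qc_pca`: list with `scores` (samples x
#'   components) and `variance_fraction` (per component, nonincreasing,
#'   summing to 1).
#' @export
pca_scores <- function(expr_subset) {
  stopifnot(is.matrix(expr_subset))
  if (ncol(expr_subset) < 2) stop("pca_scores needs at least 2 samples")
  x <- t(expr_subset - rowMeans(expr_subset))   # samples x transcripts, centered
  sv <- svd(x)
  scores <- sv$u %*% diag(sv$d, nrow = length(sv$d))
  # sign convention: first nonzero loading of each component positive
  for (k in seq_len(ncol(scores))) {
    v <- sv$v[, k]
    nz <- which(abs(v) > 1e-12)
    if (length(nz) > 0 && v[nz[1]] < 0) {
      scores[, k] <- -scores[, k]
      sv$v[, k] <- -v
    }
  }
  rownames(scores) <- colnames(expr_subset)
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  varfrac <- sv$d^2 / sum(sv$d^2)
  if (sum(sv$d^2) == 0) varfrac <- rep(0, length(sv$d))
  structure(list(scores = scores, variance_fraction = varfrac,
                 loadings = sv$v), class = "qc_pca")
}

#' @export
print.qc_pca <- function(x, ...) {
  cat(sprintf("<qc_pca> %d samples, %d components; PC1 %.1f%% / PC2 %.1f%%\n",
              nrow(x$scores), ncol(x$scores),
              100 * x$variance_fraction[1],
              100 * ifelse(length(x$variance_fraction) > 1,
                           x$variance_fraction[2], 0)))
  invisible(x)
}

#' @rdname pca_scores
#' @param x A `qc_pca` object.
#' @param ... Unused.
#' @method tidy qc_pca
#' @export
tidy.qc_pca <- function(x, ...) {
  as_tibble(x$scores) |>
    dplyr::mutate(sample_id = rownames(x$scores), .before = 1)
}

#' @rdname pca_scores
#' @method glance qc_pca
#' @export
glance.qc_pca <- function(x, ...) {
  tibble(n_samples = nrow(x$scores),
         n_components = ncol(x$scores),
         pc1_variance_fraction = x$variance_fraction[1],
         pc2_variance_fraction = ifelse(length(x$variance_fraction) > 1,
                                        x$variance_fraction[2], NA_real_))
}

#' Run both QC checks
#'
#' Convenience wrapper producing the correlation matrix over the most variable
#' transcripts and the PCA of an (optionally different) transcript subset.
#'
#' @param summary An [summarize_expression()] result.
#' @param top_n Transcripts for the correlation check.
#' @param pca_transcripts Optional transcript ids for the PCA (default: the
#'   same top-SD set used for the correlation matrix).
#' @return List with `correlation` and `pca` (a `qc_pca`).
#' @export
run_qc <- function(summary, top_n = 1000L, pca_transcripts = NULL) {
  stopifnot(inherits(summary, "expression_summary"))
  expr <- summary$transcript_expr
  corr <- top_sd_correlation(expr, top_n)
  sub <- if (is.null(pca_transcripts)) {
    sds <- apply(expr, 1L, stats::sd)
    ord <- order(-sds, rownames(expr))
    expr[ord[seq_len(min(top_n, nrow(expr)))], , drop = FALSE]
  } else {
    expr[intersect(pca_transcripts, rownames(expr)), , drop = FALSE]
  }
  list(correlation = corr, pca = pca_scores(sub))
}
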