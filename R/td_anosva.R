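#' Presence filter for probe-level splicing analysis
#'
#' Applies the probe/probeset/transcript filter cascade that precedes the
#' splicing tests: (i) cross-hybridizing probes are dropped; (ii) a probeset
#' counts as *present* in a sample when its mean log2 probe intensity exceeds
#' the `present_quantile` quantile of all probeset means in that sample, and
#' is kept when present in at least half the samples of at least one
#' treatment group (pooled controls, kainate 1 h, 4 h, 8 h); (iii) a
#' transcript is kept when at least half of its probesets are present in at
#' least half the samples of some group; (iv) transcripts left with fewer
#' than 3 probesets are removed.
#'
#' @param ds Log2-scale [exon_dataset()].
#' @param present_quantile Presence threshold quantile (default 0.25).
#' @return Filtered [exon_dataset()]; per-stage counts are attached as
#'   attribute `filter_stats`.
#' @export
presence_filter <- function(ds, present_quantile = 0.25) {
  stopifnot(inherits(ds, "exon_dataset"))
  if (ds$scale != "log2") stop("presence_filter expects log2-scale data")
  anno <- ds$annotation
  stats0 <- c(probes_in = nrow(anno),
              probesets_in = dplyr::n_distinct(anno$probeset_id),
              transcripts_in = dplyr::n_distinct(anno$transcript_id))

  keep_probe <- !anno$cross_hybridizing
  anno <- anno[keep_probe, , drop = FALSE]
  mat <- ds$intensities[keep_probe, , drop = FALSE]
  if (nrow(anno) == 0) {
    warning("presence filter removed all probes")
    return(empty_filtered(ds, stats0))
  }

  # probeset mean intensity per sample
  ps_means <- rowsum(mat, anno$probeset_id) /
    as.vector(table(anno$probeset_id)[sort(unique(anno$probeset_id))])
  thresh <- apply(ps_means, 2, stats::quantile, probs = present_quantile,
                  names = FALSE)
  present <- sweep(ps_means, 2, thresh, ">")

  cond <- condition_labels(ds$design)
  groups <- split(seq_len(nrow(ds$design)), cond)
  groups <- groups[lengths(groups) > 0]
  present_in_group <- vapply(groups, function(idx) {
    rowMeans(present[, idx, drop = FALSE]) >= 0.5
  }, logical(nrow(ps_means)))
  if (is.null(dim(present_in_group))) {
    present_in_group <- matrix(present_in_group, nrow = nrow(ps_means))
  }
  ps_keep <- rownames(ps_means)[rowSums(present_in_group) > 0]

  # transcript rule: >= half of its probesets present in >= half of some
  # group's samples
  ps_map <- anno |> dplyr::distinct(.data$probeset_id, .data$transcript_id)
  pig <- present_in_group[ps_map$probeset_id, , drop = FALSE]
  frac <- rowsum(pig * 1, ps_map$transcript_id) /
    as.vector(table(ps_map$transcript_id)[sort(unique(ps_map$transcript_id))])
  tx_keep <- rownames(frac)[apply(frac >= 0.5, 1, any)]

  anno2 <- anno |>
    dplyr::filter(.data$probeset_id %in% ps_keep,
                  .data$transcript_id %in% tx_keep)
  # rule (iv): >= 3 surviving probesets
  n_ps <- anno2 |>
    dplyr::distinct(.data$transcript_id, .data$probeset_id) |>
    dplyr::count(.data$transcript_id)
  tx_final <- n_ps$transcript_id[n_ps$n >= 3]
  anno2 <- anno2 |> dplyr::filter(.data$transcript_id %in% tx_final)

  if (nrow(anno2) == 0) {
    warning("presence filter removed all transcripts")
    return(empty_filtered(ds, stats0))
  }
  out <- exon_dataset(anno2, ds$design,
                      mat[anno2$probe_id, , drop = FALSE], scale = "log2")
  attr(out, "filter_stats") <- c(
    stats0,
    probes_out = nrow(anno2),
    probesets_out = dplyr::n_distinct(anno2$probeset_id),
    transcripts_out = dplyr::n_distinct(anno2$transcript_id))
  out
}

empty_filtered <- function(ds, stats0) {
  anno <- ds$annotation[0, , drop = FALSE]
  out <- structure(list(annotation = anno, design = ds$design,
                        intensities = ds$intensities[0, , drop = FALSE],
                        scale = "log2"),
                   class = "exon_dataset")
  attr(out, "filter_stats") <- c(stats0, probes_out = 0L,
                                 probesets_out = 0L, transcripts_out = 0L)
  out
}

#' Fit the probeset-by-condition interaction model for one gene
#'
#' Ordinary least squares on the probe-level log2 intensities of a single
#' transcript: intercept, probeset main effects (reference = the 5'-most
#' probeset), condition main effects over the pooled four-level condition
#' factor (reference = control; under the pooled design the treatment and
#' time main effects are confounded and enter as this single factor), and
#' the probeset-by-condition interaction whose coefficients carry the
#' splicing signal. Residual variance is taken from the full fit.
#'
#' @param y Numeric vector of log2 intensities (one entry per probe/sample pair).
#' @param probeset Factor of probeset ids, levels in 5'-to-3' order.
#' @param condition Factor of condition labels, reference level first.
#' @param transcript_id Transcript identifier carried into the result.
#' @return Object of class `anosva_fit`, or an `anosva_skip` marker (with a
#'   `reason`) when the design is rank deficient or has no residual degrees
#'   of freedom. `anosva_fit` fields:
#'   `transcript_id`, `coefficients`, `gamma` (tibble of interaction terms
#'   with `estimate`, `se`), `sigma_sq`, `df`, `fitted`, `residuals`.
#' @export
anosva_fit_gene <- function(y, probeset, condition, transcript_id = NA_character_) {
  probeset <- droplevels(as.factor(probeset))
  condition <- droplevels(as.factor(condition))
  X <- stats::model.matrix(~ probeset * condition)
  n <- length(y)
  p <- ncol(X)
  df <- n - p
  if (df <= 0) return(anosva_skip(transcript_id, "no residual degrees of freedom"))
  qrX <- qr(X)
  if (qrX$rank < p) return(anosva_skip(transcript_id, "rank-deficient design (empty cell)"))
  coef <- qr.coef(qrX, y)
  fitted <- drop(X %*% coef)
  res <- y - fitted
  sigma_sq <- sum(res^2) / df
  # chol2inv of qr.R gives (X'X)^-1 in pivoted column order
  piv <- qrX$pivot
  XtX_inv <- chol2inv(qr.R(qrX))[order(piv), order(piv), drop = FALSE]
  se <- sqrt(sigma_sq * diag(XtX_inv))
  is_gamma <- grepl(":", colnames(X), fixed = TRUE)
  gm <- tibble(
    term = colnames(X)[is_gamma],
    probeset_id = sub("^probeset(.*):condition.*$", "\\1", colnames(X)[is_gamma]),
    condition = sub("^.*:condition", "", colnames(X)[is_gamma]),
    estimate = unname(coef[is_gamma]),
    se = unname(se[is_gamma])
  )
  structure(
    list(transcript_id = transcript_id, coefficients = coef, gamma = gm,
         sigma_sq = sigma_sq, df = df, fitted = fitted, residuals = res,
         n_obs = n, n_probesets = nlevels(probeset),
         conditions = levels(condition)),
    class = "anosva_fit"
  )
}

anosva_skip <- function(transcript_id, reason) {
  structure(list(transcript_id = transcript_id, reason = reason),
            class = "anosva_skip")
}

#' @export
print.anosva_fit <- function(x, ...) {
  cat(sprintf("<anosva_fit> %s: %d probesets, %d obs, %d interaction terms, sigma^2 = %.4g (df %d)\n",
              x$transcript_id, x$n_probesets, x$n_obs, nrow(x$gamma),
              x$sigma_sq, x$df))
  invisible(x)
}

#' @rdname anosva_fit_gene
#' @param x An `anosva_fit`.
#' @param ... Unused.
#' @method tidy anosva_fit
#' @export
tidy.anosva_fit <- function(x, ...) {
  p <- interaction_pvalues(x)
  dplyr::mutate(x$gamma,
                statistic = .data$estimate / .data$se,
                p_value = p)
}

#' @rdname anosva_fit_gene
#' @method glance anosva_fit
#' @export
glance.anosva_fit <- function(x, ...) {
  tibble(transcript_id = x$transcript_id, n_obs = x$n_obs,
         n_probesets = x$n_probesets, n_terms = nrow(x$gamma),
         sigma_sq = x$sigma_sq, df = x$df)
}

#' Two-sided p-values for the interaction terms
#'
#' `t = gamma / se(gamma)` against the fit's residual degrees of freedom.
#' With zero residual variance the p-value degenerates to 0 for a nonzero
#' coefficient and 1 for a zero one.
#'
#' @param fit An `anosva_fit`.
#' @return Numeric vector of p-values, one per interaction coefficient.
#' @export
interaction_pvalues <- function(fit) {
  stopifnot(inherits(fit, "anosva_fit"), fit$df >= 1)
  g <- fit$gamma
  if (fit$sigma_sq <= 0 || any(g$se == 0)) {
    return(ifelse(abs(g$estimate) > 1e-12, 0, 1))
  }
  2 * stats::pt(-abs(g$estimate / g$se), df = fit$df)
}

#' Gene-level splice calls from per-gene interaction p-values
#'
#' Within each gene, the interaction p-values are Holm-adjusted and their
#' minimum taken as the gene-level p (a valid familywise-corrected minimum);
#' across genes those minima are BH-adjusted and genes called at `fdr`.
#' The reported top term is the argmin, ties broken by probeset order then
#' condition order.
#'
#' @param terms Tibble with columns `transcript_id`, `probeset_id`,
#'   `condition`, `estimate`, `se`, `p` (one row per interaction coefficient,
#'   probesets/conditions already in model order within gene).
#' @param fdr Across-gene FDR cutoff (default 0.05).
#' @return List: `results` (one row per gene: `transcript_id`, `p_gene`,
#'   `q_gene`, `call`, `top_probeset_id`, `top_condition`, `n_terms`) and
#'   `terms` (the input plus `holm_p`).
#' @export
gene_level_call <- function(terms, fdr = 0.05) {
  stopifnot(nrow(terms) >= 1)
  terms <- terms |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::mutate(holm_p = stats::p.adjust(.data$p, method = "holm")) |>
    dplyr::ungroup()
  results <- terms |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::summarise(
      p_gene = min(.data$holm_p),
      top_probeset_id = .data$probeset_id[which.min(.data$holm_p)],
      top_condition = .data$condition[which.min(.data$holm_p)],
      n_terms = dplyr::n(),
      .groups = "drop"
    )
  results$q_gene <- adjust_bh(results$p_gene)
  results$call <- results$q_gene <= fdr
  results <- results |>
    dplyr::select("transcript_id", "p_gene", "q_gene", "call",
                  "top_probeset_id", "top_condition", "n_terms") |>
    dplyr::arrange(.data$p_gene, .data$transcript_id)
  list(results = results, terms = terms)
}

anosva_long_data <- function(ds, timepoint = NULL) {
  design <- ds$design
  cond <- condition_labels(design)
  keep_s <- if (is.null(timepoint)) rep(TRUE, nrow(design)) else
    cond %in% c("control", paste0("KA", timepoint))
  list(samples = which(keep_s), condition = droplevels(cond[keep_s]))
}

#' Time-dependent (or single-timepoint) ANOSVA over a dataset
#'
#' Runs the per-gene probeset-by-condition interaction test on every
#' transcript of a presence-filtered dataset. With `timepoint = NULL` the
#' condition factor has the four pooled levels (control, KA1, KA4, KA8);
#' with a single timepoint only control and kainate-at-t samples enter and
#' the factor has two levels (the original single-condition test).
#'
#' @param ds Log2-scale [exon_dataset()], already presence-filtered (use
#'   [presence_filter()]); transcripts with fewer than 3 probesets are
#'   refused by the filter upstream.
#' @param fdr Gene-level FDR cutoff (default 0.05).
#' @param timepoint `NULL` for the time-dependent test, or one of 1, 4, 8.
#' @return Object of class `anosva_result`: list with `results` and `terms`
#'   tibbles (see [gene_level_call()]) and `skipped` (transcript_id, reason).
#' @export
run_anosva <- function(ds, fdr = 0.05, timepoint = NULL) {
  stopifnot(inherits(ds, "exon_dataset"))
  sub <- anosva_long_data(ds, timepoint)
  anno <- ds$annotation
  mat <- ds$intensities[, sub$samples, drop = FALSE]
  cond_s <- sub$condition
  tx_ids <- unique(anno$transcript_id)
  term_list <- vector("list", length(tx_ids))
  skipped <- list()
  for (i in seq_along(tx_ids)) {
    tx <- tx_ids[i]
    rows <- which(anno$transcript_id == tx)
    sub_anno <- anno[rows, , drop = FALSE]
    ord <- sub_anno |>
      dplyr::distinct(.data$probeset_id, .data$probeset_order) |>
      dplyr::arrange(.data$probeset_order)
    ps_f <- factor(rep(sub_anno$probeset_id, times = length(cond_s)),
                   levels = ord$probeset_id)
    cond_f <- rep(cond_s, each = length(rows))
    y <- as.vector(mat[rows, , drop = FALSE])
    fit <- anosva_fit_gene(y, ps_f, cond_f, transcript_id = tx)
    if (inherits(fit, "anosva_skip")) {
      skipped[[length(skipped) + 1L]] <-
        tibble(transcript_id = tx, reason = fit$reason)
      next
    }
    p <- interaction_pvalues(fit)
    term_list[[i]] <- dplyr::mutate(fit$gamma, p = p, transcript_id = tx,
                                    .before = 1) |>
      dplyr::select("transcript_id", "probeset_id", "condition",
                    "estimate", "se", "p")
  }
  terms <- dplyr::bind_rows(term_list)
  skipped <- if (length(skipped)) dplyr::bind_rows(skipped) else
    tibble(transcript_id = character(), reason = character())
  if (nrow(terms) == 0) {
    warning("no genes could be fitted")
    return(structure(list(
      results = tibble(transcript_id = character(), p_gene = double(),
                       q_gene = double(), call = logical(),
                       top_probeset_id = character(), top_condition = character(),
                       n_terms = integer()),
      terms = terms, skipped = skipped, fdr = fdr, timepoint = timepoint),
      class = "anosva_result"))
  }
  calls <- gene_level_call(terms, fdr = fdr)
  structure(list(results = calls$results, terms = calls$terms,
                 skipped = skipped, fdr = fdr, timepoint = timepoint),
            class = "anosva_result")
}

#' @export
print.anosva_result <- function(x, ...) {
  lbl <- if (is.null(x$timepoint)) "time-dependent" else
    paste0("single-timepoint (", x$timepoint, " h)")
  cat(sprintf("<anosva_result> %s: %d genes tested, %d called at FDR %.2g, %d skipped\n",
              lbl, nrow(x$results), sum(x$results$call), x$fdr, nrow(x$skipped)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
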