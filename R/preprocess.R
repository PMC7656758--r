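#' Background-correct probe intensities
#'
#' Optional percentile-shift background correction for linear-scale data:
#' subtracts the per-sample `q`-th percentile (type-7 linear interpolation)
#' and floors the result at a small positive constant so the subsequent log2
#' transform is defined. `method = "none"` passes the data through.
#'
#' @param ds Linear-scale [exon_dataset()].
#' @param method `"none"` or `"shift"`.
#' @param q Percentile subtracted per sample (default 0.01).
#' @param floor Positive floor applied after subtraction (default `2^-10`).
#' @return A linear-scale [exon_dataset()].
#' @export
background_correct <- function(ds, method = c("none", "shift"),
                               q = 0.01, floor = 2^-10) {
  method <- match.arg(method)
  stopifnot(inherits(ds, "exon_dataset"))
  if (ds$scale != "linear") {
    stop("background_correct expects linear-scale intensities")
  }
  if (method == "none") return(ds)
  bg <- apply(ds$intensities, 2, stats::quantile, probs = q, names = FALSE)
  mat <- sweep(ds$intensities, 2, bg, "-")
  mat[mat < floor] <- floor
  ds$intensities <- mat
  ds
}

#' Quantile-normalize probe intensities
#'
#' Forces every sample column onto the common empirical distribution (the
#' vector of row-wise means of column-sorted values) while preserving
#' within-column ranks; ties share the mean of the quantile values they span.
#' Linear-scale input is log2-transformed first. The heavy lifting is
#' delegated to [limma::normalizeQuantiles()].
#'
#' @param ds An [exon_dataset()] on either scale.
#' @return A log2-scale [exon_dataset()].
#' @export
quantile_normalize <- function(ds) {
  stopifnot(inherits(ds, "exon_dataset"))
  mat <- ds$intensities
  if (ds$scale == "linear") {
    if (any(mat <= 0)) stop("linear intensities must be positive before log2")
    mat <- log2(mat)
  }
  if (ncol(mat) < 2) {
    warning("single-sample dataset: quantile normalization skipped")
  } else {
    dn <- dimnames(mat)
    mat <- limma::normalizeQuantiles(mat, ties = TRUE)
    dimnames(mat) <- dn
  }
  ds$intensities <- mat
  ds$scale <- "log2"
  ds
}

#' Median-polish fit of the additive probe x sample model
#'
#' Fits `y[p, s] = overall + probe_effect[p] + chip[s] + residual[p, s]` by
#' iterated median sweeps (probes swept before samples each iteration, the
#' RMA convention). The decomposition is exact at every iteration; iteration
#' stops when no cell changes by more than `tol` or after `max_iter` sweeps.
#' The summarized expression values are `overall + col_effects`.
#'
#' @param mat Numeric matrix of log2 probe intensities, probes x samples.
#' @param max_iter Maximum number of full sweeps (default 10).
#' @param tol Per-cell convergence tolerance in log2 units (default 0.01).
#' @return List with `overall`, `row_effects` (probe affinities),
#'   `col_effects`, `chip_effects` (= overall + col_effects), `residuals`,
#'   `converged`, `iterations`.
#' @export
median_polish_fit <- function(mat, max_iter = 10L, tol = 0.01) {
  if (!is.matrix(mat) || nrow(mat) < 1L || ncol(mat) < 1L) {
    stop("median_polish_fit needs a matrix with at least one probe and one sample")
  }
  fit <- .medpolish_cpp(mat, as.integer(max_iter), tol)
  row_eff <- stats::setNames(fit$row_effects, rownames(mat))
  col_eff <- stats::setNames(fit$col_effects, colnames(mat))
  res <- fit$residuals
  dimnames(res) <- dimnames(mat)
  list(overall = fit$overall, row_effects = row_eff, col_effects = col_eff,
       chip_effects = fit$overall + col_eff, residuals = res,
       converged = fit$converged, iterations = fit$iterations)
}

# pure-R reference implementation of the same sweep schedule; used as an
# in-package oracle for the compiled engine
median_polish_r <- function(mat, max_iter = 10L, tol = 0.01) {
  r <- mat
  row_eff <- rep(0, nrow(mat))
  col_eff <- rep(0, ncol(mat))
  overall <- 0
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    old <- r
    rm <- apply(r, 1L, stats::median)
    r <- r - rm
    row_eff <- row_eff + rm
    delta <- stats::median(row_eff)
    row_eff <- row_eff - delta
    overall <- overall + delta
    cm <- apply(r, 2L, stats::median)
    r <- sweep(r, 2L, cm)
    col_eff <- col_eff + cm
    delta <- stats::median(col_eff)
    col_eff <- col_eff - delta
    overall <- overall + delta
    if (max(abs(r - old)) <= tol) { converged <- TRUE; break }
  }
  names(row_eff) <- rownames(mat)
  names(col_eff) <- colnames(mat)
  list(overall = overall, row_effects = row_eff, col_effects = col_eff,
       chip_effects = overall + col_eff, residuals = r, converged = converged,
       iterations = iter)
}

#' Summarize normalized probe intensities to probeset and transcript level
#'
#' Runs one median polish per probeset (giving the probeset-level expression
#' matrix) and one per transcript over all of its probes (giving the
#' transcript-level expression, the per-transcript probe affinities, and the
#' residual matrices that the FIRMA scores are built from).
#'
#' @param ds Quantile-normalized log2-scale [exon_dataset()].
#' @param max_iter,tol Passed to [median_polish_fit()].
#' @return An object of class `expression_summary` with elements
#'   `probeset_expr` (probesets x samples), `transcript_expr`
#'   (transcripts x samples), `residuals` and `probe_effects` (named lists per
#'   transcript), `probesets` (probeset -> transcript annotation tibble) and
#'   the `design`.
#' @export
summarize_expression <- function(ds, max_iter = 10L, tol = 0.01) {
  stopifnot(inherits(ds, "exon_dataset"))
  if (ds$scale != "log2") stop("summarize_expression expects log2-scale data")
  anno <- ds$annotation
  mat <- ds$intensities

  ps_anno <- anno |>
    dplyr::distinct(.data$probeset_id, .data$transcript_id, .data$probeset_order) |>
    dplyr::arrange(.data$transcript_id, .data$probeset_order)

  ps_rows <- split(seq_len(nrow(anno)), anno$probeset_id)
  probeset_expr <- t(vapply(
    ps_anno$probeset_id,
    function(p) median_polish_fit(mat[ps_rows[[p]], , drop = FALSE],
                                  max_iter, tol)$chip_effects,
    numeric(ncol(mat))))
  rownames(probeset_expr) <- ps_anno$probeset_id

  tx_ids <- sort(unique(anno$transcript_id))
  tx_rows <- split(seq_len(nrow(anno)), anno$transcript_id)
  residuals <- vector("list", length(tx_ids)); names(residuals) <- tx_ids
  probe_effects <- vector("list", length(tx_ids)); names(probe_effects) <- tx_ids
  transcript_expr <- matrix(NA_real_, length(tx_ids), ncol(mat),
                            dimnames = list(tx_ids, colnames(mat)))
  for (tx in tx_ids) {
    fit <- median_polish_fit(mat[tx_rows[[tx]], , drop = FALSE], max_iter, tol)
    transcript_expr[tx, ] <- fit$chip_effects
    residuals[[tx]] <- fit$residuals
    probe_effects[[tx]] <- fit$row_effects
  }
  probe_map <- lapply(tx_rows, function(rows) {
    setNames(anno$probeset_id[rows], anno$probe_id[rows])
  })
  structure(
    list(probeset_expr = probeset_expr, transcript_expr = transcript_expr,
         residuals = residuals, probe_effects = probe_effects,
         probe_map = probe_map, probesets = ps_anno, design = ds$design),
    class = "expression_summary"
  )
}

#' @export
print.expression_summary <- function(x, ...) {
  cat(sprintf("<expression_summary> %d probesets / %d transcripts x %d samples\n",
              nrow(x$probeset_expr), nrow(x$transcript_expr), ncol(x$transcript_expr)))
  invisible(x)
}

#' Median-expression transcript filter
#'
#' Retains transcripts whose mean log2 expression across all samples is
#' strictly above the median of those per-transcript means (with an even
#' transcript count the median is the midpoint of the two central values).
#' The retained set is invariant to a global shift of the data.
#'
#' @param summary An [summarize_expression()] result.
#' @return Character vector of retained transcript ids, with the per-transcript
#'   means and the cutoff attached as attributes `means` and `cutoff`.
#' @export
median_expression_filter <- function(summary) {
  stopifnot(inherits(summary, "expression_summary"))
  if (nrow(summary$transcript_expr) < 2) {
    stop("median_expression_filter needs at least 2 transcripts")
  }
  means <- rowMeans(summary$transcript_expr)
  cutoff <- stats::median(means)
  retained <- names(means)[means > cutoff]
  if (length(retained) == 0) warning("median-expression filter retained no transcripts")
  structure(retained, means = means, cutoff = cutoff)
}

#' Per-exon log2-ratio profiles
#'
#' For each retained transcript and each timepoint t in {1,4,8} h, computes
#' the probeset-level log2 ratio mean(kainate at t) - mean(all controls),
#' where the control pool is untreated plus vehicle samples. A flat probeset
#' (equal kainate and control means) has ratio 0.
#'
#' @param summary An [summarize_expression()] result.
#' @param retained Character vector of transcript ids to report (default: all).
#' @return Tibble with `transcript_id`, `probeset_id`, `probeset_order`,
#'   `ratio_1h`, `ratio_4h`, `ratio_8h`, probesets in 5'-to-3' order.
#' @export
exon_profiles <- function(summary, retained = NULL) {
  stopifnot(inherits(summary, "expression_summary"))
  design <- summary$design
  if (is.null(retained)) retained <- unique(summary$probesets$transcript_id)
  ctrl <- design$treatment %in% c("untreated", "vehicle")
  ps <- summary$probesets |> dplyr::filter(.data$transcript_id %in% retained)
  expr <- summary$probeset_expr[ps$probeset_id, , drop = FALSE]
  ctrl_mean <- rowMeans(expr[, ctrl, drop = FALSE])
  out <- ps
  for (t in TIMEPOINTS) {
    ka <- design$treatment == "kainate" & design$time_h == t
    col <- paste0("ratio_", t, "h")
    out[[col]] <- if (!any(ka)) NA_real_ else
      unname(rowMeans(expr[, ka, drop = FALSE]) - ctrl_mean)
  }
  out |> dplyr::arrange(.data$transcript_id, .data$probeset_order)
}
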