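KINETIC_CLASSES <- c("immediate_early", "delayed_up", "delayed_down",
                     "immediate_down", "not_significant")

#' Two-group linear fit per transcript at one timepoint
#'
#' For the kainate and vehicle samples collected at timepoint `t`, fits the
#' two-group linear model to every transcript: the log2 fold change is the
#' group-mean difference (kainate minus vehicle) and `s_sq` the pooled
#' residual variance on `n_KA + n_veh - 2` degrees of freedom.
#'
#' @param transcript_expr Transcripts x samples log2 expression matrix.
#' @param design Sample-design tibble.
#' @param t Timepoint in hours (1, 4 or 8).
#' @return Tibble with `transcript_id`, `log2fc`, `s_sq`, `df`, and the group
#'   sizes `n_ka`, `n_veh`.
#' @export
fit_timepoint <- function(transcript_expr, design, t) {
  ka <- design$treatment == "kainate" & design$time_h == t
  veh <- design$treatment == "vehicle" & design$time_h == t
  if (sum(ka) < 2 || sum(veh) < 2) {
    stop(sprintf("fit_timepoint at t=%s needs >=2 kainate and >=2 vehicle samples", t))
  }
  xk <- transcript_expr[, ka, drop = FALSE]
  xv <- transcript_expr[, veh, drop = FALSE]
  mk <- rowMeans(xk); mv <- rowMeans(xv)
  ssk <- rowSums((xk - mk)^2)
  ssv <- rowSums((xv - mv)^2)
  df <- sum(ka) + sum(veh) - 2L
  tibble(
    transcript_id = rownames(transcript_expr),
    log2fc = unname(mk - mv),
    s_sq = unname(ssk + ssv) / df,
    df = df,
    n_ka = sum(ka),
    n_veh = sum(veh)
  )
}

#' Empirical-Bayes moderated t statistics
#'
#' Shrinks the per-transcript residual variances towards a common prior
#' estimated from the whole ensemble and forms moderated t statistics, the
#' standard variance-moderation approach for small-replicate microarray
#' designs. Prior estimation and shrinkage are delegated to
#' [limma::squeezeVar()] (moment matching on log variances); the moderated
#' statistic is `t = log2fc / sqrt(s2_post * (1/n_KA + 1/n_veh))` with
#' `df + d0` degrees of freedom.
#'
#' @param fit Tibble from [fit_timepoint()].
#' @return List with `prior` (`d0`, `s0_sq`) and `table`: the input tibble
#'   plus `s2_post`, `t_mod` and two-sided `p`.
#' @export
ebayes_moderate <- function(fit) {
  if (nrow(fit) < 10) stop("ebayes_moderate needs >=10 transcripts to estimate the prior")
  sq <- limma::squeezeVar(fit$s_sq, df = fit$df)
  d0 <- sq$df.prior
  s2_post <- sq$var.post
  se <- sqrt(s2_post * (1 / fit$n_ka + 1 / fit$n_veh))
  t_mod <- fit$log2fc / se
  df_total <- fit$df + d0
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  list(
    prior = list(d0 = d0, s0_sq = sq$var.prior),
    table = dplyr::mutate(fit, s2_post = s2_post, t_mod = t_mod, p = p)
  )
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a p-value vector (a thin,
#' contract-checked wrapper over [stats::p.adjust()]).
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values, same order as `p`.
#' @export
adjust_bh <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Classify differential-expression kinetics
#'
#' Assigns each transcript to one of four kinetic classes from its
#' per-timepoint significance and direction: `immediate_early` (significant
#' up at 1 h), `delayed_up` (not significant at 1 h, significant up at 4 or
#' 8 h), and the mirrored down classes; everything else is `not_significant`.
#' When the 1 h test is not significant and the later timepoints disagree in
#' direction, the timepoint with the larger absolute fold change decides.
#'
#' @param q Matrix/data frame of q-values, transcripts x timepoints (1,4,8).
#' @param log2fc Matching matrix of log2 fold changes.
#' @param alpha Significance cutoff on q (default 0.05).
#' @param lfc_min Minimum absolute log2 fold change (default 0).
#' @return Character vector of kinetic classes.
#' @export
classify_kinetics <- function(q, log2fc, alpha = 0.05, lfc_min = 0) {
  q <- as.matrix(q); log2fc <- as.matrix(log2fc)
  stopifnot(ncol(q) == 3, all(dim(q) == dim(log2fc)))
  up <- q <= alpha & log2fc > lfc_min
  down <- q <= alpha & log2fc < -lfc_min
  late <- 2:3
  vapply(seq_len(nrow(q)), function(i) {
    if (up[i, 1]) return("immediate_early")
    if (down[i, 1]) return("immediate_down")
    late_up <- any(up[i, late]); late_down <- any(down[i, late])
    if (late_up && late_down) {
      iu <- late[up[i, late]][which.max(abs(log2fc[i, late][up[i, late]]))]
      id <- late[down[i, late]][which.max(abs(log2fc[i, late][down[i, late]]))]
      return(if (abs(log2fc[i, iu]) >= abs(log2fc[i, id])) "delayed_up" else "delayed_down")
    }
    if (late_up) return("delayed_up")
    if (late_down) return("delayed_down")
    "not_significant"
  }, character(1))
}

#' Per-timepoint differential expression with kinetic classes
#'
#' Runs the full gene-level stage: for each timepoint (1, 4, 8 h) a two-group
#' kainate-vs-vehicle fit, empirical-Bayes variance moderation, BH adjustment
#' across transcripts within the timepoint, then kinetic classification.
#'
#' @param summary An [summarize_expression()] result.
#' @param alpha,lfc_min Passed to [classify_kinetics()].
#' @return Object of class `de_result`: a tibble with `transcript_id`,
#'   per-timepoint `log2fc_*`, `t_mod_*`, `p_*`, `q_*` columns and
#'   `kinetic_class`; the eBayes priors are attached as attribute `priors`.
#' @export
run_gene_de <- function(summary, alpha = 0.05, lfc_min = 0) {
  stopifnot(inherits(summary, "expression_summary"))
  expr <- summary$transcript_expr
  out <- tibble(transcript_id = rownames(expr))
  priors <- list()
  for (t in TIMEPOINTS) {
    mod <- ebayes_moderate(fit_timepoint(expr, summary$design, t))
    priors[[paste0("t", t)]] <- mod$prior
    tb <- mod$table
    out[[paste0("log2fc_", t, "h")]] <- tb$log2fc
    out[[paste0("t_mod_", t, "h")]] <- tb$t_mod
    out[[paste0("p_", t, "h")]] <- tb$p
    out[[paste0("q_", t, "h")]] <- adjust_bh(tb$p)
  }
  qm <- as.matrix(out[paste0("q_", TIMEPOINTS, "h")])
  fm <- as.matrix(out[paste0("log2fc_", TIMEPOINTS, "h")])
  out$kinetic_class <- classify_kinetics(qm, fm, alpha, lfc_min)
  structure(out, priors = priors, alpha = alpha, lfc_min = lfc_min,
            class = c("de_result", class(out)))
}
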