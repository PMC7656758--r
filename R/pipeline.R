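#' Pipeline configuration
#'
#' Collects the paths and stage parameters of a full run. Cutoffs must lie
#' in (0, 1).
#'
#' @param probe_table,sample_sheet Input TSV paths.
#' @param out_dir Output directory (created if missing).
#' @param scale Scale of the probe table (`"log2"` or `"linear"`).
#' @param present_quantile Presence-filter quantile (default 0.25).
#' @param anosva_fdr Gene-level ANOSVA FDR cutoff (default 0.05).
#' @param firma_cutoff FIRMA empirical-FDR cutoff (default 0.10).
#' @param de_alpha Differential-expression significance level (default 0.05).
#' @param top_sd_n Transcripts for the QC correlation matrix (default 1000).
#' @param background `"none"` or `"shift"` (linear input only).
#' @param stages Character vector of stages to run (any of `"qc"`, `"de"`,
#'   `"anosva"`, `"firma"`; preprocessing always runs).
#' @param seed Seed echoed into the manifest (the analysis itself is
#'   deterministic).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(probe_table, sample_sheet, out_dir,
                            scale = "log2", present_quantile = 0.25,
                            anosva_fdr = 0.05, firma_cutoff = 0.10,
                            de_alpha = 0.05, top_sd_n = 1000L,
                            background = "none",
                            stages = c("qc", "de", "anosva", "firma"),
                            seed = 1L) {
  cuts <- c(present_quantile = present_quantile, anosva_fdr = anosva_fdr,
            firma_cutoff = firma_cutoff, de_alpha = de_alpha)
  if (any(cuts <= 0 | cuts >= 1)) {
    stop("config error: cutoffs must lie in (0, 1): ",
         paste(names(cuts)[cuts <= 0 | cuts >= 1], collapse = ", "))
  }
  if (!all(stages %in% c("qc", "de", "anosva", "firma"))) {
    stop("config error: unknown stage(s)")
  }
  structure(list(probe_table = probe_table, sample_sheet = sample_sheet,
                 out_dir = out_dir, scale = scale,
                 present_quantile = present_quantile, anosva_fdr = anosva_fdr,
                 firma_cutoff = firma_cutoff, de_alpha = de_alpha,
                 top_sd_n = as.integer(top_sd_n), background = background,
                 stages = stages, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes load/validate, preprocessing (optional background correction,
#' quantile normalization, median-polish summarization, median-expression
#' filter), then the enabled stages (QC, differential expression, the
#' time-dependent splicing interaction test, FIRMA), writing every interface
#' table into `out_dir` plus a JSON manifest. Re-running with the same
#' inputs and config reproduces all outputs bit-exactly.
#'
#' @param cfg A [pipeline_config()].
#' @return List of class `run_manifest`: output file inventory, parameter
#'   echo, per-stage record counts, and the in-memory stage results.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  timings <- list()
  emit <- function(tbl, name) {
    path <- file.path(cfg$out_dir, name)
    write_result_table(tbl, path)
    outputs <<- c(outputs, path)
    path
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- expr
    timings[[name]] <<- proc.time()[["elapsed"]] - t0
    val
  }

  design <- read_sample_sheet(cfg$sample_sheet)
  ds <- read_probe_table(cfg$probe_table, design, scale = cfg$scale)
  report <- validate_exon_data(ds)
  hard <- report$violations$code %in% c("NA_INTENSITY", "NEG_INTENSITY",
                                        "MULTI_TRANSCRIPT", "ORDER_TIE")
  if (any(hard)) {
    stop("data error: ", paste(report$violations$message[hard], collapse = "; "))
  }

  ds <- stage("preprocess", {
    d <- ds
    if (d$scale == "linear") d <- background_correct(d, cfg$background)
    quantile_normalize(d)
  })
  summ <- stage("summarize", summarize_expression(ds))
  retained <- median_expression_filter(summ)
  emit(tibble(transcript_id = as.character(retained)), "retained_transcripts.tsv")
  emit(expr_to_tibble(summ$probeset_expr, "probeset_id"), "probeset_expr.tsv")
  emit(expr_to_tibble(summ$transcript_expr, "transcript_id"), "transcript_expr.tsv")
  emit(exon_profiles(summ, retained), "exon_profiles.tsv")

  results <- list(summary = summ, retained = as.character(retained))

  if ("qc" %in% cfg$stages) {
    qc <- stage("qc", run_qc(summ, top_n = cfg$top_sd_n))
    corr <- as_tibble(qc$correlation) |>
      dplyr::mutate(sample_id = rownames(qc$correlation), .before = 1)
    emit(corr, "qc_correlation.tsv")
    pca_tbl <- tidy(qc$pca)
    emit(pca_tbl, "qc_pca.tsv")
    emit(tibble(component = colnames(qc$pca$scores),
                variance_fraction = qc$pca$variance_fraction),
         "qc_pca_variance.tsv")
    results$qc <- qc
  }

  if ("de" %in% cfg$stages) {
    de <- stage("de", run_gene_de(summ, alpha = cfg$de_alpha))
    emit(de, "de_results.tsv")
    results$de <- de
  }

  if ("anosva" %in% cfg$stages) {
    filtered <- stage("presence_filter",
                      presence_filter(ds, cfg$present_quantile))
    an <- stage("anosva", run_anosva(filtered, fdr = cfg$anosva_fdr))
    emit(an$results, "anosva_results.tsv")
    emit(an$terms, "anosva_terms.tsv")
    emit(an$skipped, "anosva_skipped.tsv")
    results$anosva <- an
    results$filtered <- filtered
  }

  if ("firma" %in% cfg$stages) {
    fr <- stage("firma", run_firma(summ, cutoff = cfg$firma_cutoff))
    emit(as_tibble(fr), "firma_results.tsv")
    Fm <- attr(fr, "F_matrix")
    called <- fr$probeset_id[fr$call]
    heat <- Fm[rownames(Fm) %in% called, , drop = FALSE]
    heat_tbl <- as_tibble(sign(heat) * log2(1 + abs(heat))) |>
      dplyr::mutate(probeset_id = rownames(heat), .before = 1)
    emit(heat_tbl, "firma_heatmap.tsv")
    results$firma <- fr
  }

  manifest <- structure(
    list(outputs = outputs, parameters = unclass(cfg), timings = timings,
         counts = list(
           n_probes = report$n_probes, n_probesets = report$n_probesets,
           n_transcripts = report$n_transcripts, n_samples = report$n_samples,
           n_retained = length(retained)),
         versions = list(r = as.character(getRversion()),
                         exonusage = as.character(utils::packageVersion("exonusage"))),
         results = results),
    class = "run_manifest")
  jsonlite::write_json(
    manifest[c("outputs", "parameters", "counts", "versions")],
    file.path(cfg$out_dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  manifest
}

expr_to_tibble <- function(mat, id_col) {
  out <- as_tibble(mat)
  out[[id_col]] <- rownames(mat)
  dplyr::relocate(out, dplyr::all_of(id_col))
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> %d output tables in %s\n",
              length(x$outputs), dirname(x$outputs[1])))
  invisible(x)
}

#' Per-gene report
#'
#' Assembles the three tabular views of one transcript (probe-level log2
#' intensities, probeset-level summarized expression, and per-exon log2
#' ratios versus the pooled controls) together with its splicing-test rows.
#'
#' @param manifest A [run_pipeline()] result.
#' @param transcript_id Transcript to report.
#' @return List with tibbles `probes`, `probesets`, `ratios`, and any
#'   `anosva` / `firma` rows for the transcript.
#' @export
report_gene <- function(manifest, transcript_id) {
  stopifnot(inherits(manifest, "run_manifest"))
  summ <- manifest$results$summary
  if (!transcript_id %in% rownames(summ$transcript_expr)) {
    stop("unknown transcript: ", transcript_id)
  }
  probe_ids <- names(summ$probe_map[[transcript_id]])
  ps <- summ$probesets |> dplyr::filter(.data$transcript_id == !!transcript_id)
  probes <- tibble(probe_id = probe_ids,
                   probeset_id = unname(summ$probe_map[[transcript_id]]))
  res <- summ$residuals[[transcript_id]]
  fit <- outer(summ$probe_effects[[transcript_id]],
               summ$transcript_expr[transcript_id, ], "+")
  probes <- dplyr::bind_cols(probes, as_tibble(fit + res))
  probesets <- expr_to_tibble(
    summ$probeset_expr[ps$probeset_id, , drop = FALSE], "probeset_id")
  ratios <- exon_profiles(summ, transcript_id)
  out <- list(probes = probes, probesets = probesets, ratios = ratios)
  if (!is.null(manifest$results$anosva)) {
    out$anosva <- manifest$results$anosva$results |>
      dplyr::filter(.data$transcript_id == !!transcript_id)
  }
  if (!is.null(manifest$results$firma)) {
    out$firma <- manifest$results$firma |>
      dplyr::filter(.data$transcript_id == !!transcript_id)
  }
  out
}
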