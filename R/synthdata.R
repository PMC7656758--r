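#' Generator configuration
#'
#' Parameters of the synthetic exon-array generator. Defaults emulate the
#' study conditions the pipeline was designed for: the canonical 22-sample
#' seizure time-course design, roughly four probes per probeset, gene-level
#' induction in four kinetic classes, and probeset-restricted splice effects
#' confined to the kainate conditions.
#'
#' @param n_transcripts Number of transcripts to simulate.
#' @param probesets_per_transcript Integer range (length 2) of probesets per
#'   transcript, sampled uniformly (default 4-12).
#' @param probes_per_probeset Probes per probeset (default 4).
#' @param baseline_range Log2 baseline expression range (default 6-12).
#' @param probe_affinity_sd SD of probe affinities, centered within each
#'   probeset (default 1.0).
#' @param noise_sd SD of the iid Gaussian measurement noise in log2 units
#'   (default 0.25).
#' @param frac_de Fraction of transcripts with gene-level induction
#'   (default 0.10), split evenly over the four kinetic classes.
#' @param de_effect Peak gene-level effect in log2 units (default 2.0).
#' @param frac_spliced Fraction of transcripts carrying a probeset-restricted
#'   splice effect (default 0.10).
#' @param splice_effect Splice effect size in log2 units (default 1.5).
#' @param splice_conditions Kainate conditions carrying the splice effect
#'   (subset of `"KA1"`, `"KA4"`, `"KA8"`; default all three).
#' @param n_spliced_probesets Probesets affected per spliced transcript
#'   (default 1, the single-exon skipping/inclusion premise).
#' @param frac_absent_probesets Fraction of probesets forced to background
#'   level (default 0.05).
#' @param frac_crosshyb Fraction of probes flagged cross-hybridizing
#'   (default 0.02).
#' @param seed Integer seed; the generator is a pure function of this config.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(n_transcripts = 200L,
                             probesets_per_transcript = c(4L, 12L),
                             probes_per_probeset = 4L,
                             baseline_range = c(6, 12),
                             probe_affinity_sd = 1.0,
                             noise_sd = 0.25,
                             frac_de = 0.10,
                             de_effect = 2.0,
                             frac_spliced = 0.10,
                             splice_effect = 1.5,
                             splice_conditions = c("KA1", "KA4", "KA8"),
                             n_spliced_probesets = 1L,
                             frac_absent_probesets = 0.05,
                             frac_crosshyb = 0.02,
                             seed = 1L) {
  cfg <- list(n_transcripts = as.integer(n_transcripts),
              probesets_per_transcript = as.integer(probesets_per_transcript),
              probes_per_probeset = as.integer(probes_per_probeset),
              baseline_range = baseline_range,
              probe_affinity_sd = probe_affinity_sd, noise_sd = noise_sd,
              frac_de = frac_de, de_effect = de_effect,
              frac_spliced = frac_spliced, splice_effect = splice_effect,
              splice_conditions = splice_conditions,
              n_spliced_probesets = as.integer(n_spliced_probesets),
              frac_absent_probesets = frac_absent_probesets,
              frac_crosshyb = frac_crosshyb, seed = as.integer(seed))
  fracs <- c(cfg$frac_de, cfg$frac_spliced, cfg$frac_absent_probesets,
             cfg$frac_crosshyb)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0, 1]")
  if (cfg$probe_affinity_sd < 0 || cfg$noise_sd < 0) stop("sd values must be >= 0")
  if (cfg$n_transcripts < 1) stop("n_transcripts must be >= 1")
  if (length(cfg$probesets_per_transcript) != 2 ||
      diff(cfg$probesets_per_transcript) < 0) {
    stop("probesets_per_transcript must be an increasing range of length 2")
  }
  if (!all(cfg$splice_conditions %in% c("KA1", "KA4", "KA8"))) {
    stop("splice_conditions must be a subset of KA1/KA4/KA8")
  }
  structure(cfg, class = "generator_config")
}

#' Canonical sample design
#'
#' The study layout: 4 untreated controls at time 0, and 3 vehicle plus 3
#' kainate replicates at each of 1, 4 and 8 h (22 samples, 7 treatment-time
#' cells). Deterministic; no randomness.
#'
#' @return A sample-design tibble.
#' @export
generate_design <- function() {
  rows <- list(tibble(sample_id = paste0("cntrl_", 1:4),
                      treatment = "untreated", time_h = 0L, replicate = 1:4))
  for (t in TIMEPOINTS) {
    rows[[length(rows) + 1L]] <- tibble(
      sample_id = paste0("veh", t, "h_", 1:3),
      treatment = "vehicle", time_h = t, replicate = 1:3)
    rows[[length(rows) + 1L]] <- tibble(
      sample_id = paste0("ka", t, "h_", 1:3),
      treatment = "kainate", time_h = t, replicate = 1:3)
  }
  dplyr::bind_rows(rows)
}

# per-class log2 effect profile at 1/4/8 h, scaled by de_effect
kinetic_profile <- function(class, de_effect) {
  base <- switch(class,
                 immediate_early = c(1, 0.5, 0),
                 delayed_up      = c(0, 1, 1),
                 immediate_down  = -c(1, 0.5, 0),
                 delayed_down    = -c(0, 1, 1),
                 none            = c(0, 0, 0))
  base * de_effect
}

#' Generate a synthetic exon-array dataset with known truth
#'
#' Simulates probe-level log2 intensities under the additive model
#' `y = baseline + probe_affinity + de(condition) + splice(condition) + noise`:
#' gene-level induction follows the transcript's kinetic-class profile in the
#' kainate samples only; splice effects are added to the chosen probeset(s)
#' of spliced transcripts in the configured kainate conditions only; absent
#' probesets are generated at a baseline 2 log2 units below the 1st
#' percentile of transcript baselines and carry no effects. Identical seeds
#' give bit-identical output.
#'
#' @param cfg A [generator_config()].
#' @param design Sample design (default [generate_design()]).
#' @return List with `dataset` (a log2-scale [exon_dataset()]) and `truth`
#'   (class `synthetic_truth`): tibbles `transcripts` (de_class, per-timepoint
#'   de effects, spliced flag), `probesets` (spliced, splice_effect,
#'   splice_conditions, absent) and `probes` (cross_hybridizing).
#' @export
generate_dataset <- function(cfg, design = generate_design()) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed)
  n <- cfg$n_transcripts
  tx_ids <- sprintf("tx%05d", seq_len(n))
  n_ps_tx <- sample(seq(cfg$probesets_per_transcript[1],
                        cfg$probesets_per_transcript[2]), n, replace = TRUE)
  baseline <- stats::runif(n, cfg$baseline_range[1], cfg$baseline_range[2])

  # gene-level DE classes
  n_de <- round(cfg$frac_de * n)
  de_class <- rep("none", n)
  if (n_de > 0) {
    de_idx <- sample.int(n, n_de)
    classes <- c("immediate_early", "delayed_up", "delayed_down", "immediate_down")
    de_class[de_idx] <- classes[(seq_len(n_de) - 1L) %% 4L + 1L]
  }
  de_profiles <- t(vapply(de_class, kinetic_profile, numeric(3),
                          de_effect = cfg$de_effect))
  colnames(de_profiles) <- paste0("de_", TIMEPOINTS, "h")

  # probeset table
  ps_tbl <- tibble(
    transcript_id = rep(tx_ids, n_ps_tx),
    probeset_order = unlist(lapply(n_ps_tx, seq_len), use.names = FALSE)
  ) |>
    dplyr::mutate(probeset_id = sprintf("%s_ps%02d", .data$transcript_id,
                                        .data$probeset_order))
  n_ps <- nrow(ps_tbl)
  ps_tbl$absent <- FALSE
  n_abs <- round(cfg$frac_absent_probesets * n_ps)
  if (n_abs > 0) ps_tbl$absent[sample.int(n_ps, n_abs)] <- TRUE

  # spliced transcripts: one (or more) non-absent probeset each
  n_spl <- round(cfg$frac_spliced * n)
  ps_tbl$spliced <- FALSE
  spliced_tx <- character(0)
  if (n_spl > 0) {
    spliced_tx <- tx_ids[sample.int(n, n_spl)]
    for (tx in spliced_tx) {
      cand <- which(ps_tbl$transcript_id == tx & !ps_tbl$absent)
      if (length(cand) == 0) cand <- which(ps_tbl$transcript_id == tx)
      pick <- cand[sample.int(length(cand),
                              min(cfg$n_spliced_probesets, length(cand)))]
      ps_tbl$spliced[pick] <- TRUE
    }
  }
  ps_tbl$splice_effect <- ifelse(ps_tbl$spliced, cfg$splice_effect, 0)
  ps_tbl$splice_conditions <- ifelse(
    ps_tbl$spliced, paste(cfg$splice_conditions, collapse = ","), "")

  # probes
  probes <- ps_tbl |>
    dplyr::slice(rep(seq_len(n_ps), each = cfg$probes_per_probeset)) |>
    dplyr::mutate(probe_no = rep(seq_len(cfg$probes_per_probeset), times = n_ps),
                  probe_id = sprintf("%s_p%d", .data$probeset_id, .data$probe_no))
  n_probes <- nrow(probes)
  affinity <- stats::rnorm(n_probes, 0, cfg$probe_affinity_sd)
  # center affinities within each probeset
  affinity <- affinity - stats::ave(affinity, probes$probeset_id)
  crosshyb <- rep(FALSE, n_probes)
  n_ch <- round(cfg$frac_crosshyb * n_probes)
  if (n_ch > 0) crosshyb[sample.int(n_probes, n_ch)] <- TRUE

  cond <- as.character(condition_labels(design))
  n_s <- nrow(design)
  tx_index <- match(probes$transcript_id, tx_ids)
  ps_index <- match(probes$probeset_id, ps_tbl$probeset_id)

  absent_level <- stats::quantile(baseline, 0.01, names = FALSE) - 2
  base_probe <- ifelse(ps_tbl$absent[ps_index], absent_level,
                       baseline[tx_index]) + affinity

  # condition effect per probe x sample
  de_mat <- matrix(0, n_probes, n_s)
  spl_mat <- matrix(0, n_probes, n_s)
  for (j in seq_len(n_s)) {
    cj <- cond[j]
    if (cj %in% paste0("KA", TIMEPOINTS)) {
      t_idx <- match(as.integer(sub("KA", "", cj)), TIMEPOINTS)
      eff <- de_profiles[tx_index, t_idx]
      eff[ps_tbl$absent[ps_index]] <- 0
      de_mat[, j] <- eff
      hit <- ps_tbl$spliced[ps_index] & cj %in% cfg$splice_conditions
      spl_mat[hit, j] <- cfg$splice_effect
    }
  }
  noise <- matrix(stats::rnorm(n_probes * n_s, 0, cfg$noise_sd), n_probes, n_s)
  y <- base_probe + de_mat + spl_mat + noise
  dimnames(y) <- list(probes$probe_id, design$sample_id)

  annotation <- tibble(
    probe_id = probes$probe_id,
    probeset_id = probes$probeset_id,
    transcript_id = probes$transcript_id,
    probeset_order = probes$probeset_order,
    cross_hybridizing = crosshyb
  )
  ds <- exon_dataset(annotation, design, y, scale = "log2")
  truth <- structure(list(
    transcripts = dplyr::bind_cols(
      tibble(transcript_id = tx_ids, de_class = de_class),
      as_tibble(de_profiles)) |>
      dplyr::mutate(spliced = .data$transcript_id %in%
                      ps_tbl$transcript_id[ps_tbl$spliced]),
    probesets = ps_tbl |>
      dplyr::select("probeset_id", "transcript_id", "probeset_order",
                    "spliced", "splice_effect", "splice_conditions", "absent"),
    probes = tibble(probe_id = probes$probe_id,
                    probeset_id = probes$probeset_id,
                    cross_hybridizing = crosshyb)
  ), class = "synthetic_truth")
  list(dataset = ds, truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth> %d transcripts (%d DE, %d spliced), %d probesets, %d probes\n",
              nrow(x$transcripts), sum(x$transcripts$de_class != "none"),
              sum(x$transcripts$spliced), nrow(x$probesets), nrow(x$probes)))
  invisible(x)
}

#' Evaluate calls against generator truth
#'
#' Confusion counts and rates for a set of called ids against the known
#' spliced units: at the gene level a transcript is a true positive when it
#' carries at least one spliced probeset; at the probeset level the spliced
#' flag decides. An empty call set has false-discovery proportion 0 by the
#' `max(called, 1)` convention.
#'
#' @param calls Character vector of called transcript or probeset ids.
#' @param truth A `synthetic_truth`.
#' @param level `"gene"` or `"probeset"`.
#' @return Tibble with `n_called`, `n_true_positive`, `n_false_positive`,
#'   `realized_fdp`, `power`.
#' @export
evaluate_calls <- function(calls, truth, level = c("gene", "probeset")) {
  level <- match.arg(level)
  stopifnot(inherits(truth, "synthetic_truth"))
  if (level == "gene") {
    universe <- truth$transcripts$transcript_id
    positive <- truth$transcripts$transcript_id[truth$transcripts$spliced]
  } else {
    universe <- truth$probesets$probeset_id
    positive <- truth$probesets$probeset_id[truth$probesets$spliced]
  }
  unknown <- setdiff(calls, universe)
  if (length(unknown) > 0) {
    stop("called id(s) not present in truth: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  tp <- length(intersect(calls, positive))
  fp <- length(calls) - tp
  tibble(
    n_called = length(calls),
    n_true_positive = tp,
    n_false_positive = fp,
    realized_fdp = fp / max(length(calls), 1),
    power = if (length(positive) == 0) NA_real_ else tp / length(positive)
  )
}

#' Convert a log2 dataset to the linear scale
#'
#' @param ds A log2-scale [exon_dataset()].
#' @return A linear-scale dataset with intensities `2^y`.
#' @export
to_linear_scale <- function(ds) {
  stopifnot(inherits(ds, "exon_dataset"), ds$scale == "log2")
  ds$intensities <- 2^ds$intensities
  ds$scale <- "linear"
  ds
}
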