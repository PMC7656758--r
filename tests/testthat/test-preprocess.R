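test_that("percentile-shift background correction matches hand computation", {
  design <- tiny_design()
  ds <- tiny_dataset(design)
  lin <- to_linear_scale(ds)
  # method = none is the identity
  expect_identical(background_correct(lin, "none"), lin)
  # all-equal matrix: x - x = 0, floored
  out <- background_correct(lin, "shift", q = 0.01)
  expect_true(all(out$intensities == 2^-10))
  # hand-computed lower quartile with linear interpolation
  m <- matrix(c(1, 2, 3, 100), 4, 1, dimnames = list(paste0("p", 1:4), "s1"))
  anno <- tibble::tibble(probe_id = paste0("p", 1:4), probeset_id = "e1",
                         transcript_id = "t1", probeset_order = 1L,
                         cross_hybridizing = FALSE)
  d1 <- tibble::tibble(sample_id = "s1", treatment = "untreated",
                       time_h = 0L, replicate = 1L)
  dd <- exon_dataset(anno, d1, m, scale = "linear")
  out2 <- background_correct(dd, "shift", q = 0.25)
  expect_equal(unname(out2$intensities[, 1]),
               c(2^-10, 0.25, 1.25, 98.25))
  # log2-scale input is a contract error
  expect_error(background_correct(ds, "shift"), "linear")
})

test_that("quantile normalization forces identical column distributions", {
  design <- tiny_design()[1:2, ]
  anno <- tibble::tibble(probe_id = c("p1", "p2"), probeset_id = "e1",
                         transcript_id = "t1", probeset_order = 1L,
                         cross_hybridizing = FALSE)
  m <- matrix(c(1, 2, 3, 4), 2, 2, dimnames = list(c("p1", "p2"),
                                                   design$sample_id))
  ds <- exon_dataset(anno, design, m, scale = "log2")
  out <- quantile_normalize(ds)
  expect_equal(unname(out$intensities),
               matrix(c(2, 3, 2, 3), 2, 2))
  # identical columns are a fixed point
  m2 <- matrix(c(5, 7, 5, 7), 2, 2, dimnames = dimnames(m))
  ds2 <- exon_dataset(anno, design, m2, scale = "log2")
  expect_equal(quantile_normalize(ds2)$intensities, m2)
  # post-hoc definition check on random data: sorted columns identical
  big <- tiny_dataset(noise_sd = 2, seed = 9)
  qn <- quantile_normalize(big)
  sorted <- apply(qn$intensities, 2, sort)
  expect_lt(max(abs(sorted - sorted[, 1])), 1e-12)
  # ranks preserved within columns
  expect_identical(apply(qn$intensities, 2, order),
                   apply(big$intensities, 2, order))
  # single sample: warn, return log2 input
  one <- tiny_dataset(tiny_design()[1, , drop = FALSE])
  expect_warning(quantile_normalize(one), "single-sample")
})

test_that("median polish decomposes exactly and recovers additive structure", {
  # exactly additive input: zero residuals, chip effects recover columns
  r <- c(0.5, -1, 2); c0 <- c(3, 5, 4, 7)
  m <- outer(r, c0, "+")
  fit <- median_polish_fit(m)
  expect_equal(max(abs(fit$residuals)), 0)
  expect_equal(diff(fit$chip_effects), diff(c0))
  # single-probe transcript: chip equals the probe row
  m1 <- matrix(c(1, 4, 2), 1, 3)
  f1 <- median_polish_fit(m1)
  expect_equal(unname(f1$chip_effects), c(1, 4, 2))
  expect_equal(unname(f1$row_effects), 0)
  # exact reconstruction on noisy seeded input
  set.seed(5)
  mm <- matrix(rnorm(60), 5, 12)
  ff <- median_polish_fit(mm, max_iter = 10)
  recon <- ff$overall + outer(ff$row_effects, ff$col_effects, "+") + ff$residuals
  expect_lt(max(abs(recon - mm)), 1e-12)
  expect_error(median_polish_fit(matrix(numeric(0), 0, 2)), "at least one")
})

test_that("compiled polish agrees with the R reference and stats::medpolish", {
  set.seed(11)
  for (dims in list(c(4, 22), c(9, 6), c(1, 5))) {
    m <- matrix(rnorm(prod(dims)), dims[1], dims[2])
    a <- median_polish_fit(m, max_iter = 50, tol = 1e-9)
    b <- exonusage:::median_polish_r(m, max_iter = 50, tol = 1e-9)
    expect_equal(a$overall, b$overall, tolerance = 1e-12)
    expect_equal(unname(a$row_effects), unname(b$row_effects), tolerance = 1e-12)
    expect_equal(a$residuals, b$residuals, tolerance = 1e-12)
  }
  # independent oracle: stats::medpolish uses a different sweep/centering
  # schedule, and median-polish fixed points are not unique, so chip effects
  # agree closely but not exactly
  set.seed(12)
  m <- matrix(rnorm(80), 8, 10)
  mine <- median_polish_fit(m, max_iter = 200, tol = 1e-10)
  ref <- stats::medpolish(m, eps = 1e-12, maxiter = 200, trace.iter = FALSE)
  expect_lt(max(abs((mine$overall + mine$col_effects) -
                      (ref$overall + ref$col))), 0.05)
  expect_lt(max(abs(apply(mine$residuals, 1, stats::median))), 1e-8)
  expect_lt(max(abs(apply(mine$residuals, 2, stats::median))), 1e-8)
})

test_that("median polish resists a single outlier better than column means", {
  set.seed(21)
  base <- outer(rnorm(3), rnorm(4), "+") + 8
  spoiled <- base; spoiled[2, 3] <- spoiled[2, 3] + 10
  clean_fit <- median_polish_fit(base)$chip_effects
  spoiled_fit <- median_polish_fit(spoiled)$chip_effects
  expect_lt(max(abs(spoiled_fit - clean_fit)), 0.5)
  mean_shift <- max(abs(colMeans(spoiled) - colMeans(base)))
  expect_lt(max(abs(spoiled_fit - clean_fit)), mean_shift)
})

test_that("summarization recovers noiseless generator profiles", {
  cfg <- generator_config(n_transcripts = 12, seed = 2, noise_sd = 0,
                          frac_de = 0.5, frac_spliced = 0,
                          frac_absent_probesets = 0, frac_crosshyb = 0)
  g <- generate_dataset(cfg)
  summ <- summarize_expression(g$dataset)
  cond <- condition_labels(summ$design)
  for (tx in g$truth$transcripts$transcript_id) {
    truth_row <- g$truth$transcripts[g$truth$transcripts$transcript_id == tx, ]
    profile <- c(0, truth_row$de_1h, truth_row$de_4h, truth_row$de_8h)[
      match(cond, c("control", "KA1", "KA4", "KA8"))]
    est <- summ$transcript_expr[tx, ]
    expect_lt(max(abs((est - mean(est)) - (profile - mean(profile)))), 1e-6)
  }
  # residuals all zero for exactly additive data
  expect_lt(max(abs(summ$residuals[[1]])), 1e-10)
})

test_that("additive reconstruction holds for every summarized transcript", {
  g <- cached_synth()
  ds <- quantile_normalize(g$dataset)
  summ <- summarize_expression(ds)
  for (tx in sample(rownames(summ$transcript_expr), 5)) {
    probes <- names(summ$probe_map[[tx]])
    recon <- outer(summ$probe_effects[[tx]], summ$transcript_expr[tx, ], "+") +
      summ$residuals[[tx]]
    expect_lt(max(abs(recon - ds$intensities[probes, ])), 1e-10)
  }
})

test_that("median-expression filter keeps strictly-above-median transcripts", {
  design <- tiny_design()
  anno <- tibble::tibble(probe_id = paste0("p", 1:4),
                         probeset_id = paste0("e", 1:4),
                         transcript_id = paste0("t", 1:4),
                         probeset_order = 1L, cross_hybridizing = FALSE)
  m <- matrix(rep(c(1, 2, 3, 4), 4), 4, 4,
              dimnames = list(anno$probe_id, design$sample_id))
  ds <- exon_dataset(anno, design, m, scale = "log2")
  summ <- summarize_expression(ds)
  kept <- median_expression_filter(summ)
  expect_setequal(as.character(kept), c("t3", "t4"))
  # shift invariance
  ds2 <- ds; ds2$intensities <- ds2$intensities + 1
  expect_setequal(as.character(median_expression_filter(summarize_expression(ds2))),
                  as.character(kept))
  # all identical means: empty set with a warning
  m3 <- matrix(5, 4, 4, dimnames = dimnames(m))
  ds3 <- exon_dataset(anno, design, m3, scale = "log2")
  expect_warning(k3 <- median_expression_filter(summarize_expression(ds3)),
                 "no transcripts")
  expect_length(k3, 0)
  expect_error(median_expression_filter(
    summarize_expression(tiny_dataset(n_tx = 1))), "at least 2")
})

test_that("exon profiles isolate condition-specific splice effects", {
  cfg <- generator_config(n_transcripts = 30, seed = 6, noise_sd = 0,
                          frac_de = 0, frac_spliced = 0.2, splice_effect = 2,
                          splice_conditions = "KA4",
                          frac_absent_probesets = 0, frac_crosshyb = 0)
  g <- generate_dataset(cfg)
  summ <- summarize_expression(g$dataset)
  prof <- exon_profiles(summ)
  truth <- g$truth$probesets
  spliced <- dplyr::semi_join(prof, truth[truth$spliced, ], by = "probeset_id")
  expect_equal(spliced$ratio_4h, rep(2, nrow(spliced)), tolerance = 1e-9)
  expect_equal(spliced$ratio_1h, rep(0, nrow(spliced)), tolerance = 1e-9)
  expect_equal(spliced$ratio_8h, rep(0, nrow(spliced)), tolerance = 1e-9)
  nulls <- dplyr::semi_join(prof, truth[!truth$spliced, ], by = "probeset_id")
  expect_lt(max(abs(as.matrix(nulls[paste0("ratio_", c(1, 4, 8), "h")]))), 1e-9)
  # permuting sample columns leaves profiles unchanged
  ds2 <- g$dataset
  perm <- sample(ncol(ds2$intensities))
  ds2$intensities <- ds2$intensities[, perm]
  ds2$design <- ds2$design[perm, ]
  prof2 <- exon_profiles(summarize_expression(ds2))
  expect_equal(prof2, prof, tolerance = 1e-9)
})
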