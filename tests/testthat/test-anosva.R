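test_that("presence filter applies the four rules of the cascade", {
  # transcripts with fewer than 3 probesets are excluded outright
  ds <- tiny_dataset(generate_design(), n_tx = 4, n_ps = 2, n_probes = 4,
                     noise_sd = 0.1, seed = 51)
  filtered <- suppressWarnings(presence_filter(ds))
  expect_equal(nrow(filtered$annotation), 0)

  # cross-hybridizing probes are dropped regardless of intensity
  ds2 <- tiny_dataset(generate_design(), n_tx = 4, n_ps = 4, n_probes = 4,
                      noise_sd = 0.1, seed = 52)
  ch <- ds2$annotation$probeset_id == "t1_e1"
  ds2$annotation$cross_hybridizing[ch] <- TRUE
  f2 <- presence_filter(ds2)
  expect_false(any(f2$annotation$cross_hybridizing))
  expect_false("t1_e1" %in% f2$annotation$probeset_id)

  # probesets forced to background are removed, verified against truth
  cfg <- generator_config(n_transcripts = 100, seed = 53, frac_de = 0,
                          frac_spliced = 0, frac_absent_probesets = 0.10,
                          frac_crosshyb = 0, probesets_per_transcript = c(8, 12))
  g <- generate_dataset(cfg)
  f3 <- presence_filter(quantile_normalize(g$dataset))
  absent <- g$truth$probesets$probeset_id[g$truth$probesets$absent]
  survivors <- unique(f3$annotation$probeset_id)
  expect_length(intersect(absent, survivors), 0)
  # and the overwhelming majority of expressed probesets survive
  expressed <- g$truth$probesets$probeset_id[!g$truth$probesets$absent]
  expect_gt(length(intersect(expressed, survivors)) / length(expressed), 0.7)
})

test_that("interaction fits match stats::lm coefficient by coefficient", {
  set.seed(55)
  design <- generate_design()
  cond <- condition_labels(design)
  n_ps <- 5; n_probes <- 4
  ps <- factor(rep(sprintf("e%d", 1:n_ps), each = n_probes))
  y <- 8 + rnorm(n_ps * n_probes * nrow(design), 0, 0.3)
  ps_f <- rep(ps, times = nrow(design))
  cond_f <- rep(cond, each = n_ps * n_probes)
  fit <- anosva_fit_gene(y, ps_f, cond_f, "gene1")
  ref <- stats::lm(y ~ ps_f * cond_f)
  sm <- summary(ref)$coefficients
  ref_gamma <- sm[grepl(":", rownames(sm)), ]
  expect_equal(fit$gamma$estimate, unname(ref_gamma[, 1]), tolerance = 1e-9)
  expect_equal(fit$gamma$se, unname(ref_gamma[, 2]), tolerance = 1e-9)
  expect_equal(interaction_pvalues(fit), unname(ref_gamma[, 4]),
               tolerance = 1e-9)
  expect_equal(fit$df, ref$df.residual)
  # reconstruction identity
  expect_lt(max(abs(fit$fitted + fit$residuals - y)), 1e-10)
  expect_equal(nrow(fit$gamma), (n_ps - 1) * 3)
})

test_that("parallel probesets give exactly zero interaction terms", {
  design <- generate_design()
  cond <- condition_labels(design)
  shift <- c(control = 0, KA1 = 2, KA4 = 1, KA8 = 0.5)
  n_ps <- 4; n_probes <- 3
  base_ps <- rep(c(7, 8, 9, 10), each = n_probes)
  y <- as.vector(outer(base_ps, shift[as.character(cond)], "+"))
  ps_f <- rep(factor(rep(sprintf("e%d", 1:n_ps), each = n_probes)),
              times = nrow(design))
  cond_f <- rep(cond, each = n_ps * n_probes)
  fit <- anosva_fit_gene(y, ps_f, cond_f)
  expect_lt(max(abs(fit$gamma$estimate)), 1e-10)
  expect_lt(fit$sigma_sq, 1e-20)
})

test_that("a probeset-restricted shift yields the top interaction term", {
  set.seed(56)
  design <- generate_design()
  cond <- condition_labels(design)
  n_ps <- 4; n_probes <- 4
  y <- 8 + rnorm(n_ps * n_probes * nrow(design), 0, 0.2)
  ps_f <- rep(factor(rep(sprintf("e%d", 1:n_ps), each = n_probes)),
              times = nrow(design))
  cond_f <- rep(cond, each = n_ps * n_probes)
  hit <- ps_f == "e2" & cond_f == "KA4"
  y[hit] <- y[hit] + 3
  fit <- anosva_fit_gene(y, ps_f, cond_f)
  p <- interaction_pvalues(fit)
  top <- which.max(abs(fit$gamma$estimate))
  expect_equal(fit$gamma$probeset_id[top], "e2")
  expect_equal(fit$gamma$condition[top], "KA4")
  expect_equal(which.min(p), top)
})

test_that("degenerate designs are skipped rather than fitted", {
  # saturated model: zero residual degrees of freedom
  small <- anosva_fit_gene(rnorm(4), factor(c("e1", "e2", "e1", "e2")),
                           factor(c("c", "c", "k", "k")))
  expect_s3_class(small, "anosva_skip")
  expect_match(small$reason, "degrees of freedom")
  # empty (probeset, condition) cell: rank-deficient design
  rd <- anosva_fit_gene(rnorm(6),
                        factor(c("e1", "e2", "e1", "e2", "e1", "e1")),
                        factor(c("c", "c", "c", "c", "k", "k")))
  expect_s3_class(rd, "anosva_skip")
  expect_match(rd$reason, "rank-deficient")
})

test_that("gene-level calls combine Holm minima with across-gene BH", {
  terms <- tibble::tibble(
    transcript_id = c("g1", "g1", "g2"),
    probeset_id = c("e2", "e3", "e2"),
    condition = c("KA1", "KA4", "KA1"),
    estimate = c(1, 2, 0.1), se = c(0.3, 0.4, 0.3),
    p = c(0.01, 0.04, 0.5))
  out <- gene_level_call(terms, fdr = 0.05)
  g1 <- out$results[out$results$transcript_id == "g1", ]
  expect_equal(g1$p_gene, 0.02)  # Holm: [0.02, 0.04], min = 0.02
  expect_equal(g1$top_probeset_id, "e2")
  expect_equal(out$results$q_gene,
               stats::p.adjust(out$results$p_gene, "BH"))
  # single gene with one weak term: q = p, no call
  solo <- gene_level_call(terms[3, ], fdr = 0.05)
  expect_equal(solo$results$p_gene, 0.5)
  expect_equal(solo$results$q_gene, 0.5)
  expect_false(solo$results$call)
})

test_that("single-timepoint test finds 4h-restricted events only at 4h", {
  cfg <- generator_config(n_transcripts = 80, seed = 57, frac_de = 0,
                          frac_spliced = 0.1, splice_effect = 3, noise_sd = 0.2,
                          splice_conditions = "KA4",
                          frac_absent_probesets = 0, frac_crosshyb = 0)
  g <- generate_dataset(cfg)
  filt <- presence_filter(quantile_normalize(g$dataset))
  spl <- g$truth$transcripts$transcript_id[g$truth$transcripts$spliced]
  an4 <- run_anosva(filt, timepoint = 4)
  an1 <- run_anosva(filt, timepoint = 1)
  antd <- run_anosva(filt)
  called4 <- an4$results$transcript_id[an4$results$call]
  called1 <- an1$results$transcript_id[an1$results$call]
  calledtd <- antd$results$transcript_id[antd$results$call]
  tested_spl <- intersect(spl, an4$results$transcript_id)
  expect_gt(length(intersect(called4, tested_spl)) / length(tested_spl), 0.8)
  expect_length(intersect(called1, tested_spl), 0)
  # single-timepoint discoveries are contained in the time-dependent set
  expect_true(all(called4 %in% calledtd))
  # terms carry the two-level condition factor only
  expect_setequal(unique(an4$terms$condition), "KA4")
})

test_that("interaction p-values are uniform under a model-faithful null", {
  cfg <- generator_config(n_transcripts = 500, seed = 58, frac_de = 0,
                          frac_spliced = 0, frac_absent_probesets = 0,
                          frac_crosshyb = 0, probe_affinity_sd = 0)
  g <- generate_dataset(cfg)
  filt <- presence_filter(quantile_normalize(g$dataset))
  an <- run_anosva(filt)
  ks <- suppressWarnings(stats::ks.test(an$terms$p, "punif"))
  expect_gte(ks$p.value, 0.01)
  expect_lte(mean(an$results$call), 0.005)
})
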