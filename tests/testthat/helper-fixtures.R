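# small in-code fixtures shared across test files

tiny_design <- function() {
  tibble::tibble(
    sample_id = c("a1", "a2", "b1", "b2"),
    treatment = c("untreated", "untreated", "kainate", "kainate"),
    time_h = c(0L, 0L, 4L, 4L),
    replicate = c(1L, 2L, 1L, 2L)
  )
}

# dataset with n_tx transcripts x n_ps probesets x n_probes probes over a
# given design, deterministic values unless noise_sd > 0
tiny_dataset <- function(design = tiny_design(), n_tx = 2, n_ps = 3,
                         n_probes = 2, base = 8, noise_sd = 0, seed = 1) {
  set.seed(seed)
  anno <- tidyr::expand_grid(tx = seq_len(n_tx), ps = seq_len(n_ps),
                             p = seq_len(n_probes))
  anno <- tibble::tibble(
    probe_id = sprintf("t%d_e%d_p%d", anno$tx, anno$ps, anno$p),
    probeset_id = sprintf("t%d_e%d", anno$tx, anno$ps),
    transcript_id = sprintf("t%d", anno$tx),
    probeset_order = anno$ps,
    cross_hybridizing = FALSE
  )
  mat <- matrix(base + stats::rnorm(nrow(anno) * nrow(design), 0, noise_sd),
                nrow(anno), nrow(design),
                dimnames = list(anno$probe_id, design$sample_id))
  exon_dataset(anno, design, mat, scale = "log2")
}

write_sheet <- function(design, path = tempfile(fileext = ".tsv")) {
  write_result_table(design, path)
  path
}

# canonical small synthetic run shared by several files (cached per session)
cached_synth <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- generator_config(n_transcripts = 120, seed = 42,
                              splice_effect = 3, noise_sd = 0.2)
      cache <<- generate_dataset(cfg)
    }
    cache
  }
})
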