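# Small fixtures built in code.

make_em <- function(values, biotype = NULL, feat = NULL, samp = NULL) {
  if (is.null(feat)) feat <- sprintf("MRNA_%04d", seq_len(nrow(values)))
  if (is.null(samp)) samp <- sprintf("S%02d", seq_len(ncol(values)))
  dimnames(values) <- list(feat, samp)
  if (is.null(biotype))
    biotype <- ifelse(grepl("^LNC", feat), "lncRNA", "mRNA")
  expr_matrix(values, biotype)
}

# Random discretized states matrix for oracle checks.
random_states <- function(n_feat, n_samp) {
  matrix(sample(c(-1L, 0L, 1L), n_feat * n_samp, replace = TRUE),
         n_feat, n_samp,
         dimnames = list(sprintf("MRNA_%04d", seq_len(n_feat)),
                         sprintf("S%02d", seq_len(n_samp))))
}

balanced_labels <- function(n_per_group) {
  ids <- sprintf("S%02d", seq_len(2L * n_per_group))
  class_labels(ids, rep(c("case", "control"), each = n_per_group))
}
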