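# Small fixture builders shared across test files.

# genes x samples expr_mat with random log2-like values.
rand_mat <- function(n_genes, n_samples, seed = 1, gene_names = NULL) {
  set.seed(seed)
  if (is.null(gene_names)) gene_names <- sprintf("G%04d", seq_len(n_genes))
  expr_mat(matrix(stats::rnorm(n_genes * n_samples, mean = 6),
                  nrow = n_genes,
                  dimnames = list(gene_names, sprintf("S%03d", seq_len(n_samples)))),
           metadata = list(log_scale = TRUE))
}

# Cohort with planted epithelial and mesenchymal sample populations:
# E-list genes (incl. CDH1) up in the first half, M-list genes up in the
# second half.
planted_em_cohort <- function(n_per_group = 30, n_e = 25, n_m = 25,
                              n_background = 150, effect = 2, seed = 1) {
  set.seed(seed)
  e_genes <- c("CDH1", sprintf("EG%03d", seq_len(n_e - 1)))
  m_genes <- sprintf("MG%03d", seq_len(n_m))
  b_genes <- sprintf("BG%03d", seq_len(n_background))
  n <- 2 * n_per_group
  is_epi <- rep(c(TRUE, FALSE), each = n_per_group)
  vals <- matrix(stats::rnorm((n_e + n_m + n_background) * n, mean = 6),
                 nrow = n_e + n_m + n_background,
                 dimnames = list(c(e_genes, m_genes, b_genes),
                                 sprintf("S%03d", seq_len(n))))
  vals[e_genes, is_epi] <- vals[e_genes, is_epi] + effect
  vals[m_genes, !is_epi] <- vals[m_genes, !is_epi] + effect
  list(matrix = expr_mat(vals, metadata = list(log_scale = TRUE)),
       e_genes = e_genes, m_genes = m_genes, is_epi = is_epi)
}

write_temp_tsv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
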