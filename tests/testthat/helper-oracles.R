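# Independent brute-force oracles used to check the scoring implementations.
# Deliberately written as plain loops, separate from the vectorized package
# code paths.

# Position-by-position running-sum ssGSEA score for one sample.
oracle_ssgsea <- function(x_vec, gene_names, set_genes, alpha = 0.75) {
  N <- length(x_vec)
  stopifnot(length(gene_names) == N)
  ord <- order(-x_vec, gene_names)
  r <- rank(x_vec, ties.method = "average")
  in_set <- gene_names %in% set_genes
  n_s <- sum(in_set)
  w_sum <- sum(r[in_set]^alpha)
  running <- 0
  total <- 0
  for (pos in seq_len(N)) {
    i <- ord[pos]
    if (in_set[i]) {
      running <- running + r[i]^alpha / w_sum
    } else {
      running <- running - 1 / (N - n_s)
    }
    total <- total + running
  }
  unname(total)
}

# Signed two-sample KS statistic by explicit CDF counting on the pooled grid.
oracle_ks_signed <- function(e_vals, m_vals) {
  grid <- sort(unique(c(e_vals, m_vals)))
  d_plus <- -Inf
  d_minus <- -Inf
  for (t in grid) {
    fe <- sum(e_vals <= t) / length(e_vals)
    fm <- sum(m_vals <= t) / length(m_vals)
    d_plus <- max(d_plus, fe - fm)
    d_minus <- max(d_minus, fm - fe)
  }
  if (d_plus >= d_minus) d_plus else -d_minus
}

# Recovery-curve AUC by explicit step-curve accumulation for one cell.
oracle_aucell <- function(x_vec, gene_names, set_genes, top_fraction = 0.05) {
  N <- length(x_vec)
  ord <- order(-x_vec, gene_names)
  k_max <- ceiling(top_fraction * N)
  n_s <- length(intersect(set_genes, gene_names))
  area <- 0
  max_area <- 0
  hits <- 0
  for (k in seq_len(k_max)) {
    if (gene_names[ord[k]] %in% set_genes) hits <- hits + 1
    area <- area + hits
    max_area <- max_area + min(k, n_s)
  }
  area / max_area
}

# Direct-formula 76GS recomputation: sum_g w_g * (x_g - mean_g).
oracle_76gs <- function(values, list_genes, cor_method = "pearson") {
  gs <- intersect(list_genes, rownames(values))
  gs <- gs[apply(values[gs, , drop = FALSE], 1, stats::sd) > 0]
  out <- numeric(ncol(values))
  for (g in gs) {
    w <- stats::cor(values[g, ], values["CDH1", ], method = cor_method)
    out <- out + w * (values[g, ] - mean(values[g, ]))
  }
  unname(out)
}

# Nested-loop curation oracle: per-cohort cor.test threshold counting.
oracle_curate <- function(cohorts, anchor, rho_min, p_max, min_cohorts) {
  genes_all <- rownames(cohorts[[1]]$values)
  counts <- stats::setNames(integer(length(genes_all)), genes_all)
  for (co in cohorts) {
    av <- co$values[anchor, ]
    for (g in rownames(co$values)) {
      ct <- suppressWarnings(
        stats::cor.test(co$values[g, ], av, method = "spearman", exact = FALSE))
      if (!is.na(ct$estimate) && ct$estimate > rho_min && ct$p.value < p_max) {
        counts[g] <- counts[g] + 1
      }
    }
  }
  setdiff(names(counts)[counts >= min_cohorts], anchor)
}

# Log-rank chi-square by hand-rolled event-time tabulation (two groups).
oracle_logrank <- function(time, event, group) {
  g1 <- unique(group)[1]
  o <- 0; e <- 0; v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & group == g1)
    o <- o + d1
    e <- e + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o - e)^2 / v
}

# Area under the ROC curve for scores separating a binary label.
auroc <- function(score, is_positive) {
  r <- rank(score)
  n1 <- sum(is_positive)
  n0 <- sum(!is_positive)
  (sum(r[is_positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
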