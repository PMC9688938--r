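#' EMT gene-list bundle
#'
#' Collects the four gene lists used by the EMT scoring metrics. The
#' epithelial and mesenchymal lists must be disjoint.
#'
#' @param gs76 The 76-gene EMT list (should contain CDH1).
#' @param ks_epithelial,ks_mesenchymal The epithelial / mesenchymal lists
#'   for the signed KS score and the Epi/Mes ssGSEA scores.
#' @param pemt Partial-EMT signature.
#' @return An object of class `emt_gene_lists`.
#' @export
emt_gene_lists <- function(gs76, ks_epithelial, ks_mesenchymal, pemt) {
  gs76 <- as_gene_set(gs76, "GS76")
  e <- as_gene_set(ks_epithelial, "KS_EPI")
  m <- as_gene_set(ks_mesenchymal, "KS_MES")
  p <- as_gene_set(pemt, "PEMT")
  if (length(intersect(e$genes, m$genes)) > 0) {
    stop("epithelial and mesenchymal lists overlap: ",
         paste(utils::head(intersect(e$genes, m$genes), 5), collapse = ", "),
         call. = FALSE)
  }
  structure(list(gs76 = gs76, ks_epithelial = e, ks_mesenchymal = m, pemt = p),
            class = "emt_gene_lists")
}

#' 76GS EMT score
#'
#' CDH1-correlation-weighted sum over the 76-gene EMT list: for each list
#' gene g, the weight is the correlation (across samples) of its expression
#' with CDH1 expression; the per-sample score is `sum_g w_g * (x_g -
#' mean_g)` with per-gene mean-centering across the cohort, so the cohort
#' mean score is 0. Higher scores indicate a more epithelial phenotype; a
#' low 76GS score represents a more mesenchymal one. Because the weights
#' are cohort-level correlations the score is cohort-relative.
#'
#' @param x An [expr_mat()] with >= 2 samples and CDH1 present.
#' @param gs A [gene_set()] or character vector (the 76-gene list).
#' @param cor_method `"pearson"` (default) or `"spearman"` for the weights.
#' @param min_coverage Minimum fraction of the list required present.
#'
#' @return Tibble with columns `sample_id`, `score`; attribute
#'   `"weights"` holds the per-gene weights used.
#' @export
score_76gs <- function(x, gs, cor_method = c("pearson", "spearman"),
                       min_coverage = 0.5) {
  stopifnot(inherits(x, "expr_mat"))
  cor_method <- match.arg(cor_method)
  if (!"CDH1" %in% genes(x)) stop("CDH1 absent from matrix; 76GS weights undefined", call. = FALSE)
  if (ncol(x$values) < 2) stop("need >= 2 samples to estimate CDH1 correlation weights", call. = FALSE)
  present <- resolve_set_genes(x, gs, min_coverage)
  cdh1 <- x$values["CDH1", ]
  if (stats::sd(cdh1) == 0) stop("CDH1 has zero variance; weights undefined", call. = FALSE)
  sub <- x$values[present, , drop = FALSE]
  sds <- apply(sub, 1, stats::sd)
  if (all(sds == 0)) stop("all list genes have zero variance across samples", call. = FALSE)
  if (any(sds == 0)) {
    warning(sprintf("%d zero-variance gene(s) dropped from 76GS", sum(sds == 0)),
            call. = FALSE)
    sub <- sub[sds > 0, , drop = FALSE]
  }
  w <- apply(sub, 1, function(v) stats::cor(v, cdh1, method = cor_method))
  centered <- sub - rowMeans(sub)
  out <- tibble::tibble(sample_id = samples(x),
                        score = as.vector(crossprod(centered, w)))
  attr(out, "weights") <- w
  out
}

# Signed two-sample KS statistic over the pooled value grid.
# Positive when the mesenchymal values stochastically dominate.
ks_signed_stat <- function(e_vals, m_vals) {
  grid <- sort(unique(c(e_vals, m_vals)))
  Fe <- stats::ecdf(e_vals)(grid)
  Fm <- stats::ecdf(m_vals)(grid)
  d_plus <- max(Fe - Fm)     # mesenchymal values higher
  d_minus <- max(Fm - Fe)    # epithelial values higher
  if (abs(d_plus - d_minus) < 1e-9) {
    # pathological crossing: one-sided deviations tie; sign is arbitrary
    message("KS: D+ and D- within 1e-9; sign resolved to the larger-or-equal D+")
  }
  if (d_plus >= d_minus) d_plus else -d_minus
}

#' Signed Kolmogorov-Smirnov EMT score
#'
#' Per sample, the empirical CDFs of the expression values of the
#' epithelial-list genes and of the mesenchymal-list genes are compared:
#' the score is the two-sample KS statistic signed so that positive values
#' mean the mesenchymal genes are expressed higher (mesenchymal phenotype)
#' and negative values mean the epithelial genes dominate. Scores lie in
#' `[-1, 1]`; +1/-1 on perfectly separated value sets. The two-sided KS
#' test p-value is reported per sample.
#'
#' @param x An [expr_mat()].
#' @param epithelial,mesenchymal Gene sets or character vectors; must be
#'   disjoint.
#' @param min_coverage Minimum coverage fraction per list.
#'
#' @return Tibble with columns `sample_id`, `score`, `p_value`.
#' @export
score_ks <- function(x, epithelial, mesenchymal, min_coverage = 0.5) {
  stopifnot(inherits(x, "expr_mat"))
  e <- resolve_set_genes(x, as_gene_set(epithelial, "KS_EPI"), min_coverage)
  m <- resolve_set_genes(x, as_gene_set(mesenchymal, "KS_MES"), min_coverage)
  if (length(intersect(e, m)) > 0) stop("epithelial and mesenchymal lists overlap", call. = FALSE)
  res <- purrr::map(seq_len(ncol(x$values)), function(j) {
    ev <- x$values[e, j]
    mv <- x$values[m, j]
    s <- ks_signed_stat(ev, mv)
    p <- suppressWarnings(stats::ks.test(mv, ev, exact = FALSE)$p.value)
    list(score = s, p_value = p)
  })
  tibble::tibble(sample_id = samples(x),
                 score = purrr::map_dbl(res, "score"),
                 p_value = purrr::map_dbl(res, "p_value"))
}

#' Epi / Mes / pEMT ssGSEA scores
#'
#' Thin wrapper running [ssgsea_score()] on the KS epithelial list (Epi),
#' the KS mesenchymal list (Mes) and the partial-EMT signature (pEMT).
#'
#' @param x An [expr_mat()].
#' @param lists An [emt_gene_lists()].
#' @param ... Passed to [ssgsea_score()] (exponent, normalization).
#' @return Tibble with columns `sample_id`, `Epi`, `Mes`, `pEMT`.
#' @export
score_epi_mes_pemt <- function(x, lists, ...) {
  stopifnot(inherits(lists, "emt_gene_lists"))
  tibble::tibble(
    sample_id = samples(x),
    Epi = ssgsea_score(x, lists$ks_epithelial, ...)$score,
    Mes = ssgsea_score(x, lists$ks_mesenchymal, ...)$score,
    pEMT = ssgsea_score(x, lists$pemt, ...)$score)
}

#' All four EMT metrics in one table
#'
#' @param x An [expr_mat()].
#' @param lists An [emt_gene_lists()].
#' @param ... Passed to [ssgsea_score()].
#' @return Tibble: `sample_id`, `GS76`, `KS`, `KS_p`, `Epi`, `Mes`, `pEMT`.
#' @export
score_emt <- function(x, lists, ...) {
  stopifnot(inherits(lists, "emt_gene_lists"))
  ks <- score_ks(x, lists$ks_epithelial, lists$ks_mesenchymal)
  score_epi_mes_pemt(x, lists, ...) |>
    dplyr::mutate(GS76 = score_76gs(x, lists$gs76)$score,
                  KS = ks$score, KS_p = ks$p_value, .after = "sample_id")
}
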