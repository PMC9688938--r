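#' @importFrom rlang .data
NULL

# Intersect a gene set with the matrix universe, enforcing the minimum
# coverage fraction. Returns the present genes, warning about the missing.
resolve_set_genes <- function(x, gs, min_coverage = 0.5) {
  gs <- as_gene_set(gs)
  present <- intersect(gs$genes, genes(x))
  if (length(present) == 0) {
    stop("no gene of set '", gs$name, "' is present in the matrix", call. = FALSE)
  }
  cov <- length(present) / length(gs$genes)
  if (cov < min_coverage) {
    stop(sprintf("set '%s': only %.0f%% of genes present (< %.0f%% minimum coverage)",
                 gs$name, 100 * cov, 100 * min_coverage), call. = FALSE)
  }
  if (length(present) < length(gs$genes)) {
    warning(sprintf("set '%s': %d of %d genes absent from matrix, dropped",
                    gs$name, length(gs$genes) - length(present), length(gs$genes)),
            call. = FALSE)
  }
  present
}

#' Single-sample GSEA (ssGSEA) scores
#'
#' For each sample, genes are ordered by decreasing expression (ties get
#' average rank values; tied positions are ordered deterministically by
#' gene symbol). Walking down the ranked list, the running sum increases at
#' in-set genes by `rank^weight_exponent` (normalized to sum to 1 over the
#' in-set genes, with rank counted so the most highly expressed gene has
#' the largest rank value) and decreases at out-of-set genes by
#' `1/(N - |S|)`. The ssGSEA score is the sum of the running-sum values
#' over all N positions — the integral form, not the maximum deviation.
#' With `normalize = "range"` all samples' scores are divided by
#' `max - min` of the raw scores across the cohort, giving the normalized
#' enrichment score (NES); NES values are therefore cohort-relative.
#'
#' @param x An [expr_mat()] (log2 scale).
#' @param gs A [gene_set()] or character vector of gene symbols.
#' @param weight_exponent Non-negative rank-weighting exponent
#'   (default 0.75, the convention of the ssGSEA tool family).
#' @param normalize `"range"` (default, NES) or `"none"` (raw scores).
#' @param min_coverage Minimum fraction of the set that must be present in
#'   the matrix (default 0.5); below it scoring refuses.
#'
#' @return Tibble with columns `sample_id`, `score`.
#' @export
ssgsea_score <- function(x, gs, weight_exponent = 0.75,
                         normalize = c("range", "none"), min_coverage = 0.5) {
  stopifnot(inherits(x, "expr_mat"), weight_exponent >= 0)
  normalize <- match.arg(normalize)
  set_genes <- resolve_set_genes(x, gs, min_coverage)
  N <- nrow(x$values)
  nS <- length(set_genes)
  if (nS == N) stop("gene set equals the whole universe; out-of-set decrement undefined", call. = FALSE)
  in_set <- genes(x) %in% set_genes
  gname <- genes(x)
  raw <- vapply(seq_len(ncol(x$values)), function(j) {
    v <- x$values[, j]
    ord <- order(-v, gname)                       # deterministic within ties
    r <- rank(v, ties.method = "average")         # high expression -> high rank
    w <- r^weight_exponent
    io <- in_set[ord]
    wo <- w[ord]
    step <- numeric(N)
    step[io] <- wo[io] / sum(wo[io])
    step[!io] <- -1 / (N - nS)
    sum(cumsum(step))
  }, numeric(1))
  score <- raw
  if (normalize == "range") {
    rng <- max(raw) - min(raw)
    if (rng > 0) score <- raw / rng
  }
  tibble::tibble(sample_id = samples(x), score = score)
}

#' AUCell-style recovery-curve AUC scores
#'
#' Per cell, genes are ranked by decreasing expression (ties broken
#' deterministically by gene symbol order). The recovery curve counts the
#' set genes among the top k ranked genes for k = 1..ceiling(top_fraction
#' * N); the score is the area under this step curve normalized so the
#' maximum possible area (set genes packing the top ranks) equals 1.
#'
#' @param x An [expr_mat()]; columns are cells.
#' @param gs A [gene_set()] or character vector.
#' @param top_fraction Fraction of the ranking that defines the recovery
#'   window (default 0.05, the AUCell default).
#' @param min_coverage Minimum set coverage as in [ssgsea_score()].
#'
#' @return Tibble with columns `sample_id`, `score` (AUC in `[0, 1]`).
#' @export
aucell_score <- function(x, gs, top_fraction = 0.05, min_coverage = 0.5) {
  stopifnot(inherits(x, "expr_mat"), top_fraction > 0, top_fraction <= 1)
  set_genes <- resolve_set_genes(x, gs, min_coverage)
  N <- nrow(x$values)
  nS <- length(set_genes)
  k_max <- ceiling(top_fraction * N)
  in_set <- genes(x) %in% set_genes
  gname <- genes(x)
  max_area <- sum(pmin(seq_len(k_max), nS))
  auc <- vapply(seq_len(ncol(x$values)), function(j) {
    ord <- order(-x$values[, j], gname)
    hits <- cumsum(in_set[ord][seq_len(k_max)])
    sum(hits) / max_area
  }, numeric(1))
  tibble::tibble(sample_id = samples(x), score = auc)
}

#' Target-set activity scores (AMPK / HIF-1alpha style)
#'
#' Activity of a regulator proxied by its downstream target genes. With
#' `method = "mean_z"` each present target gene is z-scored across samples
#' and the per-sample mean of the z-scores is returned; with
#' `method = "first_pc"` samples are projected on the first principal axis
#' of the z-scored target submatrix, sign-oriented so the projection
#' correlates positively with the mean-z score.
#'
#' @param x An [expr_mat()].
#' @param gs A [gene_set()] or character vector of target genes (>=2 must
#'   be present).
#' @param method `"mean_z"` (default) or `"first_pc"`.
#' @param min_coverage Minimum set coverage as in [ssgsea_score()].
#'
#' @return Tibble with columns `sample_id`, `score`; attribute `"method"`
#'   records the method used.
#' @export
target_activity_score <- function(x, gs, method = c("mean_z", "first_pc"),
                                  min_coverage = 0.5) {
  stopifnot(inherits(x, "expr_mat"))
  method <- match.arg(method)
  present <- resolve_set_genes(x, gs, min_coverage)
  if (length(present) < 2) stop("need >= 2 target genes present", call. = FALSE)
  sub <- x$values[present, , drop = FALSE]
  sds <- apply(sub, 1, stats::sd)
  if (all(sds == 0)) stop("all target genes have zero variance across samples", call. = FALSE)
  if (any(sds == 0)) {
    warning(sprintf("%d target gene(s) with zero variance dropped", sum(sds == 0)),
            call. = FALSE)
    sub <- sub[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  z <- (sub - rowMeans(sub)) / sds
  mean_z <- colMeans(z)
  score <- if (method == "mean_z") {
    mean_z
  } else {
    pc <- stats::prcomp(t(z), center = TRUE, scale. = FALSE)
    proj <- pc$x[, 1]
    if (stats::cor(proj, mean_z) < 0) proj <- -proj
    proj
  }
  out <- tibble::tibble(sample_id = samples(x), score = unname(score))
  attr(out, "method") <- method
  out
}

#' Fatty-acid-oxidation (FAO) enzyme score
#'
#' Weighted sum of z-scored expression of FAO enzyme genes. Default
#' weights are uniform `1/|S|` over the present genes; study-specific
#' weights can be supplied directly or loaded from a two-column TSV
#' (`gene`, `weight`) via [read_weights()].
#'
#' @param x An [expr_mat()].
#' @param gs A [gene_set()] or character vector of FAO enzyme genes.
#' @param weights Optional named numeric vector of per-gene weights.
#' @param min_coverage Minimum set coverage as in [ssgsea_score()].
#'
#' @return Tibble with columns `sample_id`, `score`.
#' @export
fao_score <- function(x, gs, weights = NULL, min_coverage = 0.5) {
  stopifnot(inherits(x, "expr_mat"))
  present <- resolve_set_genes(x, gs, min_coverage)
  if (length(present) < 2) stop("need >= 2 FAO genes present", call. = FALSE)
  if (is.null(weights)) {
    weights <- stats::setNames(rep(1 / length(present), length(present)), present)
  } else {
    names(weights) <- toupper(names(weights))
    absent <- setdiff(names(weights), genes(x))
    if (length(absent) > 0) {
      warning("weights given for absent gene(s): ", paste(absent, collapse = ", "),
              call. = FALSE)
    }
    weights <- weights[intersect(names(weights), present)]
    if (length(weights) == 0) stop("no weighted gene present in the matrix", call. = FALSE)
    present <- names(weights)
  }
  sub <- x$values[present, , drop = FALSE]
  sds <- apply(sub, 1, stats::sd)
  z <- sub
  z[sds > 0, ] <- (sub[sds > 0, , drop = FALSE] - rowMeans(sub[sds > 0, , drop = FALSE])) / sds[sds > 0]
  z[sds == 0, ] <- 0
  tibble::tibble(sample_id = samples(x),
                 score = as.vector(crossprod(z, weights[present])))
}

#' Read per-gene weights from a two-column TSV
#'
#' @param path TSV with columns `gene`, `weight`.
#' @return Named numeric vector.
#' @export
read_weights <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    gene = readr::col_character(), weight = readr::col_double()))
  stats::setNames(df$weight, toupper(df$gene))
}

#' Score many gene sets into a wide score table
#'
#' Convenience wrapper building a samples x metrics tibble from ssGSEA
#' and/or AUCell scores plus raw expression columns (`EXPR:<gene>`).
#'
#' @param x An [expr_mat()].
#' @param sets A `gene_set_collection` (or named list of sets/vectors) for
#'   ssGSEA NES columns, named `NES:<set>`.
#' @param aucell_sets Optional collection for AUCell columns `AUC:<set>`.
#' @param expr_genes Optional gene symbols whose expression is copied into
#'   `EXPR:<gene>` columns.
#' @param ... Passed to [ssgsea_score()].
#'
#' @return Tibble: `sample_id` plus one column per metric.
#' @export
score_table <- function(x, sets = NULL, aucell_sets = NULL,
                        expr_genes = NULL, ...) {
  out <- tibble::tibble(sample_id = samples(x))
  for (nm in names(sets)) {
    out[[paste0("NES:", nm)]] <- ssgsea_score(x, as_gene_set(sets[[nm]], nm), ...)$score
  }
  for (nm in names(aucell_sets)) {
    out[[paste0("AUC:", nm)]] <-
      aucell_score(x, as_gene_set(aucell_sets[[nm]], nm))$score
  }
  for (g in expr_genes) {
    g <- toupper(g)
    if (!g %in% genes(x)) {
      warning("gene ", g, " absent from matrix; EXPR column skipped", call. = FALSE)
      next
    }
    out[[paste0("EXPR:", g)]] <- x$values[g, ]
  }
  out
}
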