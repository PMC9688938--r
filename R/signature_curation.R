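# Spearman rho of every gene against an anchor vector, with the
# large-sample t-approximation p-value.
spearman_vs_anchor <- function(values, anchor_vec) {
  n <- length(anchor_vec)
  ra <- rank(anchor_vec)
  rg <- t(apply(values, 1, rank))
  rho <- as.vector(stats::cor(t(rg), ra))
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  tibble::tibble(gene = rownames(values), rho = rho, p_value = p)
}

#' Curate an anchor-gene co-expression signature across a compendium
#'
#' Implements pan-cancer co-expression curation: per cohort, every gene is
#' correlated (Spearman) with the anchor gene (default CD274/PD-L1); a
#' gene qualifies in a cohort iff `rho > rho_min` and `p < p_max` (strict,
#' raw p — no multiple-testing correction, matching the published rule);
#' the returned signature is the set of genes qualifying in at least
#' `min_cohorts` cohorts. p-values use the large-sample t-approximation
#' for Spearman's rho; cohorts with fewer than 4 samples are excluded with
#' a warning (the approximation is unstable there).
#'
#' @param compendium Named list of [expr_mat()] cohorts (>= 2), each with
#'   the anchor gene present and non-constant.
#' @param anchor Anchor gene symbol (default `"CD274"`).
#' @param rho_min Spearman threshold (default 0.5, strict `>`).
#' @param p_max p-value threshold (default 0.01, strict `<`).
#' @param min_cohorts Minimum number of qualifying cohorts (default 15).
#' @param include_anchor Keep the anchor itself in the signature? Default
#'   `FALSE`: including it would make anchor-vs-signature correlations
#'   partially circular downstream.
#'
#' @return A [gene_set()] (role `"signature"`); attribute `"tally"` is a
#'   tibble of per-gene qualifying-cohort counts.
#' @export
curate_signature <- function(compendium, anchor = "CD274", rho_min = 0.5,
                             p_max = 0.01, min_cohorts = 15,
                             include_anchor = FALSE) {
  stopifnot(is.list(compendium), length(compendium) >= 2,
            rho_min > 0, rho_min < 1, p_max > 0, p_max < 1)
  anchor <- toupper(anchor)
  usable <- purrr::keep(compendium, function(co) {
    if (ncol(co$values) < 4) {
      warning("cohort with ", ncol(co$values),
              " samples excluded (p-value unstable below 4)", call. = FALSE)
      return(FALSE)
    }
    TRUE
  })
  if (length(usable) == 0) stop("all cohorts excluded (< 4 samples each)", call. = FALSE)
  if (min_cohorts < 1 || min_cohorts > length(usable)) {
    stop("min_cohorts must be between 1 and the number of usable cohorts", call. = FALSE)
  }
  tallies <- purrr::imap(usable, function(co, id) {
    if (!anchor %in% genes(co)) stop("anchor ", anchor, " absent from cohort ", id, call. = FALSE)
    av <- co$values[anchor, ]
    if (stats::sd(av) == 0) stop("anchor ", anchor, " constant in cohort ", id, call. = FALSE)
    spearman_vs_anchor(co$values, av) |>
      dplyr::filter(.data$rho > rho_min, .data$p_value < p_max) |>
      dplyr::pull("gene")
  })
  tally <- tibble::tibble(gene = unlist(tallies, use.names = FALSE)) |>
    dplyr::count(.data$gene, name = "n_cohorts") |>
    dplyr::arrange(dplyr::desc(.data$n_cohorts), .data$gene)
  hits <- tally |> dplyr::filter(.data$n_cohorts >= min_cohorts) |> dplyr::pull("gene")
  if (!include_anchor) hits <- setdiff(hits, anchor)
  if (length(hits) == 0) {
    warning("no gene qualified in >= ", min_cohorts, " cohorts; empty signature", call. = FALSE)
    out <- structure(list(name = paste0(anchor, "_SIGNATURE"), genes = character(0),
                          role = "signature"), class = "gene_set")
  } else {
    out <- gene_set(paste0(anchor, "_SIGNATURE"), hits, role = "signature")
  }
  attr(out, "tally") <- tally
  out
}
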