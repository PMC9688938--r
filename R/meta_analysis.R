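#' Correlate two score-table metrics within one dataset
#'
#' Spearman (default) or Pearson correlation with a two-sided p-value.
#' Spearman p-values use the t-approximation on ranked data (ties handled
#' by average ranks). A constant metric yields `rho = NA` with
#' `undefined = TRUE` so callers can exclude the record downstream.
#'
#' @param scores A score table: tibble with `sample_id` plus metric
#'   columns.
#' @param metric_x,metric_y Column names to correlate.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param dataset_id Identifier stamped on the record (default `NA`).
#'
#' @return One-row tibble: `dataset_id`, `metric_x`, `metric_y`, `rho`,
#'   `p_value`, `n_samples`, `undefined`.
#' @export
correlate_pair <- function(scores, metric_x, metric_y,
                           method = c("spearman", "pearson"),
                           dataset_id = NA_character_) {
  method <- match.arg(method)
  for (m in c(metric_x, metric_y)) {
    if (!m %in% names(scores)) stop("metric '", m, "' not in score table", call. = FALSE)
  }
  xv <- scores[[metric_x]]
  yv <- scores[[metric_y]]
  ok <- is.finite(xv) & is.finite(yv)
  xv <- xv[ok]; yv <- yv[ok]
  n <- length(xv)
  if (n < 3) stop("need >= 3 paired finite values", call. = FALSE)
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0) {
    return(tibble::tibble(dataset_id = dataset_id, metric_x = metric_x,
                          metric_y = metric_y, rho = NA_real_,
                          p_value = NA_real_, n_samples = n, undefined = TRUE))
  }
  ct <- suppressWarnings(stats::cor.test(xv, yv, method = method, exact = FALSE))
  p <- max(ct$p.value, .Machine$double.xmin)   # guard p -> 0 at rho = +/-1
  tibble::tibble(dataset_id = dataset_id, metric_x = metric_x,
                 metric_y = metric_y, rho = unname(ct$estimate),
                 p_value = p, n_samples = n, undefined = FALSE)
}

#' Volcano-style significance classification across datasets
#'
#' A dataset's correlation is significant iff `|rho| > r_threshold` and
#' `p < p_threshold` (both strict, the published boundary convention);
#' significant records are classified positive/negative by the sign of
#' rho. Records with undefined rho (constant metric) are excluded from the
#' totals with a message. A Benjamini-Hochberg adjusted p column is
#' emitted for transparency but never used for the counts (the headline
#' counts follow raw p-values).
#'
#' @param records Tibble of correlation records ([correlate_pair()] rows);
#'   all must share the same metric pair.
#' @param r_threshold Correlation-magnitude boundary (default 0.3).
#' @param p_threshold p-value boundary (default 0.05).
#'
#' @return Object of class `volcano_summary`: the per-record
#'   classification tibble (columns `significant`, `direction`, `p_bh`
#'   added) with the summary counts as attributes; see
#'   [glance.volcano_summary()].
#' @export
volcano_classify <- function(records, r_threshold = 0.3, p_threshold = 0.05) {
  records <- tibble::as_tibble(records)
  pairs <- dplyr::distinct(records, .data$metric_x, .data$metric_y)
  if (nrow(pairs) > 1) stop("records mix metric pairs; classify one pair at a time", call. = FALSE)
  n_undef <- sum(records$undefined %||% is.na(records$rho))
  if (n_undef > 0) {
    message(n_undef, " record(s) with undefined rho excluded from volcano totals")
  }
  rec <- records |>
    dplyr::filter(!is.na(.data$rho)) |>
    dplyr::mutate(
      p_bh = stats::p.adjust(.data$p_value, method = "BH"),
      significant = abs(.data$rho) > r_threshold & .data$p_value < p_threshold,
      direction = dplyr::case_when(
        !.data$significant ~ "ns",
        .data$rho > 0 ~ "positive",
        TRUE ~ "negative"))
  structure(rec, class = c("volcano_summary", class(rec)),
            r_threshold = r_threshold, p_threshold = p_threshold,
            n_total = nrow(rec),
            n_significant = sum(rec$significant),
            n_positive = sum(rec$direction == "positive"),
            n_negative = sum(rec$direction == "negative"))
}

#' @describeIn volcano_classify One-row summary: totals, positive /
#'   negative counts and the positive fraction among significant datasets.
#' @param x A `volcano_summary`.
#' @param ... Unused.
#' @export
glance.volcano_summary <- function(x, ...) {
  ns <- attr(x, "n_significant")
  tibble::tibble(
    metric_x = x$metric_x[1], metric_y = x$metric_y[1],
    n_total = attr(x, "n_total"), n_significant = ns,
    n_positive = attr(x, "n_positive"), n_negative = attr(x, "n_negative"),
    positive_fraction = if (ns > 0) attr(x, "n_positive") / ns else NA_real_,
    r_threshold = attr(x, "r_threshold"), p_threshold = attr(x, "p_threshold"))
}

#' Quadrant counts over datasets significant in both metric pairs
#'
#' Joins two sets of correlation records by `dataset_id`, keeps only the
#' datasets significant (at the same thresholds) in *both* pairs, and
#' counts them by the quadrant of (sign(rho_x), sign(rho_y)).
#'
#' @param records_x,records_y Correlation-record tibbles for the two
#'   pairs, keyed by `dataset_id` (no duplicates within one pair).
#' @param r_threshold,p_threshold Shared significance boundaries.
#'
#' @return Tibble with columns `quadrant` (`"++"`, `"+-"`, `"-+"`,
#'   `"--"`) and `n`; attribute `"joined"` carries the per-dataset table.
#' @export
quadrant_count <- function(records_x, records_y, r_threshold = 0.3,
                           p_threshold = 0.05) {
  for (r in list(records_x, records_y)) {
    if (anyDuplicated(r$dataset_id)) {
      stop("duplicated dataset_id within one pair: ",
           r$dataset_id[duplicated(r$dataset_id)][1], call. = FALSE)
    }
  }
  sig <- function(r) {
    r |>
      dplyr::filter(!is.na(.data$rho),
                    abs(.data$rho) > r_threshold, .data$p_value < p_threshold)
  }
  joined <- dplyr::inner_join(
    sig(records_x) |> dplyr::select("dataset_id", rho_x = "rho"),
    sig(records_y) |> dplyr::select("dataset_id", rho_y = "rho"),
    by = "dataset_id") |>
    dplyr::mutate(quadrant = paste0(ifelse(.data$rho_x > 0, "+", "-"),
                                    ifelse(.data$rho_y > 0, "+", "-")))
  counts <- tibble::tibble(quadrant = c("++", "+-", "-+", "--")) |>
    dplyr::left_join(dplyr::count(joined, .data$quadrant), by = "quadrant") |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
  attr(counts, "joined") <- joined
  counts
}

#' Checkpoint-gene x hallmark-signature correlation table
#'
#' Spearman correlation of each immune-checkpoint gene's expression column
#' against each hallmark-signature score column, with cells flagged
#' insignificant ("X" in the published heatmaps) when `p > p_threshold`.
#'
#' @param scores Score table with `EXPR:` gene columns and hallmark metric
#'   columns.
#' @param checkpoint_genes Gene symbols (matched to `EXPR:<gene>` columns,
#'   or used verbatim if the bare name is a column).
#' @param hallmark_metrics Metric column names.
#' @param p_threshold Significance boundary (default 0.05, inclusive:
#'   significant iff `p <= p_threshold`).
#'
#' @return Long tibble of class `checkpoint_table`: `gene`, `metric`,
#'   `rho`, `p_value`, `significant`.
#' @export
checkpoint_hallmark_table <- function(scores, checkpoint_genes,
                                      hallmark_metrics, p_threshold = 0.05) {
  rows <- purrr::map(checkpoint_genes, function(g) {
    col <- if (g %in% names(scores)) g else paste0("EXPR:", toupper(g))
    if (!col %in% names(scores)) {
      warning("no expression column for gene ", g, "; row emitted as missing",
              call. = FALSE)
      return(tibble::tibble(gene = g, metric = hallmark_metrics,
                            rho = NA_real_, p_value = NA_real_,
                            significant = NA))
    }
    purrr::map(hallmark_metrics, function(m) {
      rec <- correlate_pair(scores, col, m, method = "spearman")
      tibble::tibble(gene = g, metric = m, rho = rec$rho, p_value = rec$p_value,
                     significant = !is.na(rec$p_value) & rec$p_value <= p_threshold)
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  structure(rows, class = c("checkpoint_table", class(rows)),
            p_threshold = p_threshold)
}
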