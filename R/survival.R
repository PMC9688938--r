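#' Median-split stratification into P+G+ / P+G- groups
#'
#' Samples strictly above the cohort median of a metric are "high"; ties
#' at the median go to "low". `P+G+` = high on both PD-L1 and glycolysis;
#' `P+G-` = high PD-L1, low glycolysis; everything else is `other` and is
#' excluded from the two-group survival comparison.
#'
#' @param scores Score table (tibble with `sample_id` + metric columns).
#' @param pdl1_metric,glycolysis_metric Column names of the two markers
#'   (e.g. `"EXPR:CD274"` and `"NES:GLYCOLYSIS"`).
#'
#' @return Tibble of class `group_assignment`: `sample_id`, `pdl1_high`,
#'   `glycolysis_high`, `group`; attribute `"split_rule"` records the two
#'   (marker, threshold) pairs for reproducibility.
#' @export
median_split <- function(scores, pdl1_metric, glycolysis_metric) {
  for (m in c(pdl1_metric, glycolysis_metric)) {
    if (!m %in% names(scores)) stop("metric '", m, "' not in score table", call. = FALSE)
    if (stats::sd(scores[[m]]) == 0) {
      stop("metric '", m, "' is constant; median split degenerate", call. = FALSE)
    }
  }
  if (nrow(scores) < 4) stop("need >= 4 samples for a median split", call. = FALSE)
  mp <- stats::median(scores[[pdl1_metric]])
  mg <- stats::median(scores[[glycolysis_metric]])
  out <- scores |>
    dplyr::transmute(
      sample_id = .data$sample_id,
      pdl1_high = .data[[pdl1_metric]] > mp,
      glycolysis_high = .data[[glycolysis_metric]] > mg,
      group = dplyr::case_when(
        .data$pdl1_high & .data$glycolysis_high ~ "P+G+",
        .data$pdl1_high & !.data$glycolysis_high ~ "P+G-",
        TRUE ~ "other"))
  structure(out, class = c("group_assignment", class(out)),
            split_rule = tibble::tibble(
              marker = c(pdl1_metric, glycolysis_metric),
              threshold = c(mp, mg)))
}

# Join clinical records to a two-level group assignment, dropping "other".
join_survival_groups <- function(cohort, groups,
                                 levels = c("P+G-", "P+G+")) {
  cohort <- tibble::as_tibble(cohort)
  cohort$group <- NULL   # assignment, not the clinical table, defines groups
  dat <- dplyr::inner_join(cohort,
                           tibble::as_tibble(groups)[, c("sample_id", "group")],
                           by = "sample_id") |>
    dplyr::filter(.data$group %in% levels)
  for (lv in levels) {
    if (!lv %in% dat$group) stop("group '", lv, "' has zero samples", call. = FALSE)
  }
  if (anyNA(dat$os_time) || any(dat$os_time < 0)) stop("missing or negative survival times", call. = FALSE)
  if (!all(dat$os_event %in% c(0, 1))) stop("os_event must be 0/1", call. = FALSE)
  dat$group <- factor(dat$group, levels = levels)
  dat
}

#' Kaplan-Meier curves and log-rank test for two groups
#'
#' Product-limit survival estimates per group and the two-group log-rank
#' chi-square test, via the survival package. Requires at least one
#' observed event in the pooled groups (with every observation censored
#' the log-rank statistic is undefined).
#'
#' @param cohort Tibble with columns `sample_id`, `os_time`, `os_event`
#'   (1 = death observed, 0 = censored; times in consistent units).
#' @param groups A [median_split()] assignment (or tibble with
#'   `sample_id`, `group`); only `P+G+`/`P+G-` rows are used.
#' @param levels Group labels compared (default `c("P+G-", "P+G+")`).
#'
#' @return Object of class `km_result`: list with the `survfit` object,
#'   `logrank_chisq`, `logrank_p`, `n_per_group`. `tidy()` returns the
#'   per-group step table, `glance()` the test summary.
#' @export
kaplan_meier <- function(cohort, groups, levels = c("P+G-", "P+G+")) {
  dat <- join_survival_groups(cohort, groups, levels)
  if (sum(dat$os_event) == 0) stop("all observations censored; log-rank test undefined", call. = FALSE)
  fit <- survival::survfit(survival::Surv(os_time, os_event) ~ group, data = dat)
  if (length(unique(dat$group)) > 1) {
    sd <- survival::survdiff(survival::Surv(os_time, os_event) ~ group, data = dat)
    chisq <- unname(sd$chisq)
    p <- stats::pchisq(sd$chisq, df = length(sd$n) - 1, lower.tail = FALSE)
  } else {
    chisq <- NA_real_   # single-stratum estimate: no between-group test
    p <- NA_real_
  }
  structure(list(fit = fit, data = dat,
                 logrank_chisq = chisq, logrank_p = p,
                 n_per_group = table(dat$group)),
            class = "km_result")
}

#' @export
print.km_result <- function(x, ...) {
  cat("<km_result>\n")
  print(x$n_per_group)
  cat(sprintf("  log-rank chisq = %.3f, p = %.3g\n", x$logrank_chisq, x$logrank_p))
  invisible(x)
}

#' @describeIn kaplan_meier Per-group survival step table (time, n.risk,
#'   n.event, survival estimate, std.error).
#' @param x A `km_result`.
#' @param ... Unused.
#' @export
tidy.km_result <- function(x, ...) {
  s <- summary(x$fit, censored = TRUE)
  grp <- if (is.null(s$strata)) {
    rep(as.character(unique(x$data$group))[1], length(s$time))
  } else {
    as.character(s$strata)
  }
  tibble::tibble(
    group = sub("^group=", "", grp),
    time = s$time, n_risk = s$n.risk, n_event = s$n.event,
    estimate = s$surv, std_error = s$std.err)
}

#' @describeIn kaplan_meier One-row log-rank summary.
#' @export
glance.km_result <- function(x, ...) {
  tibble::tibble(logrank_chisq = x$logrank_chisq, logrank_p = x$logrank_p,
                 n = sum(x$n_per_group), n_events = sum(x$data$os_event))
}

#' Cox proportional-hazards comparison of two groups
#'
#' Single binary-covariate Cox partial-likelihood fit (Efron handling of
#' tied event times). The hazard ratio is for the second level versus the
#' first (default: `P+G+` vs `P+G-`), with a Wald 95% CI and `log2_hr =
#' log2(HR)`; `log2_hr > 0` means increased risk for the second level.
#' Monotone likelihood (complete separation) is flagged, not fatal:
#' `infinite = TRUE` with an infinite HR marker.
#'
#' @inheritParams kaplan_meier
#'
#' @return Object of class `cox_result` with fields `hazard_ratio`,
#'   `ci_low`, `ci_high`, `log2_hr`, `p_value`, `n_per_group`,
#'   `infinite`; `tidy()`/`glance()` return one-row tibbles.
#' @export
cox_hr <- function(cohort, groups, levels = c("P+G-", "P+G+")) {
  dat <- join_survival_groups(cohort, groups, levels)
  for (lv in levels) {
    if (sum(dat$os_event[dat$group == lv]) == 0) {
      stop("group '", lv, "' has zero observed events", call. = FALSE)
    }
  }
  flagged <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(os_time, os_event) ~ group, data = dat,
                    ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|converge", conditionMessage(w))) {
        flagged <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  beta <- unname(stats::coef(fit)[1])
  se <- sqrt(stats::vcov(fit)[1, 1])
  infinite <- flagged || abs(beta) > 15
  sm <- summary(fit)
  structure(list(
    hazard_ratio = exp(beta),
    ci_low = exp(beta - 1.96 * se),
    ci_high = exp(beta + 1.96 * se),
    log2_hr = beta / log(2),
    p_value = unname(sm$coefficients[1, "Pr(>|z|)"]),
    n_per_group = table(dat$group),
    levels = levels,
    infinite = infinite,
    fit = fit), class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("<cox_result> HR[%s vs %s] = %.3f (95%% CI %.3f-%.3f), log2HR = %.3f, p = %.3g%s\n",
              x$levels[2], x$levels[1], x$hazard_ratio, x$ci_low, x$ci_high,
              x$log2_hr, x$p_value,
              if (x$infinite) " [monotone likelihood: HR unreliable]" else ""))
  invisible(x)
}

#' @describeIn cox_hr One-row coefficient table.
#' @param x A `cox_result`.
#' @param ... Unused.
#' @export
tidy.cox_result <- function(x, ...) {
  tibble::tibble(contrast = paste(x$levels[2], "vs", x$levels[1]),
                 hazard_ratio = x$hazard_ratio, ci_low = x$ci_low,
                 ci_high = x$ci_high, log2_hr = x$log2_hr,
                 p_value = x$p_value, infinite = x$infinite)
}

#' @describeIn cox_hr One-row fit summary with group sizes.
#' @export
glance.cox_result <- function(x, ...) {
  tibble::tibble(n = sum(x$n_per_group),
                 n_low = unname(x$n_per_group[1]),
                 n_high = unname(x$n_per_group[2]),
                 p_value = x$p_value)
}

#' Hazard ratio for high vs low expression of one gene or metric
#'
#' Median-splits a single score-table column into high/low (ties to low)
#' and runs [cox_hr()]; the building block of forest-plot tables across
#' cancer types.
#'
#' @param cohort Clinical tibble (`sample_id`, `os_time`, `os_event`).
#' @param scores Score table containing `gene_metric`.
#' @param gene_metric Column to split on (e.g. `"EXPR:CD274"`).
#'
#' @return A `cox_result` (high vs low).
#' @export
hazard_by_gene <- function(cohort, scores, gene_metric) {
  if (!gene_metric %in% names(scores)) stop("metric '", gene_metric, "' not in score table", call. = FALSE)
  v <- scores[[gene_metric]]
  if (stats::sd(v) == 0) stop("metric '", gene_metric, "' is constant", call. = FALSE)
  grp <- tibble::tibble(
    sample_id = scores$sample_id,
    group = ifelse(v > stats::median(v), "high", "low"))
  cox_hr(cohort, grp, levels = c("low", "high"))
}
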