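test_that("median split follows the strict-above rule, ties to low", {
  tab <- tibble::tibble(sample_id = paste0("S", 1:4),
                        pdl1 = c(1, 2, 3, 4), glyc = c(4, 3, 2, 1))
  grp <- median_split(tab, "pdl1", "glyc")
  # medians 2.5: pdl1 high = S3,S4; glyc high = S1,S2 -> no P+G+, P+G- = S3,S4
  expect_identical(grp$group, c("other", "other", "P+G-", "P+G-"))
  rule <- attr(grp, "split_rule")
  expect_equal(rule$threshold, c(2.5, 2.5))

  # perfectly concordant markers leave P+G- empty
  tab2 <- tibble::tibble(sample_id = paste0("S", 1:6), a = 1:6, b = 1:6)
  grp2 <- median_split(tab2, "a", "b")
  expect_equal(sum(grp2$group == "P+G-"), 0)
  expect_equal(sum(grp2$group == "P+G+"), 3)

  expect_error(median_split(dplyr::mutate(tab, pdl1 = 1), "pdl1", "glyc"),
               "constant")
})

test_that("independent markers split roughly a quarter of samples per joint group", {
  set.seed(103)
  tab <- tibble::tibble(sample_id = sprintf("S%03d", 1:100),
                        p = stats::runif(100), g = stats::runif(100))
  grp <- median_split(tab, "p", "g")
  expect_true(abs(sum(grp$group == "P+G+") - 25) <= 10)
  expect_true(abs(sum(grp$group == "P+G-") - 25) <= 10)
})

test_that("Kaplan-Meier estimate matches the textbook product limit", {
  clin <- tibble::tibble(sample_id = c("a", "b"), os_time = c(1, 2),
                         os_event = c(1L, 1L))
  grp <- tibble::tibble(sample_id = c("a", "b"), group = "P+G+")
  km <- kaplan_meier(clin, grp, levels = "P+G+")
  steps <- tidy(km)
  expect_equal(steps$estimate[steps$time == 1], 0.5)
  expect_equal(steps$estimate[steps$time == 2], 0)
  # all censored -> log-rank undefined
  cens <- dplyr::mutate(clin, os_event = 0L)
  expect_error(kaplan_meier(cens, grp, levels = "P+G+"), "censored")
})

test_that("KM curves are non-increasing and start at 1", {
  set.seed(105)
  grp <- tibble::tibble(sample_id = sprintf("S%03d", 1:60),
                        group = rep(c("P+G+", "P+G-"), 30))
  clin <- generate_survival(synth_config(seed = 105), grp)
  km <- kaplan_meier(clin, grp)
  steps <- tidy(km) |> dplyr::group_by(.data$group)
  expect_true(all(dplyr::summarise(steps, ok = all(diff(estimate) <= 1e-12))$ok))
  expect_true(all(dplyr::summarise(steps, first = estimate[1])$first <= 1))
})

test_that("log-rank statistic matches the event-table oracle", {
  set.seed(107)
  grp <- tibble::tibble(sample_id = sprintf("S%02d", 1:40),
                        group = rep(c("P+G+", "P+G-"), each = 20))
  clin <- generate_survival(synth_config(seed = 107, hazard_multiplier = 2.5), grp)
  km <- kaplan_meier(clin, grp)
  dat <- dplyr::inner_join(clin[, 1:3], grp, by = "sample_id")
  expect_equal(km$logrank_chisq,
               oracle_logrank(dat$os_time, dat$os_event, dat$group),
               tolerance = 1e-9)
  expect_error(kaplan_meier(clin, dplyr::filter(grp, group == "P+G+")),
               "zero samples")
})

test_that("log-rank chi-square p agrees with a permutation test", {
  set.seed(109)
  grp <- tibble::tibble(sample_id = sprintf("S%02d", 1:40),
                        group = rep(c("P+G+", "P+G-"), each = 20))
  clin <- generate_survival(synth_config(seed = 109, hazard_multiplier = 2), grp)
  km <- kaplan_meier(clin, grp)
  dat <- dplyr::inner_join(clin[, 1:3], grp, by = "sample_id")
  obs <- oracle_logrank(dat$os_time, dat$os_event, dat$group)
  perm <- replicate(1000, {
    oracle_logrank(dat$os_time, dat$os_event, sample(dat$group))
  })
  p_perm <- mean(perm >= obs - 1e-12)
  mc_err <- 3 * sqrt(max(p_perm * (1 - p_perm), 0.002) / 1000)
  expect_lt(abs(km$logrank_p - p_perm), mc_err + 0.02)
})

test_that("Cox HR is near 1 under the null and inverts exactly on label swap", {
  set.seed(111)
  grp <- tibble::tibble(sample_id = sprintf("S%03d", 1:200),
                        group = rep(c("P+G+", "P+G-"), 100))
  clin <- generate_survival(synth_config(seed = 111, hazard_multiplier = 1), grp)
  res <- cox_hr(clin, grp)
  expect_lt(abs(res$log2_hr), 0.5)
  expect_true(res$ci_low <= res$hazard_ratio && res$hazard_ratio <= res$ci_high)
  expect_equal(res$log2_hr, log2(res$hazard_ratio), tolerance = 1e-12)
  swapped <- dplyr::mutate(grp, group = ifelse(group == "P+G+", "P+G-", "P+G+"))
  res_sw <- cox_hr(clin, swapped)
  expect_equal(res_sw$log2_hr, -res$log2_hr, tolerance = 1e-8)
  expect_equal(res_sw$hazard_ratio, 1 / res$hazard_ratio, tolerance = 1e-8)
})

test_that("Cox recovers a planted hazard ratio of 2", {
  set.seed(113)
  hits <- 0
  covered <- 0
  for (rep in 1:20) {
    grp <- tibble::tibble(sample_id = sprintf("S%04d", 1:1000),
                          group = rep(c("P+G-", "P+G+"), each = 500))
    clin <- generate_survival(synth_config(seed = 113 + rep,
                                           hazard_multiplier = 2), grp)
    res <- cox_hr(clin, grp)
    if (res$hazard_ratio > 1.6 && res$hazard_ratio < 2.5) hits <- hits + 1
    if (res$ci_low <= 2 && 2 <= res$ci_high) covered <- covered + 1
  }
  expect_gte(hits, 18)
  expect_gte(covered, 18)
})

test_that("hazard_by_gene is median_split + cox_hr and points the right way", {
  set.seed(115)
  n <- 120
  clin <- tibble::tibble(sample_id = sprintf("S%03d", 1:n),
                         os_time = stats::rexp(n, 0.01), os_event = 1L)
  # protective marker: tracks survival time
  tab <- tibble::tibble(sample_id = clin$sample_id,
                        marker = rank(clin$os_time) + stats::rnorm(n, sd = 1))
  res <- hazard_by_gene(clin, tab, "marker")
  expect_lt(res$log2_hr, 0)
  # delegation identity
  grp <- tibble::tibble(sample_id = tab$sample_id,
                        group = ifelse(tab$marker > stats::median(tab$marker),
                                       "high", "low"))
  direct <- cox_hr(clin, grp, levels = c("low", "high"))
  expect_equal(res$log2_hr, direct$log2_hr, tolerance = 1e-12)
  # permuted marker: CI spans 1
  set.seed(116)
  tab_null <- dplyr::mutate(tab, marker = sample(marker))
  res_null <- hazard_by_gene(clin, tab_null, "marker")
  expect_lt(res_null$ci_low, 1)
  expect_gt(res_null$ci_high, 1)
  expect_lt(abs(res_null$log2_hr), 1)
})

test_that("monotone likelihood is flagged instead of crashing", {
  clin <- tibble::tibble(sample_id = paste0("S", 1:20),
                         os_time = c(1:10, 101:110),
                         os_event = rep(1L, 20))
  grp <- tibble::tibble(sample_id = paste0("S", 1:20),
                        group = rep(c("P+G+", "P+G-"), each = 10))
  res <- cox_hr(clin, grp)
  expect_true(res$infinite || res$hazard_ratio > 5)
})
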