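test_that("ssGSEA score sign follows concordance of the set with the ranking", {
  vals <- matrix(c(5, 1, 1, 5), 2, dimnames = list(c("A", "B"), c("S1", "S2")))
  m <- expr_mat(vals)
  sc <- ssgsea_score(m, "A", normalize = "none", min_coverage = 1)
  expect_gt(sc$score[1], 0)   # A on top
  expect_lt(sc$score[2], 0)   # A at bottom
})

test_that("ssGSEA is invariant to input row order and monotone transforms", {
  m <- rand_mat(100, 6, seed = 5)
  gs <- gene_set("S", sample(genes(m), 12))
  base <- ssgsea_score(m, gs)
  shuffled <- expr_mat(m$values[sample(nrow(m$values)), ],
                       metadata = m$metadata)
  expect_equal(ssgsea_score(shuffled, gs)$score, base$score, tolerance = 1e-12)
  # strictly increasing per-sample transform: x -> 2x + 5
  trans <- expr_mat(2 * m$values + 5, metadata = m$metadata)
  expect_identical(ssgsea_score(trans, gs)$score, base$score)
})

test_that("ssGSEA matches the position-by-position running-sum oracle", {
  m <- rand_mat(10, 1, seed = 7)
  gs_genes <- genes(m)[c(2, 5, 9)]
  got <- ssgsea_score(m, gs_genes, normalize = "none")$score
  expect_equal(got, oracle_ssgsea(m$values[, 1], genes(m), gs_genes),
               tolerance = 1e-12)
  # larger randomized cases, several exponents
  for (alpha in c(0, 0.75, 1.5)) {
    mm <- rand_mat(120, 3, seed = 13 + alpha * 10)
    gset <- sample(genes(mm), 20)
    got <- ssgsea_score(mm, gset, weight_exponent = alpha,
                        normalize = "none")$score
    want <- vapply(seq_len(3), function(j) {
      oracle_ssgsea(mm$values[, j], genes(mm), gset, alpha = alpha)
    }, numeric(1))
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("ssGSEA with exponent 0 depends only on set-gene rank positions", {
  # two samples whose set genes occupy identical rank positions must tie
  g <- sprintf("G%02d", 1:20)
  v1 <- seq(20, 1)                      # G01 highest ... G20 lowest
  v2 <- seq(40, 2, by = -2) + 0.123     # same ordering, different values
  m <- expr_mat(matrix(c(v1, v2), ncol = 2, dimnames = list(g, c("S1", "S2"))))
  sc <- ssgsea_score(m, c("G03", "G10", "G17"), weight_exponent = 0,
                     normalize = "none")
  expect_equal(sc$score[1], sc$score[2], tolerance = 1e-12)
})

test_that("ssGSEA rejects degenerate gene sets", {
  m <- rand_mat(20, 2)
  expect_error(ssgsea_score(m, c("NOPE1", "NOPE2")), "no gene")
  expect_error(ssgsea_score(m, genes(m)), "whole universe")
  expect_error(ssgsea_score(m, c(genes(m)[1], "X1", "X2", "X3")),
               "coverage")
})

test_that("AUCell AUC is 1 for top-packed sets, 0 for excluded sets", {
  g <- sprintf("G%03d", 1:100)
  v <- seq(100, 1)                      # G001 ranked first
  m <- expr_mat(matrix(v, ncol = 1, dimnames = list(g, "C1")))
  expect_equal(aucell_score(m, g[1:3], top_fraction = 0.1)$score, 1)
  expect_equal(aucell_score(m, g[95:98], top_fraction = 0.05,
                            min_coverage = 0)$score, 0)
})

test_that("AUCell matches explicit step-curve integration on random cells", {
  m <- rand_mat(200, 10, seed = 21)
  gs <- sample(genes(m), 10)
  got <- aucell_score(m, gs, top_fraction = 0.05)$score
  want <- vapply(seq_len(10), function(j) {
    oracle_aucell(m$values[, j], genes(m), gs, top_fraction = 0.05)
  }, numeric(1))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("AUCell is non-decreasing when a set gene moves up in rank", {
  g <- sprintf("G%03d", 1:100)
  v <- seq(100, 1) + 0
  m0 <- expr_mat(matrix(v, ncol = 1, dimnames = list(g, "C")))
  set_genes <- c("G050", "G080")
  a0 <- aucell_score(m0, set_genes, top_fraction = 0.5)$score
  v2 <- v
  v2[50] <- 150                          # G050 jumps to the top
  m1 <- expr_mat(matrix(v2, ncol = 1, dimnames = list(g, "C")))
  a1 <- aucell_score(m1, set_genes, top_fraction = 0.5)$score
  expect_gte(a1, a0)
})

test_that("target activity: mean_z matches the z-score oracle and orders groups", {
  m <- rand_mat(50, 20, seed = 31)
  targets <- genes(m)[1:8]
  got <- target_activity_score(m, targets, min_coverage = 1)
  sub <- m$values[targets, ]
  z <- t(scale(t(sub)))
  expect_equal(got$score, unname(colMeans(z)), tolerance = 1e-12)
  # uniformly higher targets in sample 1 -> higher activity
  vals <- matrix(6, 4, 2, dimnames = list(paste0("T", 1:4), c("S1", "S2")))
  vals[, 1] <- vals[, 1] + 1
  vals <- vals + matrix(stats::rnorm(8, sd = 0.01), 4)
  m2 <- expr_mat(vals)
  sc2 <- target_activity_score(m2, paste0("T", 1:4))
  expect_gt(sc2$score[1], sc2$score[2])
})

test_that("target activity: first_pc is sign-aligned with mean_z; zero variance errors", {
  m <- rand_mat(40, 25, seed = 41)
  targets <- genes(m)[1:10]
  pc <- target_activity_score(m, targets, method = "first_pc")
  mz <- target_activity_score(m, targets, method = "mean_z")
  expect_gt(stats::cor(pc$score, mz$score), 0)
  expect_identical(attr(pc, "method"), "first_pc")
  flat <- expr_mat(matrix(5, 4, 6, dimnames = list(paste0("T", 1:4),
                                                   paste0("S", 1:6))))
  expect_error(target_activity_score(flat, paste0("T", 1:4)), "zero variance")
})

test_that("FAO score is a weighted sum of z-scores", {
  # all FAO genes shifted +1 z-unit in sample group A -> score difference 1
  set.seed(51)
  fao <- paste0("F", 1:14)
  n <- 40
  base <- matrix(stats::rnorm(14 * n, mean = 6), 14,
                 dimnames = list(fao, sprintf("S%02d", 1:n)))
  z_shift <- rep(c(1, 0), each = n / 2)
  sds <- apply(base, 1, stats::sd)
  shifted <- base + outer(sds, z_shift)
  m <- expr_mat(shifted)
  sc <- fao_score(m, fao)
  # zero weights give identically zero scores
  sc0 <- fao_score(m, fao, weights = stats::setNames(rep(0, 14), fao))
  expect_true(all(sc0$score == 0))
  # random weights match the brute-force dot product
  w <- stats::setNames(stats::runif(14), fao)
  got <- fao_score(m, fao, weights = w)$score
  z <- t(scale(t(shifted)))
  want <- as.vector(t(z) %*% w)
  expect_equal(got, want, tolerance = 1e-12)
  expect_warning(fao_score(m, fao, weights = c(w, ABSENT = 1)), "absent")
})

test_that("all four scorers separate a planted active population", {
  fix <- planted_em_cohort(n_per_group = 50, seed = 61)
  m <- fix$matrix
  lab <- fix$is_epi
  expect_gt(auroc(ssgsea_score(m, fix$e_genes)$score, lab), 0.95)
  expect_gt(auroc(aucell_score(m, fix$e_genes, top_fraction = 0.25)$score, lab), 0.95)
  expect_gt(auroc(target_activity_score(m, fix$e_genes)$score, lab), 0.95)
  expect_gt(auroc(fao_score(m, fix$e_genes)$score, lab), 0.95)
})
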