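test_that("76GS scores planted epithelial samples higher and matches the formula", {
  fix <- planted_em_cohort(n_per_group = 30, seed = 71)
  gs76 <- c(fix$e_genes, fix$m_genes)   # CDH1-correlated and anti-correlated genes
  sc <- score_76gs(fix$matrix, gs76, min_coverage = 1)
  expect_gt(mean(sc$score[fix$is_epi]), mean(sc$score[!fix$is_epi]))
  expect_equal(sc$score, oracle_76gs(fix$matrix$values, gs76), tolerance = 1e-10)
  expect_equal(mean(sc$score), 0, tolerance = 1e-8)   # mean-centering
})

test_that("76GS is invariant to per-gene constant offsets", {
  fix <- planted_em_cohort(n_per_group = 15, seed = 73)
  gs76 <- c(fix$e_genes, fix$m_genes)
  base <- score_76gs(fix$matrix, gs76, min_coverage = 1)
  shifted <- expr_mat(fix$matrix$values + stats::rnorm(nrow(fix$matrix$values)),
                      metadata = fix$matrix$metadata)
  expect_equal(score_76gs(shifted, gs76, min_coverage = 1)$score, base$score,
               tolerance = 1e-9)
})

test_that("76GS rejects cohorts where the weights are undefined", {
  m <- rand_mat(30, 10, seed = 75)
  expect_error(score_76gs(m, genes(m)[1:10]), "CDH1 absent")
  one <- expr_mat(matrix(1:3, ncol = 1,
                         dimnames = list(c("CDH1", "A", "B"), "S1")))
  expect_error(score_76gs(one, c("A", "B")), ">= 2 samples")
  flat <- expr_mat(rbind(CDH1 = stats::rnorm(6),
                         matrix(5, 3, 6, dimnames = list(paste0("A", 1:3), NULL))) |>
                     (\(v) {colnames(v) <- paste0("S", 1:6); v})())
  expect_error(score_76gs(flat, paste0("A", 1:3)), "zero variance")
})

test_that("KS score hits +1/-1 on perfectly separated lists and 0 on ties", {
  e <- paste0("E", 1:5)
  m_g <- paste0("M", 1:5)
  vals <- matrix(c(1:5, 6:10), ncol = 1, dimnames = list(c(e, m_g), "S1"))
  mes_high <- expr_mat(vals)
  expect_equal(score_ks(mes_high, e, m_g)$score, 1)       # all M above all E
  epi_high <- expr_mat(vals[c(m_g, e), , drop = FALSE] |>
                         (\(v) {rownames(v) <- c(e, m_g); v})())
  expect_equal(score_ks(epi_high, e, m_g)$score, -1)
  tied <- expr_mat(matrix(c(1:5, 1:5), ncol = 1, dimnames = list(c(e, m_g), "S1")))
  expect_equal(suppressMessages(score_ks(tied, e, m_g)$score), 0)
})

test_that("KS magnitude equals the two-sample KS statistic (oracle and ks.test)", {
  set.seed(81)
  for (rep in 1:20) {
    e <- paste0("E", 1:30)
    mg <- paste0("M", 1:30)
    vals <- matrix(stats::rnorm(60, mean = 6), ncol = 1,
                   dimnames = list(c(e, mg), "S1"))
    m <- expr_mat(vals)
    got <- score_ks(m, e, mg)
    expect_equal(got$score, oracle_ks_signed(vals[e, 1], vals[mg, 1]),
                 tolerance = 1e-12)
    expect_equal(abs(got$score),
                 unname(stats::ks.test(vals[e, 1], vals[mg, 1])$statistic),
                 tolerance = 1e-12)
    expect_true(got$score >= -1 && got$score <= 1)
  }
})

test_that("KS requires disjoint, represented lists", {
  m <- rand_mat(20, 2, seed = 83)
  expect_error(score_ks(m, genes(m)[1:5], genes(m)[5:9]), "overlap")
  expect_error(score_ks(m, c("NOPE1", "NOPE2"), genes(m)[1:5]), "no gene")
})

test_that("Epi/Mes/pEMT wrapper delegates to ssgsea_score", {
  fix <- planted_em_cohort(n_per_group = 10, seed = 85)
  pemt <- sample(genes(fix$matrix)[grepl("^BG", genes(fix$matrix))], 15)
  lists <- emt_gene_lists(c(fix$e_genes, fix$m_genes), fix$e_genes,
                          fix$m_genes, pemt)
  out <- score_epi_mes_pemt(fix$matrix, lists)
  expect_equal(out$Epi, ssgsea_score(fix$matrix, lists$ks_epithelial)$score)
  expect_equal(out$Mes, ssgsea_score(fix$matrix, lists$ks_mesenchymal)$score)
  expect_equal(out$pEMT, ssgsea_score(fix$matrix, lists$pemt)$score)
  # planted mesenchymal samples enrich the mesenchymal signature
  expect_gt(mean(out$Mes[!fix$is_epi]), mean(out$Mes[fix$is_epi]))
})

test_that("overlapping E/M lists are rejected at bundle construction", {
  expect_error(emt_gene_lists(c("A", "B"), c("E1", "X"), c("M1", "X"), "P1"),
               "overlap")
})

test_that("EMT metrics cross-correlate with the expected signs on planted cohorts", {
  fix <- planted_em_cohort(n_per_group = 30, seed = 87)
  pemt <- genes(fix$matrix)[grepl("^BG", genes(fix$matrix))][1:20]
  lists <- emt_gene_lists(c(fix$e_genes, fix$m_genes), fix$e_genes,
                          fix$m_genes, pemt)
  tab <- score_emt(fix$matrix, lists)
  expect_lt(stats::cor(tab$GS76, tab$KS), 0)    # 76GS epithelial vs KS mesenchymal
  expect_gt(stats::cor(tab$KS, tab$Mes), 0)     # KS tracks Mes enrichment
  expect_lt(stats::cor(tab$Epi, tab$Mes), 0)
})

test_that("hybrid samples score intermediate on KS but top on pEMT", {
  set.seed(89)
  e <- paste0("EG", 1:20); mg <- paste0("MG", 1:20); pg <- paste0("PG", 1:20)
  bg <- paste0("BG", 1:140)
  n_per <- 20
  pops <- rep(c("epi", "hybrid", "mes"), each = n_per)
  n <- length(pops)
  vals <- matrix(stats::rnorm((200) * n, mean = 6), 200,
                 dimnames = list(c(e, mg, pg, bg), sprintf("S%03d", 1:n)))
  vals[e, pops == "epi"] <- vals[e, pops == "epi"] + 2
  vals[mg, pops == "mes"] <- vals[mg, pops == "mes"] + 2
  # hybrids co-express half of each program and the pEMT signature
  vals[e[1:10], pops == "hybrid"] <- vals[e[1:10], pops == "hybrid"] + 2
  vals[mg[1:10], pops == "hybrid"] <- vals[mg[1:10], pops == "hybrid"] + 2
  vals[pg, pops == "hybrid"] <- vals[pg, pops == "hybrid"] + 2
  m <- expr_mat(vals)
  ks <- score_ks(m, e, mg)$score
  pemt <- ssgsea_score(m, pg)$score
  expect_lt(mean(ks[pops == "epi"]), mean(ks[pops == "hybrid"]))
  expect_lt(mean(ks[pops == "hybrid"]), mean(ks[pops == "mes"]))
  expect_gt(mean(pemt[pops == "hybrid"]), mean(pemt[pops == "epi"]))
  expect_gt(mean(pemt[pops == "hybrid"]), mean(pemt[pops == "mes"]))
})
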