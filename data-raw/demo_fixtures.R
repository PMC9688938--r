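# Builds the small demo fixtures under inst/extdata/demo: two synthetic
# expression matrices with planted epithelial/mesenchymal structure, the
# matching GMT, a clinical table, and golden pipeline outputs used by the
# regression test. Run from the package root after any change here:
#   Rscript data-raw/demo_fixtures.R

library(plastiscore)

demo_dir <- "inst/extdata/demo"
dir.create(demo_dir, recursive = TRUE, showWarnings = FALSE)

make_demo_matrix <- function(seed, n = 20) {
  set.seed(seed)
  e_genes <- sprintf("EGENE%02d", 1:19)
  m_genes <- sprintf("MGENE%02d", 1:20)
  p_genes <- sprintf("PGENE%02d", 1:19)
  g_genes <- sprintf("GGENE%02d", 1:20)
  b_genes <- sprintf("BGENE%02d", 1:38)
  all_genes <- c("CDH1", e_genes, "CD274", p_genes, m_genes, g_genes, b_genes)
  # latents: EMT coordinate (epithelial negative), PD-L1 coupled to it,
  # glycolysis coupled to PD-L1
  emt <- c(rep(-1, n / 2), rep(1, n / 2)) + rnorm(n, sd = 0.3)
  pdl1 <- 0.8 * emt + rnorm(n, sd = 0.5)
  glyc <- 0.7 * pdl1 + rnorm(n, sd = 0.6)
  vals <- matrix(rnorm(length(all_genes) * n, mean = 6), nrow = length(all_genes),
                 dimnames = list(all_genes, sprintf("P%02d", 1:n)))
  vals[c("CDH1", e_genes), ] <- vals[c("CDH1", e_genes), ] + 2 * rep(-emt, each = 20)
  vals[m_genes, ] <- vals[m_genes, ] + 2 * rep(emt, each = 20)
  vals[c("CD274", p_genes), ] <- vals[c("CD274", p_genes), ] + 2 * rep(pdl1, each = 20)
  vals[g_genes, ] <- vals[g_genes, ] + 2 * rep(glyc, each = 20)
  expr_mat(vals, metadata = list(log_scale = TRUE))
}

m1 <- make_demo_matrix(101)
m2 <- make_demo_matrix(202)
write_expression(m1, file.path(demo_dir, "d1.tsv"))
write_expression(m2, file.path(demo_dir, "d2.tsv"))

sets <- list(
  gene_set("EPI", c("CDH1", sprintf("EGENE%02d", 1:19)), role = "epithelial"),
  gene_set("MES", sprintf("MGENE%02d", 1:20), role = "mesenchymal"),
  gene_set("PDL1_SIG", c("CD274", sprintf("PGENE%02d", 1:19)), role = "signature"),
  gene_set("GLYCOLYSIS", sprintf("GGENE%02d", 1:20), role = "hallmark_pathway"))
write_gmt(sets, file.path(demo_dir, "sets.gmt"))

# clinical table for d1: P+G+-like samples (high EMT half) die faster
set.seed(303)
grp <- median_split(score_table(m1, expr_genes = "CD274",
                                sets = list(GLYCOLYSIS = sprintf("GGENE%02d", 1:20))),
                    "EXPR:CD274", "NES:GLYCOLYSIS")
clin <- generate_survival(synth_config(seed = 303, hazard_multiplier = 3), grp)
readr::write_tsv(clin[, c("sample_id", "os_time", "os_event")] |>
                   dplyr::mutate(os_time = round(os_time, 3)),
                 file.path(demo_dir, "clin.tsv"))

# golden outputs for the byte-identity regression test
golden <- file.path(demo_dir, "golden")
unlink(golden, recursive = TRUE)
cfg <- list(
  datasets = list(list(id = "d1", path = file.path(demo_dir, "d1.tsv")),
                  list(id = "d2", path = file.path(demo_dir, "d2.tsv"))),
  gene_sets = file.path(demo_dir, "sets.gmt"),
  metrics = list(ssgsea = c("PDL1_SIG", "MES", "EPI", "GLYCOLYSIS"),
                 expr = "CD274"),
  pairs = list(c("NES:PDL1_SIG", "NES:MES"), c("NES:PDL1_SIG", "NES:EPI")),
  survival = list(clinical = file.path(demo_dir, "clin.tsv"), dataset = "d1",
                  pdl1 = "EXPR:CD274", glycolysis = "NES:GLYCOLYSIS"),
  out_dir = golden)
run_all(cfg)
unlink(file.path(golden, "report.yaml"))  # hashes repeat the TSVs; keep goldens lean
cat("demo fixtures written to", demo_dir, "\n")
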