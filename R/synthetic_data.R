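#' Default coupling matrix among latent signature activities
#'
#' Correlation matrix of the latent activities driving the synthetic
#' generators, mirroring the sign structure reported across cancer
#' datasets: PD-L1 couples positively with the mesenchymal, partial-EMT,
#' glycolysis and HIF-1alpha programs, negatively with OXPHOS, and is
#' uncorrelated with the epithelial program; glycolysis and HIF-1alpha
#' reinforce each other and oppose OXPHOS. AMPK and FAO activities are
#' present but uncoupled by default.
#'
#' @return A 9 x 9 symmetric positive-definite correlation matrix with
#'   dimnames `Epi, Mes, pEMT, PDL1, GLYC, HIF1A, OXPHOS, AMPK, FAO`.
#' @export
default_coupling <- function() {
  nm <- c("Epi", "Mes", "pEMT", "PDL1", "GLYC", "HIF1A", "OXPHOS", "AMPK", "FAO")
  C <- diag(length(nm))
  dimnames(C) <- list(nm, nm)
  set_pair <- function(a, b, v) {
    C[a, b] <<- v
    C[b, a] <<- v
  }
  set_pair("Epi", "Mes", -0.5)
  set_pair("Mes", "pEMT", 0.4)
  set_pair("PDL1", "Mes", 0.5)
  set_pair("PDL1", "pEMT", 0.5)
  set_pair("PDL1", "GLYC", 0.4)
  set_pair("PDL1", "HIF1A", 0.5)
  set_pair("PDL1", "OXPHOS", -0.4)
  set_pair("GLYC", "HIF1A", 0.5)
  set_pair("GLYC", "OXPHOS", -0.3)
  set_pair("HIF1A", "OXPHOS", -0.3)
  C
}

#' Synthetic-data configuration
#'
#' Fixes the study conditions emulated by every generator: gene-universe
#' size, gene-list sizes (25-gene epithelial and mesenchymal lists as in
#' typical KS lists, the 76-gene list with CDH1, 30-gene pathway sets,
#' 23/33-gene HIF-1alpha/AMPK target sets, 14 FAO enzymes), the
#' epithelial/hybrid/mesenchymal population mix, the z-shift of active
#' programs, the latent coupling structure, noise level on log2 scale,
#' and the survival-generation parameters.
#'
#' @param seed Integer seed; every generator is a pure function of
#'   (config, seed).
#' @param n_genes Universe size (default 2000).
#' @param n_samples Samples (or cells) per generated matrix (default 100).
#' @param population_fractions Named or ordered fractions (epithelial,
#'   hybrid, mesenchymal); must sum to 1.
#' @param effect_size z-shift applied per unit latent activity and to
#'   planted populations (default 2).
#' @param coupling Latent correlation matrix (default [default_coupling()]);
#'   must be symmetric positive semi-definite.
#' @param noise_sd Gene-level Gaussian noise sd on log2 scale (default 1).
#' @param baseline_mean,baseline_sd Per-gene baseline expression
#'   distribution on log2 scale (defaults 6 and 1).
#' @param hazard_multiplier Hazard ratio of P+G+ vs P+G- in survival
#'   generation (default 2).
#' @param baseline_hazard Baseline exponential event rate (default 0.01
#'   per time unit).
#' @param censoring_fraction Expected fraction censored (default 0.2).
#'
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(seed = 1, n_genes = 2000, n_samples = 100,
                         population_fractions = c(epithelial = 0.4,
                                                  hybrid = 0.2,
                                                  mesenchymal = 0.4),
                         effect_size = 2, coupling = default_coupling(),
                         noise_sd = 1, baseline_mean = 6, baseline_sd = 1,
                         hazard_multiplier = 2, baseline_hazard = 0.01,
                         censoring_fraction = 0.2) {
  stopifnot(abs(sum(population_fractions) - 1) < 1e-8,
            length(population_fractions) == 3,
            n_genes >= 300, n_samples >= 2, noise_sd >= 0,
            censoring_fraction >= 0, censoring_fraction < 1)
  if (!isSymmetric(unname(coupling))) stop("coupling matrix must be symmetric", call. = FALSE)
  ev <- eigen(coupling, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop("coupling matrix is not positive semi-definite (min eigenvalue ",
         signif(min(ev), 3), "); project it to the nearest PSD matrix ",
         "(e.g. Matrix::nearPD) before use", call. = FALSE)
  }
  structure(list(seed = seed, n_genes = n_genes, n_samples = n_samples,
                 population_fractions = population_fractions,
                 effect_size = effect_size, coupling = coupling,
                 noise_sd = noise_sd, baseline_mean = baseline_mean,
                 baseline_sd = baseline_sd,
                 hazard_multiplier = hazard_multiplier,
                 baseline_hazard = baseline_hazard,
                 censoring_fraction = censoring_fraction),
            class = "synth_config")
}

# Draw n latent-activity vectors with the configured coupling (Gaussian
# copula via Cholesky; rank-deficient couplings fall back to eigen).
draw_latents <- function(n, coupling) {
  p <- nrow(coupling)
  L <- tryCatch(t(chol(coupling)), error = function(e) {
    eg <- eigen(coupling, symmetric = TRUE)
    eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), p)
  })
  z <- matrix(stats::rnorm(n * p), nrow = p)
  lat <- t(L %*% z)
  colnames(lat) <- rownames(coupling)
  lat
}

# The gene-set layout of the synthetic universe: which genes belong to
# which signature and which latent drives each.
synth_gene_layout <- function(n_genes) {
  sizes <- c(EPI = 24, MES = 25, PEMT = 30, GS76_EPI = 40, GS76_MES = 35,
             GLYCOLYSIS = 30, HIF1A_TARGETS = 23, OXPHOS = 30,
             AMPK_TARGETS = 33, FAO_ENZYMES = 14, PDL1_SIG = 30)
  need <- sum(sizes) + 2  # + CDH1, CD274
  if (n_genes < need + 50) stop("n_genes too small for the gene-set layout", call. = FALSE)
  pool <- sprintf("GENE%04d", seq_len(n_genes - 2))
  idx <- 0
  take <- function(k) {
    out <- pool[idx + seq_len(k)]
    idx <<- idx + k
    out
  }
  blocks <- purrr::map(sizes, take)
  list(
    sets = list(
      EPI = c("CDH1", blocks$EPI),
      MES = blocks$MES,
      PEMT = blocks$PEMT,
      GS76 = c("CDH1", blocks$GS76_EPI, blocks$GS76_MES),
      GLYCOLYSIS = blocks$GLYCOLYSIS,
      HIF1A_TARGETS = blocks$HIF1A_TARGETS,
      OXPHOS = blocks$OXPHOS,
      AMPK_TARGETS = blocks$AMPK_TARGETS,
      FAO_ENZYMES = blocks$FAO_ENZYMES,
      PDL1_SIG = c("CD274", blocks$PDL1_SIG)),
    driver = c(
      stats::setNames(rep("Epi", length(blocks$EPI) + 1), c("CDH1", blocks$EPI)),
      stats::setNames(rep("Mes", length(blocks$MES)), blocks$MES),
      stats::setNames(rep("pEMT", length(blocks$PEMT)), blocks$PEMT),
      stats::setNames(rep("Epi", length(blocks$GS76_EPI)), blocks$GS76_EPI),
      stats::setNames(rep("Mes", length(blocks$GS76_MES)), blocks$GS76_MES),
      stats::setNames(rep("GLYC", length(blocks$GLYCOLYSIS)), blocks$GLYCOLYSIS),
      stats::setNames(rep("HIF1A", length(blocks$HIF1A_TARGETS)), blocks$HIF1A_TARGETS),
      stats::setNames(rep("OXPHOS", length(blocks$OXPHOS)), blocks$OXPHOS),
      stats::setNames(rep("AMPK", length(blocks$AMPK_TARGETS)), blocks$AMPK_TARGETS),
      stats::setNames(rep("FAO", length(blocks$FAO_ENZYMES)), blocks$FAO_ENZYMES),
      stats::setNames(rep("PDL1", length(blocks$PDL1_SIG) + 1),
                      c("CD274", blocks$PDL1_SIG))),
    background = pool[(idx + 1):length(pool)])
}

#' Generate a bulk expression dataset with planted structure
#'
#' Draws a latent activity vector per sample from a multivariate normal
#' with the configured coupling correlation, plants
#' epithelial/hybrid/mesenchymal populations by shifting the EMT latents
#' (epithelial: +Epi/-Mes; mesenchymal: +Mes/-Epi; hybrid: partial +Epi
#' and +Mes simultaneously plus full +pEMT — the partial-EMT structure),
#' and emits each signature gene as `baseline + effect_size * latent +
#' noise` on log2 scale. CDH1 is tied to the epithelial latent (so 76GS
#' weights are recoverable) and CD274 to the PD-L1 latent.
#'
#' @param config A [synth_config()].
#' @param dataset_id Metadata tag for the generated matrix.
#'
#' @return List: `matrix` ([expr_mat()]), `gene_sets`
#'   (`gene_set_collection`), `truth` (tibble of per-sample population
#'   labels and latent activities).
#' @export
generate_bulk_dataset <- function(config, dataset_id = "synthetic") {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n <- config$n_samples
  layout <- synth_gene_layout(config$n_genes)
  lat <- draw_latents(n, config$coupling)
  pops <- sample(c("epithelial", "hybrid", "mesenchymal"), n, replace = TRUE,
                 prob = config$population_fractions)
  shift <- config$effect_size / 2
  lat[, "Epi"] <- lat[, "Epi"] +
    ifelse(pops == "epithelial", shift, ifelse(pops == "hybrid", shift / 2, -shift))
  lat[, "Mes"] <- lat[, "Mes"] +
    ifelse(pops == "mesenchymal", shift, ifelse(pops == "hybrid", shift / 2, -shift))
  lat[, "pEMT"] <- lat[, "pEMT"] + ifelse(pops == "hybrid", shift, 0)
  all_genes <- c(names(layout$driver), layout$background)
  baseline <- stats::rnorm(length(all_genes), config$baseline_mean, config$baseline_sd)
  vals <- matrix(stats::rnorm(length(all_genes) * n, sd = config$noise_sd),
                 nrow = length(all_genes),
                 dimnames = list(all_genes, sprintf("S%04d", seq_len(n))))
  vals <- vals + baseline
  drv <- layout$driver
  vals[names(drv), ] <- vals[names(drv), ] +
    config$effect_size * t(lat[, drv, drop = FALSE])
  sets <- purrr::imap(layout$sets, function(g, nm) gene_set(nm, g))
  truth <- tibble::tibble(sample_id = colnames(vals), population = pops) |>
    dplyr::bind_cols(tibble::as_tibble(lat))
  list(matrix = expr_mat(vals, metadata = list(dataset_id = dataset_id,
                                               log_scale = TRUE)),
       gene_sets = structure(sets, class = "gene_set_collection"),
       truth = truth)
}

#' Generate a pan-cancer compendium with planted anchor co-expression
#'
#' Builds `n_cohorts` independent cohorts in which a block of planted
#' genes correlates with the anchor gene (bivariate-normal correlation
#' `rho_true`, default 0.7) in exactly `planted_cohort_count` cohorts;
#' every other gene-anchor pair is independent noise. Exercises the
#' co-expression curation rule end to end.
#'
#' @param config A [synth_config()] (`n_samples` = samples per cohort,
#'   `n_genes` = genes per cohort).
#' @param n_cohorts Number of cohorts (default 27).
#' @param planted_genes Number of planted genes (default 50).
#' @param planted_cohort_count Cohorts in which they correlate (default 20).
#' @param rho_true Planted latent correlation (default 0.7).
#' @param anchor Anchor gene symbol (default `"CD274"`).
#'
#' @return List: `cohorts` (named list of [expr_mat()]), `planted`
#'   (character vector of planted gene names).
#' @export
generate_compendium <- function(config, n_cohorts = 27, planted_genes = 50,
                                planted_cohort_count = 20, rho_true = 0.7,
                                anchor = "CD274") {
  stopifnot(inherits(config, "synth_config"),
            planted_cohort_count <= n_cohorts)
  set.seed(config$seed)
  n <- config$n_samples
  n_null <- config$n_genes - planted_genes - 1
  planted <- sprintf("PLANT%04d", seq_len(planted_genes))
  nulls <- sprintf("NULL%04d", seq_len(n_null))
  cohorts <- purrr::map(seq_len(n_cohorts), function(k) {
    av <- stats::rnorm(n)
    pm <- if (k <= planted_cohort_count) {
      rho_true * matrix(rep(av, planted_genes), nrow = planted_genes, byrow = TRUE) +
        sqrt(1 - rho_true^2) * matrix(stats::rnorm(planted_genes * n), nrow = planted_genes)
    } else {
      matrix(stats::rnorm(planted_genes * n), nrow = planted_genes)
    }
    vals <- rbind(matrix(av, nrow = 1), pm,
                  matrix(stats::rnorm(n_null * n), nrow = n_null))
    dimnames(vals) <- list(c(anchor, planted, nulls), sprintf("S%04d", seq_len(n)))
    expr_mat(vals + config$baseline_mean,
             metadata = list(dataset_id = sprintf("COHORT%02d", k),
                             log_scale = TRUE))
  })
  names(cohorts) <- sprintf("COHORT%02d", seq_len(n_cohorts))
  list(cohorts = cohorts, planted = planted)
}

#' Generate a single-cell EMT-induction time course
#'
#' Emulates an EMT-induction experiment: across timepoints the latent EMT
#' coordinate advances monotonically (mesenchymal latent up, epithelial
#' latent down), while the PD-L1-like gene and the metabolic latents
#' co-vary with EMT through the coupling matrix. Matrices are dense
#' (post-imputation-like) and suitable for AUCell scoring.
#'
#' @param config A [synth_config()] (`n_samples` = cells per timepoint).
#' @param n_timepoints Number of timepoints (>= 2).
#'
#' @return List of [expr_mat()] (one per timepoint, `metadata$timepoint`
#'   set), plus attribute `"gene_sets"` as in [generate_bulk_dataset()].
#' @export
generate_timecourse <- function(config, n_timepoints = 5) {
  stopifnot(inherits(config, "synth_config"))
  if (config$n_samples <= 0) stop("need a positive number of cells per timepoint", call. = FALSE)
  if (n_timepoints < 2) stop("need >= 2 timepoints", call. = FALSE)
  set.seed(config$seed)
  layout <- synth_gene_layout(config$n_genes)
  all_genes <- c(names(layout$driver), layout$background)
  baseline <- stats::rnorm(length(all_genes), config$baseline_mean, config$baseline_sd)
  drv <- layout$driver
  mats <- purrr::map(seq_len(n_timepoints), function(t) {
    progress <- (t - 1) / (n_timepoints - 1)      # 0 -> 1 along induction
    lat <- draw_latents(config$n_samples, config$coupling)
    lat[, "Mes"] <- lat[, "Mes"] + config$effect_size * (progress - 0.5)
    lat[, "Epi"] <- lat[, "Epi"] - config$effect_size * (progress - 0.5)
    vals <- matrix(stats::rnorm(length(all_genes) * config$n_samples,
                                sd = config$noise_sd),
                   nrow = length(all_genes),
                   dimnames = list(all_genes,
                                   sprintf("T%dC%04d", t, seq_len(config$n_samples))))
    vals <- vals + baseline
    vals[names(drv), ] <- vals[names(drv), ] +
      config$effect_size * t(lat[, drv, drop = FALSE])
    expr_mat(vals, metadata = list(timepoint = t, log_scale = TRUE))
  })
  sets <- purrr::imap(layout$sets, function(g, nm) gene_set(nm, g))
  attr(mats, "gene_sets") <- structure(sets, class = "gene_set_collection")
  mats
}

#' Generate survival data under proportional hazards between groups
#'
#' Exponential event times with rate `baseline_hazard *
#' hazard_multiplier^[group == risk_group]` and independent exponential
#' censoring calibrated so the expected censored fraction equals
#' `censoring_fraction` in every group.
#'
#' @param config A [synth_config()] (hazard and censoring settings).
#' @param groups A [median_split()] assignment or tibble with
#'   `sample_id`, `group`.
#' @param risk_group Label carrying the hazard multiplier (default
#'   `"P+G+"`).
#'
#' @return Tibble: `sample_id`, `os_time`, `os_event` (1 = event,
#'   0 = censored), `group`.
#' @export
generate_survival <- function(config, groups, risk_group = "P+G+") {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  g <- tibble::as_tibble(groups)
  rate <- config$baseline_hazard *
    ifelse(g$group == risk_group, config$hazard_multiplier, 1)
  t_event <- stats::rexp(nrow(g), rate = rate)
  if (config$censoring_fraction > 0) {
    f <- config$censoring_fraction
    c_rate <- rate * f / (1 - f)   # P(censored) = f for exponential races
    t_cens <- stats::rexp(nrow(g), rate = c_rate)
    tibble::tibble(sample_id = g$sample_id,
                   os_time = pmin(t_event, t_cens),
                   os_event = as.integer(t_event <= t_cens),
                   group = g$group)
  } else {
    tibble::tibble(sample_id = g$sample_id, os_time = t_event,
                   os_event = 1L, group = g$group)
  }
}
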