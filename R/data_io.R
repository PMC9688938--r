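#' Expression matrix container
#'
#' A thin wrapper around a numeric genes x samples matrix on log2 scale.
#' Gene symbols are uppercased at construction so that matching against
#' gene sets (also uppercased on load) is consistent across platforms,
#' which mix symbol cases freely.
#'
#' @param values Numeric matrix, genes in rows, samples in columns, with
#'   unique non-empty rownames (gene or probe identifiers) and unique
#'   colnames (sample identifiers).
#' @param metadata Named list of free-form annotations (dataset id,
#'   platform, treatment, ...). The reserved entry `log_scale` records
#'   whether the values are on log2 scale (`TRUE`/`FALSE`/`NA` = unknown).
#' @param uppercase Uppercase rownames (default `TRUE`). Probe-level
#'   matrices may want to keep probe ids as-is.
#'
#' @return An object of class `expr_mat`.
#' @export
expr_mat <- function(values, metadata = list(), uppercase = TRUE) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (genes x samples)", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have rownames (genes) and colnames (samples)", call. = FALSE)
  }
  if (uppercase) rownames(values) <- toupper(rownames(values))
  gid <- rownames(values)
  sid <- colnames(values)
  if (anyDuplicated(gid)) {
    stop("duplicate gene/probe ids: ",
         paste(utils::head(unique(gid[duplicated(gid)]), 5), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(sid)) {
    stop("duplicate sample ids: ",
         paste(utils::head(unique(sid[duplicated(sid)]), 5), collapse = ", "),
         call. = FALSE)
  }
  if (any(!nzchar(gid)) || anyNA(gid)) stop("empty gene ids are not allowed", call. = FALSE)
  if (!("log_scale" %in% names(metadata))) metadata$log_scale <- NA
  structure(list(values = values, metadata = metadata), class = "expr_mat")
}

#' @export
print.expr_mat <- function(x, ...) {
  cat(sprintf("<expr_mat> %d genes x %d samples (log2 scale: %s)\n",
              nrow(x$values), ncol(x$values), as.character(x$metadata$log_scale)))
  if (!is.null(x$metadata$dataset_id)) cat("  dataset:", x$metadata$dataset_id, "\n")
  invisible(x)
}

#' @export
dim.expr_mat <- function(x) dim(x$values)

#' Gene ids of an expression matrix
#' @param x An `expr_mat`.
#' @return Character vector of gene symbols (rownames).
#' @export
genes <- function(x) rownames(x$values)

#' Sample ids of an expression matrix
#' @param x An `expr_mat`.
#' @return Character vector of sample identifiers (colnames).
#' @export
samples <- function(x) colnames(x$values)

#' @describeIn expr_mat Long-format view: one row per (gene, sample, value).
#' @param x An `expr_mat`.
#' @param ... Unused.
#' @export
as_tibble.expr_mat <- function(x, ...) {
  tibble::as_tibble(x$values, rownames = "gene") |>
    tidyr::pivot_longer(-"gene", names_to = "sample_id", values_to = "value")
}

#' Read a delimited expression matrix
#'
#' Expects one header row of sample ids and one leading column of gene (or
#' probe) ids; TSV or CSV is chosen from the file extension. Genes with any
#' missing value are dropped with a warning — downstream scoring assumes
#' complete expression vectors.
#'
#' @param path File path (`.tsv`/`.txt` tab-delimited, `.csv` comma).
#' @param transpose If `TRUE` the file is samples x genes and is flipped
#'   to the genes x samples orientation on read.
#' @param log_scale Whether the stored values are already log2 scale
#'   (default `TRUE`); use `FALSE` for linear-scale input that still needs
#'   [log2_normalize()].
#' @param metadata Extra metadata entries for the returned object.
#'
#' @return An [expr_mat()].
#' @export
read_expression <- function(path, transpose = FALSE, log_scale = TRUE,
                            metadata = list()) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()), name_repair = "minimal")
  if (ncol(df) < 2) stop("malformed header in ", path, ": need an id column plus >=1 sample column", call. = FALSE)
  hdr <- names(df)[-1]
  if (anyDuplicated(hdr)) {
    stop("duplicate sample id '", hdr[duplicated(hdr)][1], "' in header of ", path,
         call. = FALSE)
  }
  ids <- df[[1]]
  num <- suppressWarnings(
    vapply(df[-1], function(col) as.numeric(col), numeric(nrow(df))))
  if (nrow(df) == 1L) num <- matrix(num, nrow = 1, dimnames = list(NULL, names(df)[-1]))
  bad <- which(is.na(num) & !is.na(as.matrix(df[-1])), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-numeric cell at row '%s', column '%s' in %s",
                 ids[bad[1, 1]], colnames(num)[bad[1, 2]], path), call. = FALSE)
  }
  rownames(num) <- ids
  if (transpose) num <- t(num)
  n_missing <- sum(!stats::complete.cases(num))
  if (n_missing > 0) {
    warning(sprintf("dropped %d gene(s) with missing values", n_missing), call. = FALSE)
    num <- num[stats::complete.cases(num), , drop = FALSE]
  }
  metadata$log_scale <- log_scale
  if (is.null(metadata$path)) metadata$path <- path
  expr_mat(num, metadata = metadata)
}

#' Write an expression matrix as TSV
#'
#' Values are formatted with 10 significant digits so repeated runs on the
#' same inputs produce byte-identical files.
#'
#' @param x An `expr_mat`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  df <- tibble::as_tibble(x$values, rownames = "gene")
  df <- dplyr::mutate(df, dplyr::across(-"gene", ~ sprintf("%.10g", .x)))
  readr::write_tsv(df, path)
  invisible(path)
}

#' Collapse a probe-level matrix to gene level
#'
#' Each gene's value per sample is the arithmetic mean over all probes
#' mapped to it. A probe annotated to several genes contributes to each of
#' them; probes with no (or empty) gene annotation are dropped.
#'
#' @param probe_matrix An `expr_mat` whose rows are probe ids.
#' @param annotation Data frame with columns `probe_id`, `gene_symbol`
#'   (one row per probe-gene pair; empty symbol = unmapped).
#'
#' @return A gene-level [expr_mat()]; `metadata$dropped_probes` records how
#'   many probes had no mapping.
#' @export
collapse_probes <- function(probe_matrix, annotation) {
  stopifnot(inherits(probe_matrix, "expr_mat"))
  ann <- tibble::as_tibble(annotation)
  if (!all(c("probe_id", "gene_symbol") %in% names(ann))) {
    stop("annotation needs columns probe_id, gene_symbol", call. = FALSE)
  }
  ann <- ann |>
    dplyr::mutate(gene_symbol = toupper(.data$gene_symbol)) |>
    dplyr::filter(!is.na(.data$gene_symbol), nzchar(.data$gene_symbol)) |>
    dplyr::filter(.data$probe_id %in% rownames(probe_matrix$values)) |>
    dplyr::distinct(.data$probe_id, .data$gene_symbol)
  if (nrow(ann) == 0) stop("zero probes map to a gene symbol", call. = FALSE)
  vals <- probe_matrix$values[ann$probe_id, , drop = FALSE]
  sums <- rowsum(vals, group = ann$gene_symbol)
  counts <- as.vector(table(ann$gene_symbol)[rownames(sums)])
  collapsed <- sums / counts
  md <- probe_matrix$metadata
  md$dropped_probes <- nrow(probe_matrix$values) - length(unique(ann$probe_id))
  expr_mat(collapsed, metadata = md)
}

#' log2-transform a linear-scale matrix
#'
#' Replaces every value x by `log2(x + pseudocount)` and flags the matrix
#' as log scale. Refuses matrices already flagged log scale and matrices
#' with negative values.
#'
#' @param x An `expr_mat` on linear scale.
#' @param pseudocount Non-negative offset added before the log (default 1).
#' @return The transformed `expr_mat`.
#' @export
log2_normalize <- function(x, pseudocount = 1) {
  stopifnot(inherits(x, "expr_mat"))
  if (isTRUE(x$metadata$log_scale)) {
    stop("matrix is already flagged log2 scale; refusing to transform twice", call. = FALSE)
  }
  if (pseudocount < 0) stop("pseudocount must be >= 0", call. = FALSE)
  if (any(x$values < 0)) stop("negative values: input must be linear scale (>= 0)", call. = FALSE)
  x$values <- log2(x$values + pseudocount)
  x$metadata$log_scale <- TRUE
  x$metadata$pseudocount <- pseudocount
  x
}

#' Construct a gene set
#'
#' @param name Set name.
#' @param genes Character vector of gene symbols (uppercased, deduplicated).
#' @param role Optional role tag: one of `"epithelial"`, `"mesenchymal"`,
#'   `"pemt"`, `"hallmark_pathway"`, `"target_set"`, `"signature"`.
#' @return An object of class `gene_set`.
#' @export
gene_set <- function(name, genes, role = NA_character_) {
  genes <- unique(toupper(as.character(genes)))
  genes <- genes[nzchar(genes) & !is.na(genes)]
  if (length(genes) == 0) stop("gene set '", name, "' is empty", call. = FALSE)
  ok_roles <- c("epithelial", "mesenchymal", "pemt", "hallmark_pathway",
                "target_set", "signature")
  if (!is.na(role) && !role %in% ok_roles) {
    stop("unknown role '", role, "'", call. = FALSE)
  }
  structure(list(name = name, genes = genes, role = role), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s (%d genes%s)\n", x$name, length(x$genes),
              if (is.na(x$role)) "" else paste0(", role: ", x$role)))
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$genes)

# Accept a gene_set or a bare character vector of symbols.
as_gene_set <- function(gs, name = "set") {
  if (inherits(gs, "gene_set")) gs else gene_set(name, gs)
}

#' Read a GMT gene-set file
#'
#' One set per line: `name TAB description TAB gene TAB gene ...`. The
#' description field is discarded; duplicate genes within a line are
#' deduplicated with a warning.
#'
#' @param path GMT file path.
#' @return A named list of [gene_set()] objects (class
#'   `gene_set_collection`).
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop(sprintf("GMT line %d has %d field(s); need name, description, >=1 gene",
                   i, length(fields)), call. = FALSE)
    }
    nm <- fields[[1]]
    gs <- toupper(fields[-(1:2)])
    gs <- gs[nzchar(gs)]
    if (anyDuplicated(gs)) {
      warning(sprintf("GMT line %d ('%s'): %d duplicate gene(s) removed",
                      i, nm, sum(duplicated(gs))), call. = FALSE)
    }
    if (nm %in% names(sets)) stop("duplicate set name '", nm, "' in ", path, call. = FALSE)
    sets[[nm]] <- gene_set(nm, gs)
  }
  structure(sets, class = "gene_set_collection")
}

#' Write a collection (or single set) to GMT
#'
#' @param sets A `gene_set_collection`, list of `gene_set`s, or single set.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  if (inherits(sets, "gene_set")) sets <- list(sets)
  lines <- vapply(sets, function(s) {
    paste(c(s$name, "na", s$genes), collapse = "\t")
  }, character(1))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a two-column probe annotation TSV
#'
#' @param path TSV with columns `probe_id`, `gene_symbol`.
#' @return A tibble with those two columns.
#' @export
read_probe_annotation <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    probe_id = readr::col_character(),
    gene_symbol = readr::col_character()))
}
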