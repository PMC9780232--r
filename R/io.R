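#' Write a simulated dataset to disk
#'
#' Serializes a [simulate_dataset()] result as plain-text artifacts: counts as
#' a MatrixMarket sparse matrix (`counts.mtx`, genes x cells, 1-based indices
#' per the MTX standard), cell metadata (`cell_metadata.tsv`: cell_id,
#' individual_id, group), gene truth (`gene_truth.tsv`: gene_id, is_de,
#' fold_change, baseline_mean) and the full parameter set including the master
#' seed (`params.yaml`). [read_dataset()] round-trips the result losslessly.
#'
#' @param ds A `sim_dataset`.
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_dataset <- function(ds, out_dir) {
  stopifnot(inherits(ds, "sim_dataset"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create directory: ", out_dir, call. = FALSE)

  m <- methods::as(Matrix::Matrix(ds$counts, sparse = TRUE), "CsparseMatrix")
  Matrix::writeMM(m, file.path(out_dir, "counts.mtx"))

  cell_meta <- data.frame(cell_id = colnames(ds$counts),
                          individual_id = unname(ds$cell_individual),
                          group = unname(ds$individual_group[ds$cell_individual]),
                          stringsAsFactors = FALSE)
  utils::write.table(cell_meta, file.path(out_dir, "cell_metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  truth <- ds$truth
  truth$fold_change <- sprintf("%.17g", truth$fold_change)
  truth$baseline_mean <- sprintf("%.17g", truth$baseline_mean)
  utils::write.table(truth, file.path(out_dir, "gene_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  cfg <- unclass(ds$params)
  cfg$seed_used <- ds$seed_used
  yaml::write_yaml(cfg, file.path(out_dir, "params.yaml"),
                   precision = 17L)
  invisible(out_dir)
}

#' Read a simulated dataset written by [write_dataset()]
#'
#' Also serves as the reader for user-supplied counts: any directory with a
#' genes x cells `counts.mtx`, a `cell_metadata.tsv` (cell_id, individual_id,
#' group) and optionally `gene_truth.tsv` / `params.yaml` is accepted; the
#' DE-method layer only needs counts and the cell-to-individual map.
#'
#' @param dir Directory containing the dataset files.
#' @return A `sim_dataset` (with `truth`/`params` set to `NULL` when the
#'   corresponding files are absent).
#' @export
read_dataset <- function(dir) {
  mtx <- file.path(dir, "counts.mtx")
  meta_f <- file.path(dir, "cell_metadata.tsv")
  if (!file.exists(mtx) || !file.exists(meta_f))
    stop("dataset directory must contain counts.mtx and cell_metadata.tsv",
         call. = FALSE)
  counts <- as.matrix(Matrix::readMM(mtx))
  storage.mode(counts) <- "integer"
  cell_meta <- utils::read.table(meta_f, header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE)

  truth <- NULL
  truth_f <- file.path(dir, "gene_truth.tsv")
  if (file.exists(truth_f)) {
    truth <- utils::read.table(truth_f, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
    truth$is_de <- as.logical(truth$is_de)
  }

  params <- NULL
  seed_used <- NA_integer_
  params_f <- file.path(dir, "params.yaml")
  if (file.exists(params_f)) {
    cfg <- yaml::read_yaml(params_f)
    seed_used <- cfg$seed_used
    cfg$seed_used <- NULL
    params <- do.call(sim_params, cfg)
  }

  gene_id <- if (!is.null(truth)) truth$gene_id else
    sprintf("gene_%06d", seq_len(nrow(counts)))
  dimnames(counts) <- list(gene_id, cell_meta$cell_id)

  ind <- unique(cell_meta[, c("individual_id", "group")])
  structure(list(
    counts = counts,
    cell_individual = stats::setNames(cell_meta$individual_id, cell_meta$cell_id),
    individual_group = stats::setNames(ind$group, ind$individual_id),
    truth = truth,
    params = params,
    seed_used = seed_used
  ), class = "sim_dataset")
}

#' Write per-method differential expression results
#'
#' One TSV per method (`<method>.tsv`, spaces and colons sanitised) with
#' columns gene_id, p_value, effect_estimate, fit_ok.
#'
#' @param results Named list of `de_result` objects (as from
#'   [run_all_methods()]).
#' @param gene_id Gene identifiers matching the result length.
#' @param out_dir Output directory (created if missing).
#' @return Invisible character vector of files written.
#' @export
write_de_results <- function(results, gene_id, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (res in results) {
    stopifnot(inherits(res, "de_result"))
    tab <- data.frame(gene_id = gene_id,
                      p_value = res$p_values,
                      effect_estimate = res$effect_estimates,
                      fit_ok = !is.na(res$p_values),
                      stringsAsFactors = FALSE)
    f <- file.path(out_dir, paste0(
      gsub("[^A-Za-z0-9]+", "_", tolower(res$method_name)), ".tsv"))
    utils::write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
  }
  invisible(files)
}
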