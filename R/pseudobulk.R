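# Pseudobulk aggregation and the sample-level two-group test.

de_result <- function(method, p_values, effect, checksum, extra = list()) {
  p_ok <- p_values[!is.na(p_values)]
  stopifnot(all(p_ok >= 0 & p_ok <= 1))
  structure(c(list(
    method_name = method,
    p_values = as.numeric(p_values),
    effect_estimates = as.numeric(effect),
    n_failed = sum(is.na(p_values)),
    dataset_checksum = checksum
  ), extra), class = "de_result")
}

#' @export
print.de_result <- function(x, ...) {
  cat(sprintf("de_result '%s': %d genes, %d failed fits, %d p < 0.05\n",
              x$method_name, length(x$p_values), x$n_failed,
              sum(x$p_values < 0.05, na.rm = TRUE)))
  invisible(x)
}

#' Collapse single-cell counts to one value per gene per individual
#'
#' @param ds A `sim_dataset` (simulated or read from disk).
#' @param aggregation `"sum"` (integer sum of an individual's cells) or
#'   `"mean"` (that sum divided by the individual's own cell count; invariant
#'   to between-group differences in cells per individual).
#' @return An object of class `pseudobulk`: `values` (genes x individuals),
#'   `individual_group`, `aggregation`, `normalized`, and the checksum of the
#'   source counts.
#' @examples
#' ds <- simulate_dataset(sim_params(n_genes = 20, n_cases = 3, n_controls = 3,
#'   cells_per_individual_case = 5, cells_per_individual_control = 5,
#'   master_seed = 1))
#' pb <- aggregate_pseudobulk(ds, "mean")
#' dim(pb$values)
#' @export
aggregate_pseudobulk <- function(ds, aggregation = c("sum", "mean")) {
  aggregation <- match.arg(aggregation)
  ind_ids <- names(ds$individual_group)
  f <- factor(ds$cell_individual, levels = ind_ids)
  n_cells <- as.vector(table(f))
  if (any(n_cells == 0))
    stop("every individual must have at least one cell", call. = FALSE)
  # genes x cells %*% cells x individuals indicator
  M <- Matrix::sparseMatrix(i = seq_along(f), j = as.integer(f), x = 1,
                            dims = c(length(f), length(ind_ids)))
  values <- as.matrix(ds$counts %*% M)
  if (aggregation == "mean") {
    values <- sweep(values, 2L, n_cells, "/")
  }
  dimnames(values) <- list(rownames(ds$counts), ind_ids)
  structure(list(
    values = values,
    individual_group = ds$individual_group,
    n_cells = stats::setNames(n_cells, ind_ids),
    aggregation = aggregation,
    normalized = FALSE,
    source_checksum = dataset_checksum(ds$counts)
  ), class = "pseudobulk")
}

#' Counts-per-million normalization of a pseudobulk matrix
#'
#' Rescales each individual's column to a total of one million. Off by default
#' in the benchmark pipeline (the simulator induces no library-size variation,
#' and running un-normalized reproduces the conditions under which sum
#' aggregation degrades on imbalanced designs); turning it on makes mean and
#' sum aggregation exactly equivalent, since the two differ only by a per-column
#' scale.
#'
#' @param pb A `pseudobulk` object with strictly positive column totals.
#' @return The normalized `pseudobulk` (idempotent).
#' @export
normalize_cpm <- function(pb) {
  stopifnot(inherits(pb, "pseudobulk"))
  totals <- colSums(pb$values)
  if (any(totals <= 0))
    stop("cannot CPM-normalize a column with non-positive total", call. = FALSE)
  pb$values <- sweep(pb$values, 2L, totals / 1e6, "/")
  pb$normalized <- TRUE
  pb
}

# Vectorised Welch two-sample t-test across matrix rows.
# Zero pooled SE: p = 1 when the group means agree (no evidence), 0 otherwise.
welch_rows <- function(X, idx1, idx2) {
  n1 <- length(idx1); n2 <- length(idx2)
  stopifnot(n1 >= 2, n2 >= 2)
  X1 <- X[, idx1, drop = FALSE]; X2 <- X[, idx2, drop = FALSE]
  m1 <- rowMeans(X1); m2 <- rowMeans(X2)
  v1 <- rowSums((X1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((X2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  zero <- se2 == 0
  if (any(zero)) p[zero] <- ifelse(m1[zero] == m2[zero], 1, 0)
  list(p = p, effect = m1 - m2, t = tstat, df = df)
}

#' Sample-level two-group test on a pseudobulk matrix
#'
#' Per gene, a Welch two-sample t-test of case vs control individuals on
#' `log2(value + 1)`; the effect estimate is the difference of group means on
#' that scale. Genes with zero variance in both groups get p = 1 when the
#' means agree (no evidence) and p = 0 otherwise.
#'
#' @param pb A `pseudobulk` with at least two individuals per group.
#' @return A `de_result` named `"Pseudobulk: Mean"` or `"Pseudobulk: Sum"`
#'   after the aggregation used.
#' @export
test_pseudobulk <- function(pb) {
  stopifnot(inherits(pb, "pseudobulk"))
  grp <- pb$individual_group
  idx1 <- which(grp == "case"); idx2 <- which(grp == "control")
  if (length(idx1) < 2 || length(idx2) < 2)
    stop("need at least two individuals per group", call. = FALSE)
  w <- welch_rows(log2(pb$values + 1), idx1, idx2)
  de_result(paste0("Pseudobulk: ", tools::toTitleCase(pb$aggregation)),
            w$p, w$effect, pb$source_checksum,
            extra = list(normalized = pb$normalized))
}
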