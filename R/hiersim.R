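#' Draw signed fold changes for differentially expressed genes
#'
#' Magnitudes are drawn uniformly (or log-uniformly) from
#' \[`fc_min`, `fc_max`\]; each gene is up-regulated (fold change = magnitude)
#' or down-regulated (fold change = 1/magnitude) with probability 1/2.
#'
#' Draws are interleaved per gene (magnitude, then direction) so that the
#' first `k` genes consume the same random numbers regardless of how many
#' genes follow — this is what keeps gene counts invariant when only the DE
#' proportion changes.
#'
#' @param n_de Number of DE genes (>= 0).
#' @param fc_min,fc_max Magnitude bounds; `fc_min > 1`, `fc_max >= fc_min`.
#' @param log_uniform Draw magnitudes log-uniformly instead of uniformly.
#' @param stream Optional RNG state (an `.Random.seed` vector) to use;
#'   by default the current global stream is consumed.
#' @return Numeric vector of `n_de` fold changes, each in
#'   \[`fc_min`, `fc_max`\] or \[1/`fc_max`, 1/`fc_min`\].
#' @examples
#' set.seed(1)
#' fc <- sample_fold_changes(5, 1.1, 10)
#' all(pmax(fc, 1 / fc) >= 1.1)
#' @export
sample_fold_changes <- function(n_de, fc_min = 1.1, fc_max = 10,
                                log_uniform = FALSE, stream = NULL) {
  if (!is.numeric(n_de) || length(n_de) != 1L || n_de < 0 || n_de != round(n_de))
    stop("n_de must be a non-negative integer", call. = FALSE)
  if (fc_min <= 1) stop("fc_min must exceed 1", call. = FALSE)
  if (fc_max < fc_min) stop("fc_max must be >= fc_min", call. = FALSE)
  if (n_de == 0) return(numeric(0))
  if (!is.null(stream)) set_stream(stream)
  u <- matrix(stats::runif(2L * n_de), nrow = 2L)
  mag <- if (log_uniform) {
    exp(log(fc_min) + u[1L, ] * (log(fc_max) - log(fc_min)))
  } else {
    fc_min + u[1L, ] * (fc_max - fc_min)
  }
  up <- u[2L, ] < 0.5
  ifelse(up, mag, 1 / mag)
}

#' Simulate one gene's counts over all cells
#'
#' One draw from the hierarchical law: a log-normal individual effect on the
#' gene mean, the fold change applied to case individuals, negative-binomial
#' cell counts, and logistic dropout whose rate falls with the individual's
#' mean expression (see [sim_params()] for the model statement).
#'
#' @param gene_mean Baseline mean expression (> 0).
#' @param fold_change Case/control fold change (> 0); 1 for a null gene.
#' @param design Layout from the internal design builder: a list with
#'   `individuals` (individual_id, group, n_cells) and `cells` data frames.
#' @param params A [sim_params()] object (only the noise/dropout fields are
#'   read here).
#' @param stream Optional RNG state to use for this gene.
#' @return Integer vector of counts, one per cell, in design cell order.
#' @export
simulate_gene <- function(gene_mean, fold_change, design, params, stream = NULL) {
  if (!is.numeric(gene_mean) || length(gene_mean) != 1L || gene_mean <= 0)
    stop("gene_mean must be a positive number", call. = FALSE)
  if (!is.numeric(fold_change) || length(fold_change) != 1L || fold_change <= 0)
    stop("fold_change must be a positive number", call. = FALSE)
  if (!is.null(stream)) set_stream(stream)

  ind <- design$individuals
  n_ind <- nrow(ind)
  delta <- stats::rnorm(n_ind, 0, params$sigma_ind)
  m <- gene_mean * exp(delta)
  m[ind$group == "case"] <- m[ind$group == "case"] * fold_change

  mu_cell <- rep(m, ind$n_cells)
  n_cells <- length(mu_cell)
  latent <- if (params$nb_dispersion > 0) {
    stats::rnbinom(n_cells, mu = mu_cell, size = 1 / params$nb_dispersion)
  } else {
    stats::rpois(n_cells, mu_cell)
  }
  pi_ind <- stats::plogis(params$dropout_intercept - params$dropout_slope * log(m))
  drop <- stats::runif(n_cells) < rep(pi_ind, ind$n_cells)
  counts <- latent
  counts[drop] <- 0L
  as.integer(counts)
}

#' Simulate a full two-group single-cell dataset with known DE truth
#'
#' Draws gene baseline means from
#' LogNormal(`grand_mean_log_mu`, `grand_mean_log_sd`), flags exactly
#' `round(n_genes * prop_de)` genes as differentially expressed (the first k
#' indices of a seeded permutation), assigns them signed fold changes via
#' [sample_fold_changes()], and simulates every gene independently with
#' [simulate_gene()] on its own RNG substream. Regenerating with the same
#' parameters and master seed yields a bit-identical dataset, and changing
#' `prop_de` leaves the counts of genes with unchanged DE status untouched.
#'
#' @param params A [sim_params()] object.
#' @return An object of class `sim_dataset`: a list with `counts` (genes x
#'   cells integer matrix), `cell_individual` (per-cell individual id),
#'   `individual_group` (named vector, individual id -> "case"/"control"),
#'   `truth` (data frame: gene_id, is_de, fold_change, baseline_mean),
#'   `params`, and `seed_used`.
#' @examples
#' ds <- simulate_dataset(sim_params(n_genes = 50, prop_de = 0.2,
#'   n_cases = 3, n_controls = 3, cells_per_individual_case = 10,
#'   cells_per_individual_control = 10, master_seed = 42))
#' sum(ds$truth$is_de)
#' @export
simulate_dataset <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  design <- make_design(params)
  n_genes <- params$n_genes
  n_cells <- nrow(design$cells)

  old <- save_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  streams <- derive_streams(params$master_seed, n_genes + 1L)

  # Meta stream: baseline means, DE assignment, fold changes (in that order).
  set_stream(streams[[1L]])
  gene_means <- stats::rlnorm(n_genes, params$grand_mean_log_mu,
                              params$grand_mean_log_sd)
  perm <- sample.int(n_genes)
  n_de <- round(n_genes * params$prop_de)
  de_idx <- perm[seq_len(n_de)]
  fold_change <- rep(1, n_genes)
  if (n_de > 0) {
    fold_change[de_idx] <- sample_fold_changes(
      n_de, params$fc_min, params$fc_max, log_uniform = params$fc_log_uniform)
  }
  is_de <- logical(n_genes)
  is_de[de_idx] <- TRUE

  counts <- matrix(0L, nrow = n_genes, ncol = n_cells)
  for (g in seq_len(n_genes)) {
    counts[g, ] <- simulate_gene(gene_means[g], fold_change[g], design, params,
                                 stream = streams[[g + 1L]])
  }
  gene_id <- sprintf("gene_%06d", seq_len(n_genes))
  dimnames(counts) <- list(gene_id, design$cells$cell_id)

  individual_group <- stats::setNames(design$individuals$group,
                                      design$individuals$individual_id)
  cell_individual <- stats::setNames(design$cells$individual_id,
                                     design$cells$cell_id)

  structure(list(
    counts = counts,
    cell_individual = cell_individual,
    individual_group = individual_group,
    truth = data.frame(gene_id = gene_id, is_de = is_de,
                       fold_change = fold_change, baseline_mean = gene_means,
                       stringsAsFactors = FALSE),
    params = params,
    seed_used = params$master_seed
  ), class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("sim_dataset: %d genes x %d cells (%d DE), %d cases + %d controls, seed %d\n",
              nrow(x$counts), ncol(x$counts), sum(x$truth$is_de),
              x$params$n_cases, x$params$n_controls, x$seed_used))
  invisible(x)
}

#' Checksum of a counts matrix
#'
#' A cheap deterministic fingerprint of the counts (values and shape), used to
#' assert that every differential-expression method within one benchmark
#' iteration consumed the identical dataset.
#'
#' @param counts Integer/numeric matrix, or a `sim_dataset`.
#' @return A string `"<genes>x<cells>-<digest>"`.
#' @export
dataset_checksum <- function(counts) {
  if (inherits(counts, "sim_dataset")) counts <- counts$counts
  x <- as.numeric(counts)
  w <- rep_len(c(1, 2, 5, 11, 17, 31, 43, 59), length(x))
  sprintf("%dx%d-%.0f", nrow(counts), ncol(counts),
          sum(x * w) %% 2147483647)
}
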