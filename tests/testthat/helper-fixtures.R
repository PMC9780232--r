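# Shared fixture builders. Everything is generated in code at test time.

# A small, fast parameter set; override any field via ...
small_params <- function(...) {
  defaults <- list(
    n_genes = 100L, prop_de = 0.1, n_cases = 5L, n_controls = 5L,
    cells_per_individual_case = 20L, cells_per_individual_control = 20L,
    master_seed = 42L
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_params, args)
}

# Build a sim_dataset by hand from an explicit counts matrix and a
# cell -> individual -> group layout. Used for arithmetic-level checks where
# the counts must be chosen, not simulated.
manual_dataset <- function(counts, individual_of_cell, group_of_individual,
                           is_de = rep(FALSE, nrow(counts))) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  gene_id <- sprintf("gene_%06d", seq_len(nrow(counts)))
  cell_id <- sprintf("cell_%06d", seq_len(ncol(counts)))
  dimnames(counts) <- list(gene_id, cell_id)
  structure(list(
    counts = counts,
    cell_individual = stats::setNames(individual_of_cell, cell_id),
    individual_group = group_of_individual,
    truth = data.frame(gene_id = gene_id, is_de = is_de,
                       fold_change = ifelse(is_de, 2, 1),
                       baseline_mean = rep(1, nrow(counts)),
                       stringsAsFactors = FALSE),
    params = NULL,
    seed_used = NA_integer_
  ), class = "sim_dataset")
}

# A dataset where case and control cells carry identical count vectors
# (gene-wise), so every two-sided test should find no evidence.
mirrored_dataset <- function(n_genes = 20, n_ind_per_group = 4, cells = 5,
                             seed = 1) {
  set.seed(seed)
  half <- matrix(rpois(n_genes * n_ind_per_group * cells, 3),
                 nrow = n_genes)
  counts <- cbind(half, half)
  inds <- c(rep(sprintf("case_%02d", seq_len(n_ind_per_group)), each = cells),
            rep(sprintf("ctrl_%02d", seq_len(n_ind_per_group)), each = cells))
  grp <- stats::setNames(rep(c("case", "control"), each = n_ind_per_group),
                         c(sprintf("case_%02d", seq_len(n_ind_per_group)),
                           sprintf("ctrl_%02d", seq_len(n_ind_per_group))))
  manual_dataset(counts, inds, grp)
}

# Intraclass correlation from a one-way ANOVA decomposition (the classic
# expected-mean-squares estimator), used as the oracle for donor effects.
anova_icc <- function(values, cluster) {
  cluster <- factor(cluster)
  k <- length(values) / nlevels(cluster)
  fit <- stats::aov(values ~ cluster)
  ms <- summary(fit)[[1]][["Mean Sq"]]
  (ms[1] - ms[2]) / (ms[1] + (k - 1) * ms[2])
}
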