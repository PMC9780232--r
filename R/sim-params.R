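#' Simulation parameters for the hierarchical single-cell count generator
#'
#' Bundles every knob of the two-group hierarchical simulator: the gene
#' complement, the case/control design (individuals and cells per individual),
#' the fold-change bounds for differentially expressed (DE) genes, and the
#' generative law's parameters (log-normal baseline means, donor random
#' effect, negative-binomial dispersion, logistic dropout).
#'
#' The generative model, per gene with baseline mean \eqn{\mu} and fold change
#' \eqn{f}: each individual \eqn{i} gets a mean
#' \eqn{m_i = \mu e^{\delta_i}} with \eqn{\delta_i \sim N(0, \sigma_{ind}^2)},
#' multiplied by \eqn{f} if the individual is a case; each cell of individual
#' \eqn{i} draws a latent count from a negative binomial with mean \eqn{m_i}
#' and variance \eqn{m_i + \phi m_i^2}; the observed count is zeroed with
#' dropout probability
#' \eqn{\pi_i = \mathrm{logit}^{-1}(a - b \log m_i)}.
#'
#' @param n_genes Number of genes simulated independently.
#' @param prop_de Fraction of genes that are DE, in \[0, 1\]. The DE count is
#'   exactly `round(n_genes * prop_de)`.
#' @param n_cases,n_controls Individuals per group.
#' @param cells_per_individual_case,cells_per_individual_control Cells per
#'   individual in each group; set them unequal for the imbalanced design.
#' @param fc_min,fc_max Fold-change magnitude bounds for DE genes
#'   (defaults 1.1 and 10). `fc_min` must exceed 1.
#' @param fc_log_uniform If `TRUE`, fold-change magnitudes are drawn
#'   log-uniformly on \[fc_min, fc_max\]; default is uniform on the natural
#'   scale.
#' @param grand_mean_log_mu,grand_mean_log_sd Mean and SD (log scale) of the
#'   log-normal distribution of gene baseline means.
#' @param sigma_ind SD (log scale) of the individual-level random effect;
#'   0 makes cells exchangeable across individuals.
#' @param nb_dispersion Negative-binomial dispersion \eqn{\phi}
#'   (variance \eqn{= m + \phi m^2}); 0 collapses to Poisson.
#' @param dropout_intercept,dropout_slope Parameters \eqn{a}, \eqn{b} of the
#'   logistic dropout curve; `dropout_intercept = -Inf` disables dropout.
#' @param master_seed Non-negative integer seeding the whole dataset.
#'
#' @return An object of class `sim_params`.
#' @examples
#' p <- sim_params(n_genes = 100, prop_de = 0.1, n_cases = 4, n_controls = 4,
#'                 cells_per_individual_case = 20,
#'                 cells_per_individual_control = 20, master_seed = 7)
#' p$n_genes
#' @export
sim_params <- function(n_genes = 10000L,
                       prop_de = 0.1,
                       n_cases = 20L,
                       n_controls = 20L,
                       cells_per_individual_case = 100L,
                       cells_per_individual_control = 100L,
                       fc_min = 1.1,
                       fc_max = 10,
                       fc_log_uniform = FALSE,
                       grand_mean_log_mu = 1,
                       grand_mean_log_sd = 1,
                       sigma_ind = 0.5,
                       nb_dispersion = 0.5,
                       dropout_intercept = 0,
                       dropout_slope = 1,
                       master_seed = 1L) {
  check_count <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != round(x))
      stop(nm, " must be a positive integer", call. = FALSE)
    as.integer(x)
  }
  check_num <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x))
      stop(nm, " must be a single number", call. = FALSE)
    as.numeric(x)
  }
  n_genes <- check_count(n_genes, "n_genes")
  n_cases <- check_count(n_cases, "n_cases")
  n_controls <- check_count(n_controls, "n_controls")
  cells_per_individual_case <- check_count(cells_per_individual_case,
                                           "cells_per_individual_case")
  cells_per_individual_control <- check_count(cells_per_individual_control,
                                              "cells_per_individual_control")
  prop_de <- check_num(prop_de, "prop_de")
  if (prop_de < 0 || prop_de > 1) stop("prop_de must lie in [0, 1]", call. = FALSE)
  fc_min <- check_num(fc_min, "fc_min")
  fc_max <- check_num(fc_max, "fc_max")
  if (fc_min <= 1) stop("fc_min must exceed 1", call. = FALSE)
  if (fc_max < fc_min) stop("fc_max must be >= fc_min", call. = FALSE)
  sigma_ind <- check_num(sigma_ind, "sigma_ind")
  if (sigma_ind < 0) stop("sigma_ind must be >= 0", call. = FALSE)
  nb_dispersion <- check_num(nb_dispersion, "nb_dispersion")
  if (nb_dispersion < 0) stop("nb_dispersion must be >= 0", call. = FALSE)
  grand_mean_log_sd <- check_num(grand_mean_log_sd, "grand_mean_log_sd")
  if (grand_mean_log_sd < 0) stop("grand_mean_log_sd must be >= 0", call. = FALSE)
  if (!is.numeric(master_seed) || length(master_seed) != 1L || is.na(master_seed) ||
      master_seed < 0 || master_seed != round(master_seed))
    stop("master_seed must be a non-negative integer", call. = FALSE)

  structure(list(
    n_genes = n_genes,
    prop_de = prop_de,
    n_cases = n_cases,
    n_controls = n_controls,
    cells_per_individual_case = cells_per_individual_case,
    cells_per_individual_control = cells_per_individual_control,
    fc_min = fc_min,
    fc_max = fc_max,
    fc_log_uniform = isTRUE(fc_log_uniform),
    grand_mean_log_mu = check_num(grand_mean_log_mu, "grand_mean_log_mu"),
    grand_mean_log_sd = grand_mean_log_sd,
    sigma_ind = sigma_ind,
    nb_dispersion = nb_dispersion,
    dropout_intercept = check_num(dropout_intercept, "dropout_intercept"),
    dropout_slope = check_num(dropout_slope, "dropout_slope"),
    master_seed = as.integer(master_seed)
  ), class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Hierarchical scRNA-seq simulation parameters\n")
  cat(sprintf("  %d genes (%.1f%% DE, |fc| in [%g, %g]%s)\n",
              x$n_genes, 100 * x$prop_de, x$fc_min, x$fc_max,
              if (x$fc_log_uniform) ", log-uniform" else ""))
  cat(sprintf("  %d cases x %d cells, %d controls x %d cells\n",
              x$n_cases, x$cells_per_individual_case,
              x$n_controls, x$cells_per_individual_control))
  cat(sprintf("  baseline: LogNormal(%g, %g); sigma_ind = %g; NB dispersion = %g\n",
              x$grand_mean_log_mu, x$grand_mean_log_sd, x$sigma_ind,
              x$nb_dispersion))
  cat(sprintf("  dropout: logit^-1(%g - %g log m); master seed %d\n",
              x$dropout_intercept, x$dropout_slope, x$master_seed))
  invisible(x)
}

# Individual- and cell-level layout implied by a sim_params object.
make_design <- function(params) {
  individual_id <- c(sprintf("case_%03d", seq_len(params$n_cases)),
                     sprintf("ctrl_%03d", seq_len(params$n_controls)))
  group <- rep(c("case", "control"), c(params$n_cases, params$n_controls))
  n_cells <- rep(c(params$cells_per_individual_case,
                   params$cells_per_individual_control),
                 c(params$n_cases, params$n_controls))
  individuals <- data.frame(individual_id = individual_id, group = group,
                            n_cells = n_cells, stringsAsFactors = FALSE)
  cells <- data.frame(
    cell_id = sprintf("cell_%06d", seq_len(sum(n_cells))),
    individual_id = rep(individual_id, n_cells),
    group = rep(group, n_cells),
    stringsAsFactors = FALSE
  )
  list(individuals = individuals, cells = cells)
}
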