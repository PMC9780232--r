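# Factorial benchmark orchestration: grid over individuals x cells with
# repeated runs, the imbalanced-cells variant, and the pooled-ROC study over
# DE-gene proportions. One dataset is simulated per iteration and passed to
# every method; iteration seeds are pre-derived from the master seed so the
# output is independent of execution order.

#' Specification of a benchmark grid
#'
#' @param individuals_levels Per-group numbers of individuals (the default
#'   spans 5-40).
#' @param cells_levels Cells per individual at each grid level (default spans
#'   50-500). Each element may also be a length-2 vector
#'   `c(case, control)` for an imbalanced level.
#' @param runs_per_cell Simulated datasets per grid point.
#' @param prop_de Proportion of DE genes in each dataset.
#' @param alpha P-value threshold for the confusion-matrix metrics.
#' @param roster Methods to run, a subset of [de_method_roster()].
#' @param params Base [sim_params()]; the design fields and seed are
#'   overridden per iteration.
#' @param master_seed Seed from which all iteration seeds are derived.
#' @param normalize CPM-normalize pseudobulk matrices before testing.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(individuals_levels = c(5, 10, 20, 30, 40),
                      cells_levels = c(50, 100, 250, 500),
                      runs_per_cell = 50L,
                      prop_de = 0.1,
                      alpha = 0.05,
                      roster = de_method_roster(),
                      params = sim_params(),
                      master_seed = 1L,
                      normalize = FALSE) {
  if (!is.list(cells_levels)) cells_levels <- as.list(cells_levels)
  stopifnot(length(individuals_levels) >= 1, all(individuals_levels >= 2),
            length(cells_levels) >= 1,
            all(vapply(cells_levels, function(x)
              length(x) %in% 1:2 && all(x >= 1), logical(1))),
            runs_per_cell >= 1,
            prop_de >= 0, prop_de <= 1,
            alpha > 0, alpha < 1,
            length(roster) >= 1,
            inherits(params, "sim_params"))
  unknown <- setdiff(roster, de_method_roster())
  if (length(unknown) > 0)
    stop("unknown method name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  structure(list(
    individuals_levels = as.integer(individuals_levels),
    cells_levels = lapply(cells_levels, as.integer),
    runs_per_cell = as.integer(runs_per_cell),
    prop_de = prop_de, alpha = alpha, roster = roster,
    params = params, master_seed = as.integer(master_seed),
    normalize = isTRUE(normalize)
  ), class = "grid_spec")
}

#' Run the full benchmark grid
#'
#' For each (individuals, cells, run) iteration: derive the iteration seed,
#' simulate one dataset, run every roster method on that same dataset, and
#' score each against the ground truth at `spec$alpha`. A method that errors
#' on a whole iteration yields a row of missing metrics with the cause in the
#' `note` column, never a silently dropped row.
#'
#' @param spec A [grid_spec()].
#' @return A tibble with one row per (grid point, run, method): columns
#'   `n_individuals`, `n_cells_case`, `n_cells_control`, `run`, `method`,
#'   `mcc`, `type1`, `sensitivity`, `n_failed`, `seed`, `checksum`, `note`.
#' @export
run_grid <- function(spec) {
  stopifnot(inherits(spec, "grid_spec"))
  n_iter <- length(spec$individuals_levels) * length(spec$cells_levels) *
    spec$runs_per_cell
  seeds <- derive_iteration_seeds(spec$master_seed, n_iter)
  rows <- vector("list", n_iter * length(spec$roster))
  idx <- 0L; row_i <- 0L
  for (n_ind in spec$individuals_levels) {
    for (cl in spec$cells_levels) {
      cc <- if (length(cl) == 2L) cl else c(cl, cl)
      for (run in seq_len(spec$runs_per_cell)) {
        idx <- idx + 1L
        p <- spec$params
        p$n_cases <- n_ind; p$n_controls <- n_ind
        p$cells_per_individual_case <- cc[1L]
        p$cells_per_individual_control <- cc[2L]
        p$prop_de <- spec$prop_de
        p$master_seed <- seeds[idx]
        ds <- simulate_dataset(p)
        for (m in spec$roster) {
          row_i <- row_i + 1L
          res <- tryCatch(run_method(ds, m, spec$normalize),
                          error = function(e) e)
          if (inherits(res, "error")) {
            rows[[row_i]] <- tibble::tibble(
              n_individuals = n_ind, n_cells_case = cc[1L],
              n_cells_control = cc[2L], run = run, method = m,
              mcc = NA_real_, type1 = NA_real_, sensitivity = NA_real_,
              n_failed = NA_integer_, seed = seeds[idx],
              checksum = NA_character_, note = conditionMessage(res))
          } else {
            ev <- evaluate_result(res, ds$truth, spec$alpha)
            rows[[row_i]] <- tibble::tibble(
              n_individuals = n_ind, n_cells_case = cc[1L],
              n_cells_control = cc[2L], run = run, method = m,
              mcc = ev$mcc, type1 = ev$type1, sensitivity = ev$sensitivity,
              n_failed = ev$n_failed, seed = seeds[idx],
              checksum = res$dataset_checksum, note = NA_character_)
          }
        }
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Benchmark with an imbalanced number of cells between groups
#'
#' The same pipeline as [run_grid()] with a fixed, unequal pair of
#' cells-per-individual values for case vs control individuals (the balanced
#' pair reduces exactly to the corresponding [run_grid()] point). Run with
#' `normalize = FALSE` (the default spec) to reproduce the conditions under
#' which sum aggregation degrades, and with `normalize = TRUE` to test its
#' recovery under CPM.
#'
#' @param spec A [grid_spec()] whose `params` carry the (typically unequal)
#'   `cells_per_individual_case` / `cells_per_individual_control`; the spec's
#'   `cells_levels` are ignored in favour of that single pair.
#' @return A tibble as from [run_grid()].
#' @export
run_imbalanced_study <- function(spec) {
  stopifnot(inherits(spec, "grid_spec"))
  spec$cells_levels <- list(c(spec$params$cells_per_individual_case,
                              spec$params$cells_per_individual_control))
  run_grid(spec)
}

#' Pooled ROC study over proportions of DE genes
#'
#' For each DE proportion, simulates `runs` datasets at a fixed design
#' (defaults: 20 case + 20 control individuals, 100 cells each), runs the
#' roster, pools each method's p-values (and the matching truth) across runs,
#' and builds one ROC curve per method and proportion, reporting AUC and
#' sensitivity at `target_fpr`.
#'
#' @param prop_de_levels DE-gene proportions (default the study grid
#'   0.05, 0.1, 0.2, 0.3).
#' @param runs Datasets pooled per proportion.
#' @param n_individuals Individuals per group.
#' @param n_cells Cells per individual.
#' @param params Base [sim_params()] (noise model and gene complement).
#' @param roster Methods to run.
#' @param target_fpr FPR at which sensitivity is interpolated.
#' @param master_seed Seed for the study.
#' @param normalize CPM-normalize pseudobulk before testing.
#' @param method_overrides Named list of functions `f(ds) -> de_result` that
#'   replace the named roster entries (a plumbing hook for injecting synthetic
#'   p-values in tests).
#' @return A list with `summary` (tibble: prop_de, method, auc,
#'   sensitivity, n_pooled) and `curves` (nested list,
#'   `curves[[as.character(prop_de)]][[method]]` a `roc_curve`).
#' @export
run_roc_study <- function(prop_de_levels = c(0.05, 0.1, 0.2, 0.3),
                          runs = 50L,
                          n_individuals = 20L,
                          n_cells = 100L,
                          params = sim_params(),
                          roster = de_method_roster(),
                          target_fpr = 0.05,
                          master_seed = 1L,
                          normalize = FALSE,
                          method_overrides = list()) {
  stopifnot(all(prop_de_levels > 0), all(prop_de_levels <= 1), runs >= 1)
  bad <- setdiff(setdiff(roster, de_method_roster()), names(method_overrides))
  if (length(bad) > 0)
    stop("unknown method name(s): ", paste(bad, collapse = ", "), call. = FALSE)
  seeds <- derive_iteration_seeds(master_seed, length(prop_de_levels) * runs)
  curves <- list()
  rows <- list()
  idx <- 0L
  for (lev in prop_de_levels) {
    pooled_p <- stats::setNames(vector("list", length(roster)), roster)
    pooled_truth <- logical(0)
    for (run in seq_len(runs)) {
      idx <- idx + 1L
      p <- params
      p$n_cases <- n_individuals; p$n_controls <- n_individuals
      p$cells_per_individual_case <- n_cells
      p$cells_per_individual_control <- n_cells
      p$prop_de <- lev
      p$master_seed <- seeds[idx]
      ds <- simulate_dataset(p)
      pooled_truth <- c(pooled_truth, ds$truth$is_de)
      for (m in roster) {
        res <- if (!is.null(method_overrides[[m]])) method_overrides[[m]](ds)
               else run_method(ds, m, normalize)
        pooled_p[[m]] <- c(pooled_p[[m]], res$p_values)
      }
    }
    lev_curves <- list()
    for (m in roster) {
      cv <- roc_curve(pooled_p[[m]], pooled_truth)
      lev_curves[[m]] <- cv
      rows[[length(rows) + 1L]] <- tibble::tibble(
        prop_de = lev, method = m, auc = cv$auc,
        sensitivity = sensitivity_at_fpr(cv, target_fpr),
        n_pooled = length(pooled_truth))
    }
    curves[[as.character(lev)]] <- lev_curves
  }
  list(summary = dplyr::bind_rows(rows), curves = curves)
}

#' Summarize a benchmark table
#'
#' Per (method, grid point): the mean and Monte-Carlo standard error of each
#' metric over runs, plus the count of runs and a flag for method/grid cells
#' whose metrics are all missing (kept, never dropped).
#'
#' @param table A tibble from [run_grid()] / [run_imbalanced_study()].
#' @return A tibble with one row per (method, n_individuals, n_cells_case,
#'   n_cells_control).
#' @export
summarize_benchmark <- function(table) {
  stopifnot(nrow(table) > 0)
  se <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) <= 1) return(NA_real_)
    stats::sd(x) / sqrt(length(x))
  }
  table |>
    dplyr::group_by(.data$method, .data$n_individuals, .data$n_cells_case,
                    .data$n_cells_control) |>
    dplyr::summarise(
      n_runs = dplyr::n(),
      mcc_mean = mean(.data$mcc, na.rm = TRUE),
      mcc_se = se(.data$mcc),
      type1_mean = mean(.data$type1, na.rm = TRUE),
      type1_se = se(.data$type1),
      sensitivity_mean = mean(.data$sensitivity, na.rm = TRUE),
      sensitivity_se = se(.data$sensitivity),
      n_failed_mean = mean(.data$n_failed, na.rm = TRUE),
      all_missing = all(is.na(.data$mcc)),
      .groups = "drop"
    )
}
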