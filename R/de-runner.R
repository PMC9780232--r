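#' The fixed roster of differential-expression methods
#'
#' Three families: pseudobulk aggregation tested at the individual level
#' (`"Pseudobulk: Mean"`, `"Pseudobulk: Sum"`), pseudoreplication tests that
#' take cells as independent replicates (`"Modified t"`, `"Tobit"`,
#' `"Two-part hurdle: Default"`, `"Two-part hurdle: Corrected"`), and the
#' cluster-aware `"GEE1"`.
#'
#' @return Character vector of method names.
#' @export
de_method_roster <- function() {
  c("Pseudobulk: Mean", "Pseudobulk: Sum",
    "Modified t", "Tobit",
    "Two-part hurdle: Default", "Two-part hurdle: Corrected",
    "GEE1")
}

run_method <- function(ds, name, normalize = FALSE) {
  switch(name,
    "Pseudobulk: Mean" = {
      pb <- aggregate_pseudobulk(ds, "mean")
      if (normalize) pb <- normalize_cpm(pb)
      test_pseudobulk(pb)
    },
    "Pseudobulk: Sum" = {
      pb <- aggregate_pseudobulk(ds, "sum")
      if (normalize) pb <- normalize_cpm(pb)
      test_pseudobulk(pb)
    },
    "Modified t" = test_modified_t(ds),
    "Tobit" = test_tobit(ds),
    "Two-part hurdle: Default" = test_two_part_hurdle(ds, corrected = FALSE),
    "Two-part hurdle: Corrected" = test_two_part_hurdle(ds, corrected = TRUE),
    "GEE1" = test_gee1(ds),
    stop("unknown method name: ", name, call. = FALSE)
  )
}

#' Run a roster of DE methods on one dataset
#'
#' Every method consumes the identical counts matrix (each `de_result` records
#' the dataset checksum so this can be asserted) and methods share no mutable
#' state, so execution order is irrelevant.
#'
#' @param ds A `sim_dataset`.
#' @param roster Method names, a subset of [de_method_roster()].
#' @param normalize CPM-normalize pseudobulk matrices before testing
#'   (default `FALSE`, matching a simulator with no library-size variation).
#' @return Named list of `de_result`, in roster order.
#' @examples
#' ds <- simulate_dataset(sim_params(n_genes = 30, n_cases = 3, n_controls = 3,
#'   cells_per_individual_case = 10, cells_per_individual_control = 10,
#'   master_seed = 5))
#' res <- run_all_methods(ds, c("Pseudobulk: Mean", "Modified t"))
#' names(res)
#' @export
run_all_methods <- function(ds, roster = de_method_roster(), normalize = FALSE) {
  stopifnot(inherits(ds, "sim_dataset"), length(roster) >= 1)
  unknown <- setdiff(roster, de_method_roster())
  if (length(unknown) > 0)
    stop("unknown method name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  out <- lapply(roster, function(name) run_method(ds, name, normalize))
  names(out) <- roster
  out
}
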