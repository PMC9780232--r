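# DE method layer: aggregation arithmetic, the three test families, and the
# shared-dataset contract.

test_that("pseudobulk aggregation arithmetic is exact", {
  counts <- matrix(c(2L, 3L, 5L), nrow = 1)
  ds <- manual_dataset(counts, rep("ind_1", 3),
                       c(ind_1 = "case"))
  expect_equal(aggregate_pseudobulk(ds, "sum")$values[1, 1], 10)
  expect_equal(aggregate_pseudobulk(ds, "mean")$values[1, 1], 10 / 3)
})

test_that("sum equals n times mean under a balanced design", {
  ds <- simulate_dataset(small_params())
  s <- aggregate_pseudobulk(ds, "sum")$values
  m <- aggregate_pseudobulk(ds, "mean")$values
  expect_equal(s, 20 * m)
})

test_that("an individual with zero cells is a structural error", {
  ds <- mirrored_dataset()
  ds$individual_group <- c(ds$individual_group, orphan = "case")
  expect_error(aggregate_pseudobulk(ds, "sum"), "at least one cell")
})

test_that("CPM normalization scales columns to a million and is idempotent", {
  ds <- manual_dataset(matrix(c(1L, 3L), nrow = 2), "ind_1", c(ind_1 = "case"))
  pb <- aggregate_pseudobulk(ds, "sum")
  cpm <- normalize_cpm(pb)
  expect_equal(unname(cpm$values[, 1]), c(250000, 750000))
  expect_true(cpm$normalized)
  expect_equal(normalize_cpm(cpm)$values, cpm$values, tolerance = 1e-12)

  # proportional columns become identical
  ds2 <- manual_dataset(matrix(c(1L, 3L, 10L, 30L), nrow = 2),
                        c("a", "b"), c(a = "case", b = "control"))
  cpm2 <- normalize_cpm(aggregate_pseudobulk(ds2, "sum"))
  expect_equal(cpm2$values[, 1], cpm2$values[, 2], ignore_attr = TRUE)

  # all-zero column is a structural error
  ds3 <- manual_dataset(matrix(c(0L, 0L, 1L, 2L), nrow = 2),
                        c("a", "b"), c(a = "case", b = "control"))
  expect_error(normalize_cpm(aggregate_pseudobulk(ds3, "sum")), "non-positive")
})

test_that("CPM-normalized sum and mean aggregation coincide exactly, even imbalanced", {
  ds <- simulate_dataset(small_params(cells_per_individual_case = 30L,
                                      cells_per_individual_control = 10L))
  a <- normalize_cpm(aggregate_pseudobulk(ds, "sum"))$values
  b <- normalize_cpm(aggregate_pseudobulk(ds, "mean"))$values
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("pseudobulk Welch test matches stats::t.test and handles degeneracy", {
  # printed example: case pseudobulk [8,9,10], control [1,2,3]
  ds <- manual_dataset(
    matrix(c(8L, 9L, 10L, 1L, 2L, 3L), nrow = 1),
    c("c1", "c2", "c3", "k1", "k2", "k3"),
    c(c1 = "case", c2 = "case", c3 = "case",
      k1 = "control", k2 = "control", k3 = "control"))
  res <- test_pseudobulk(aggregate_pseudobulk(ds, "mean"))
  oracle <- t.test(log2(c(8, 9, 10) + 1), log2(c(1, 2, 3) + 1))
  expect_equal(res$p_values[1], oracle$p.value, tolerance = 1e-10)
  expect_equal(res$effect_estimates[1],
               mean(log2(c(8, 9, 10) + 1)) - mean(log2(c(1, 2, 3) + 1)))

  # identical case and control pseudobulk vectors: p = 1 everywhere
  res_null <- test_pseudobulk(aggregate_pseudobulk(mirrored_dataset(), "mean"))
  expect_true(all(res_null$p_values == 1))
})

test_that("pseudobulk mean is calibrated on null-only hierarchical data", {
  pool <- c()
  for (s in 1:5) {
    ds <- simulate_dataset(small_params(
      n_genes = 2000L, prop_de = 0, n_cases = 20L, n_controls = 20L,
      cells_per_individual_case = 30L, cells_per_individual_control = 30L,
      master_seed = 100L + s))
    pool <- c(pool, test_pseudobulk(aggregate_pseudobulk(ds, "mean"))$p_values)
  }
  rate <- type1_error(pool, 0.05)
  slack <- 3 * sqrt(0.05 * 0.95 / length(pool))
  expect_lt(abs(rate - 0.05), slack)
})

test_that("modified t coincides with mean pseudobulk at one cell per individual", {
  ds <- simulate_dataset(small_params(
    n_genes = 50L, n_cases = 10L, n_controls = 10L,
    cells_per_individual_case = 1L, cells_per_individual_control = 1L))
  mt <- test_modified_t(ds)
  pb <- test_pseudobulk(aggregate_pseudobulk(ds, "mean"))
  expect_equal(mt$p_values, pb$p_values, tolerance = 1e-12)

  expect_true(all(test_modified_t(mirrored_dataset())$p_values == 1))
})

test_that("Tobit equals the Gaussian-MLE Wald test when censoring is inactive", {
  set.seed(8)
  counts <- matrix(rpois(30 * 40, 30) + 1L, 30, 40)  # strictly positive
  inds <- paste0("i", rep(1:8, each = 5))
  grp <- setNames(rep(c("case", "control"), each = 4), paste0("i", 1:8))
  ds <- manual_dataset(counts, inds, grp)
  tb <- test_tobit(ds)
  g01 <- as.numeric(unname(grp[inds]) == "case")
  oracle <- vapply(1:30, function(i) {
    y <- log2(counts[i, ] + 1)
    fit <- lm(y ~ g01)
    s2 <- sum(resid(fit)^2) / length(y)       # Gaussian MLE variance
    se <- sqrt(s2 * solve(crossprod(cbind(1, g01)))[2, 2])
    2 * pnorm(-abs(coef(fit)[2] / se))
  }, numeric(1))
  expect_equal(tb$p_values, oracle, tolerance = 1e-6)
  expect_identical(tb$n_failed, 0L)
})

test_that("Tobit reports degenerate and symmetric genes correctly", {
  ds <- mirrored_dataset(n_genes = 10, seed = 3)
  ds$counts[1, ] <- 0L                        # all-zero gene
  tb <- test_tobit(ds)
  expect_true(is.na(tb$p_values[1]))
  expect_gte(tb$n_failed, 1L)
  # mirrored counts with some zeros: group effect ~ 0
  expect_true(all(tb$p_values[-1] > 0.5, na.rm = TRUE))
})

test_that("hurdle df bookkeeping: all-detected gene reduces to the continuous part", {
  set.seed(14)
  counts <- matrix(rpois(5 * 60, 20) + 1L, 5, 60)   # detected everywhere
  inds <- paste0("i", rep(1:6, each = 10))
  grp <- setNames(rep(c("case", "control"), each = 3), paste0("i", 1:6))
  ds <- manual_dataset(counts, inds, grp)
  res <- test_two_part_hurdle(ds, corrected = FALSE)
  g01 <- as.numeric(unname(grp[inds]) == "case")
  oracle <- vapply(1:5, function(i) {
    y <- log2(counts[i, ])
    n <- length(y)
    rss0 <- sum(resid(lm(y ~ 1))^2)
    rss1 <- sum(resid(lm(y ~ g01))^2)
    pchisq(n * log(rss0 / rss1), df = 1, lower.tail = FALSE)
  }, numeric(1))
  expect_equal(res$p_values, oracle, tolerance = 1e-8)
})

test_that("hurdle handles symmetric, missing and corrected cases", {
  ds <- mirrored_dataset(n_genes = 15, seed = 5)
  ds$counts[1, ] <- 0L                       # never detected
  res <- test_two_part_hurdle(ds)
  expect_true(is.na(res$p_values[1]))
  expect_true(all(res$p_values[-1] > 0.5, na.rm = TRUE))

  resc <- test_two_part_hurdle(ds, corrected = TRUE)
  expect_identical(resc$method_name, "Two-part hurdle: Corrected")
  ok <- !is.na(resc$p_values)
  expect_true(all(resc$p_values[ok] >= 0 & resc$p_values[ok] <= 1))
})

test_that("GEE1 reduces to HC0-robust OLS with clusters of size one", {
  ds <- simulate_dataset(small_params(
    n_genes = 25L, prop_de = 0.2, n_cases = 15L, n_controls = 15L,
    cells_per_individual_case = 1L, cells_per_individual_control = 1L,
    master_seed = 3L))
  g <- test_gee1(ds)
  grp <- as.numeric(unname(ds$individual_group[ds$cell_individual]) == "case")
  oracle <- vapply(seq_len(25), function(i) {
    y <- log2(ds$counts[i, ] + 1)
    if (var(y) == 0) return(NA_real_)
    fit <- lm(y ~ grp)
    v <- sandwich::vcovHC(fit, type = "HC0")
    2 * pnorm(-abs(coef(fit)[2] / sqrt(v[2, 2])))
  }, numeric(1))
  ok <- !is.na(oracle)
  expect_equal(g$p_values[ok], oracle[ok], tolerance = 1e-6)
  # degenerate genes get the no-evidence verdict, not a failure
  expect_true(all(g$p_values[!ok] == 1))

  expect_true(all(test_gee1(mirrored_dataset())$p_values > 0.99))
})

test_that("null type-1 error orders pseudobulk <= GEE1 < modified t under clustering", {
  rates <- setNames(c(0, 0, 0), c("Pseudobulk: Mean", "GEE1", "Modified t"))
  n <- 0
  for (s in 1:3) {
    ds <- simulate_dataset(small_params(
      n_genes = 300L, prop_de = 0, n_cases = 20L, n_controls = 20L,
      cells_per_individual_case = 100L, cells_per_individual_control = 100L,
      master_seed = 200L + s))
    res <- run_all_methods(ds, c("Pseudobulk: Mean", "GEE1", "Modified t"))
    rates <- rates + vapply(res, function(r) sum(r$p_values <= 0.05, na.rm = TRUE),
                            numeric(1))
    n <- n + 300
  }
  rates <- rates / n
  expect_lt(rates[["Modified t"]] - rates[["GEE1"]], 1)  # sanity on names
  expect_lt(rates[["GEE1"]], rates[["Modified t"]])
  # pseudobulk at or below the cluster-aware test, small Monte-Carlo slack
  expect_lte(rates[["Pseudobulk: Mean"]], rates[["GEE1"]] + 0.02)
})

test_that("run_all_methods is deterministic, order-independent and checksum-consistent", {
  ds <- simulate_dataset(small_params(n_genes = 40L))
  roster <- c("Pseudobulk: Mean", "Pseudobulk: Sum", "Modified t", "GEE1")
  a <- run_all_methods(ds, roster)
  b <- run_all_methods(ds, roster)
  expect_identical(lapply(a, `[[`, "p_values"), lapply(b, `[[`, "p_values"))

  perm <- run_all_methods(ds, rev(roster))
  for (m in roster) expect_identical(perm[[m]]$p_values, a[[m]]$p_values)

  sums <- vapply(a, `[[`, character(1), "dataset_checksum")
  expect_length(unique(sums), 1L)
  expect_identical(unname(sums[1]), dataset_checksum(ds))

  single <- run_all_methods(ds, "Pseudobulk: Mean")
  expect_length(single, 1L)
  expect_error(run_all_methods(ds, "DESeq2"), "unknown method")
})
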