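# Pseudoreplication tests: cells treated as independent replicates.

cell_groups <- function(ds) {
  grp <- unname(ds$individual_group[ds$cell_individual])
  list(case = which(grp == "case"), control = which(grp == "control"),
       grp01 = as.numeric(grp == "case"))
}

#' Cell-level Welch t-test ("Modified t")
#'
#' Per gene, a Welch two-sample t-test on `log2(count + 1)` across cells,
#' case vs control, ignoring the nesting of cells within individuals. The
#' canonical pseudoreplication baseline: with donor-level variation its type-1
#' error inflates, increasingly so with more cells per individual.
#'
#' @param ds A `sim_dataset` with at least two cells per group.
#' @return A `de_result` named `"Modified t"`.
#' @export
test_modified_t <- function(ds) {
  cg <- cell_groups(ds)
  if (length(cg$case) < 2 || length(cg$control) < 2)
    stop("need at least two cells per group", call. = FALSE)
  w <- welch_rows(log2(ds$counts + 1), cg$case, cg$control)
  de_result("Modified t", w$p, w$effect, dataset_checksum(ds$counts))
}

#' Cell-level Tobit regression
#'
#' Per gene, a maximum-likelihood Gaussian regression of `log2(count + 1)` on
#' the group indicator with left-censoring at 0 (zeros treated as censored
#' observations), cells as units; two-sided Wald test on the group
#' coefficient. Genes whose likelihood is degenerate (e.g. all counts zero) or
#' whose fit fails get a missing p-value, tallied in `n_failed`.
#'
#' @param ds A `sim_dataset` with at least two cells per group.
#' @return A `de_result` named `"Tobit"`.
#' @export
test_tobit <- function(ds) {
  cg <- cell_groups(ds)
  if (length(cg$case) < 2 || length(cg$control) < 2)
    stop("need at least two cells per group", call. = FALSE)
  n_genes <- nrow(ds$counts)
  grp <- cg$grp01
  p <- rep(NA_real_, n_genes)
  eff <- rep(NA_real_, n_genes)
  for (g in seq_len(n_genes)) {
    y <- log2(ds$counts[g, ] + 1)
    if (all(y == 0)) next
    fit <- tryCatch(
      suppressWarnings(survival::survreg(
        survival::Surv(y, y > 0, type = "left") ~ grp,
        dist = "gaussian",
        control = survival::survreg.control(maxiter = 100))),
      error = function(e) NULL)
    if (is.null(fit) || length(fit$coefficients) < 2L) next
    b <- unname(fit$coefficients[2L])
    v <- fit$var[2L, 2L]
    if (!is.finite(b) || !is.finite(v) || v <= 0) next
    p[g] <- 2 * stats::pnorm(-abs(b) / sqrt(v))
    eff[g] <- b
  }
  de_result("Tobit", p, eff, dataset_checksum(ds$counts))
}

#' Cell-level two-part hurdle test
#'
#' Per gene, two components fitted over cells:
#' a logistic regression of detection (count > 0) on group, and a linear
#' regression of `log2(count)` on group among detected cells. Each part
#' contributes a likelihood-ratio chi-square on 1 df; a degenerate part
#' (detection constant, or too few/one-group detected cells) contributes 0 df
#' and the combined statistic is referred to a chi-square with the remaining
#' df. With `corrected = TRUE` the cellular detection rate (fraction of genes
#' detected in each cell) enters both parts as a covariate.
#'
#' Genes detected in no cell get a missing p-value; genes where both parts are
#' degenerate but the gene is detected get p = 1.
#'
#' @param ds A `sim_dataset` with at least two cells per group.
#' @param corrected Add the cellular detection-rate covariate.
#' @return A `de_result` named `"Two-part hurdle: Default"` or
#'   `"Two-part hurdle: Corrected"`.
#' @export
test_two_part_hurdle <- function(ds, corrected = FALSE) {
  cg <- cell_groups(ds)
  if (length(cg$case) < 2 || length(cg$control) < 2)
    stop("need at least two cells per group", call. = FALSE)
  n_genes <- nrow(ds$counts)
  grp <- cg$grp01
  detected_mat <- ds$counts > 0
  cdr <- colMeans(detected_mat)
  p <- rep(NA_real_, n_genes)
  eff <- rep(NA_real_, n_genes)

  for (g in seq_len(n_genes)) {
    cnt <- ds$counts[g, ]
    d <- detected_mat[g, ]
    if (!any(d)) next
    chisq <- 0; df <- 0L

    # Detection part: LRT for group, skipped when detection is constant.
    if (!all(d)) {
      fit0 <- tryCatch(suppressWarnings(
        if (corrected) stats::glm(d ~ cdr, family = stats::binomial())
        else stats::glm(d ~ 1, family = stats::binomial())),
        error = function(e) NULL)
      fit1 <- tryCatch(suppressWarnings(
        if (corrected) stats::glm(d ~ cdr + grp, family = stats::binomial())
        else stats::glm(d ~ grp, family = stats::binomial())),
        error = function(e) NULL)
      if (!is.null(fit0) && !is.null(fit1)) {
        chisq <- chisq + max(fit0$deviance - fit1$deviance, 0)
        df <- df + 1L
      }
    }

    # Continuous part among detected cells.
    dg <- grp[d]
    if (sum(d) >= 3L && length(unique(dg)) == 2L) {
      y <- log2(cnt[d])
      n <- length(y)
      X0 <- if (corrected) cbind(1, cdr[d]) else matrix(1, n, 1L)
      X1 <- cbind(X0, dg)
      rss0 <- sum(stats::.lm.fit(X0, y)$residuals^2)
      f1 <- stats::.lm.fit(X1, y)
      rss1 <- sum(f1$residuals^2)
      if (rss0 > 0) {
        if (rss1 <= 0) {
          chisq <- Inf
        } else {
          chisq <- chisq + max(n * (log(rss0) - log(rss1)), 0)
        }
        df <- df + 1L
        eff[g] <- f1$coefficients[ncol(X1)]
      }
    }

    p[g] <- if (df == 0L) 1 else
      stats::pchisq(chisq, df, lower.tail = FALSE)
  }
  de_result(paste0("Two-part hurdle: ", if (corrected) "Corrected" else "Default"),
            p, eff, dataset_checksum(ds$counts))
}
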