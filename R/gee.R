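# Cluster-aware GEE1. No GEE package ships with this stack, and for a
# cluster-constant binary covariate the Gaussian/identity/exchangeable GEE has
# a closed-form GLS step in the cluster sums, so the estimating equations are
# solved directly — vectorised over all genes at once.
#
# For cluster i with n_i cells, working covariance sigma^2[(1-rho)I + rho J]
# gives X_i' V_i^-1 X_i = w_i [1, x_i; x_i, x_i^2] with cluster weight
# w_i = n_i / (sigma^2 (1 + (n_i - 1) rho)), and X_i' V_i^-1 y_i =
# k_i S_i [1; x_i] with k_i = 1 / (sigma^2 (1 + (n_i - 1) rho)) and S_i the
# cluster sum of y. The sigma^2 factor cancels between bread and meat of the
# sandwich, so it is dropped throughout.

#' Cluster-aware GEE test (exchangeable working correlation)
#'
#' Per gene, Gaussian generalized estimating equations of `log2(count + 1)` on
#' the group indicator with identity link, exchangeable working correlation
#' and individuals as clusters; two-sided Wald test of the group coefficient
#' using the robust (sandwich) variance. With all clusters of size one the
#' estimate reduces to OLS with HC0 robust standard errors.
#'
#' The working correlation is re-estimated from Pearson residuals by the
#' moment estimator at each iteration; genes whose iteration fails to converge
#' or yields a non-finite variance get a missing p-value, tallied in
#' `n_failed`. Genes with zero residual variance get p = 1 when the group
#' means agree and p = 0 otherwise.
#'
#' @param ds A `sim_dataset` with at least two individuals per group and at
#'   least one cell per individual.
#' @param max_iter,tol Iteration cap and convergence tolerance on the
#'   coefficient update.
#' @return A `de_result` named `"GEE1"`.
#' @export
test_gee1 <- function(ds, max_iter = 25L, tol = 1e-8) {
  ind_ids <- names(ds$individual_group)
  x_i <- as.numeric(ds$individual_group == "case")
  if (sum(x_i == 1) < 2 || sum(x_i == 0) < 2)
    stop("need at least two individuals per group", call. = FALSE)
  f <- factor(ds$cell_individual, levels = ind_ids)
  n_i <- as.vector(table(f))
  if (any(n_i == 0))
    stop("every individual must have at least one cell", call. = FALSE)

  Y <- log2(ds$counts + 1)
  n_genes <- nrow(Y)
  N <- ncol(Y)
  n_ind <- length(ind_ids)
  x_cell <- x_i[as.integer(f)]

  # cells x individuals indicator for cluster sums
  M <- Matrix::sparseMatrix(i = seq_len(N), j = as.integer(f), x = 1,
                            dims = c(N, n_ind))
  Sy <- as.matrix(Y %*% M)              # genes x individuals sums of y
  n_pairs <- sum(n_i * (n_i - 1)) / 2
  max_ni <- max(n_i)

  # start from OLS (rho = 0)
  beta0 <- rep(0, n_genes); beta1 <- rep(0, n_genes)
  mx <- mean(x_cell)
  ym <- rowMeans(Y)
  sxx <- sum((x_cell - mx)^2)
  beta1 <- as.vector(Y %*% (x_cell - mx)) / sxx
  beta0 <- ym - beta1 * mx

  rho <- rep(0, n_genes)
  for (iter in seq_len(max_iter)) {
    # residual cluster sums and sums of squares
    fitted_shift <- outer(beta1, x_cell)        # genes x cells, + beta0 below
    R_sums <- Sy - (outer(beta1, x_i * n_i) + beta0 * matrix(rep(n_i, each = n_genes), n_genes))
    ss_tot <- rowSums((Y - fitted_shift - beta0)^2)
    sigma2 <- ss_tot / pmax(N - 2, 1)

    # within-cluster residual sums of squares per gene
    Rsq_by_cluster <- as.matrix((Y - fitted_shift - beta0)^2 %*% M)
    cross <- (rowSums(R_sums^2) - rowSums(Rsq_by_cluster)) / 2
    denom <- sigma2 * max(n_pairs - 2, 1)
    rho_new <- ifelse(n_pairs > 0 & sigma2 > 0, cross / denom, 0)
    lo <- if (max_ni > 1) -1 / (max_ni - 1) + 1e-6 else -0.99
    rho <- pmin(pmax(rho_new, max(lo, -0.99)), 0.99)

    # GLS step via cluster sums: k_gi = 1 / (1 + (n_i - 1) rho_g)
    K <- 1 / (1 + outer(rho, n_i - 1))          # genes x individuals
    W <- sweep(K, 2L, n_i, "*")                  # w_gi = n_i k_gi
    A11 <- rowSums(W)
    A12 <- as.vector(W %*% x_i)
    A22 <- A12                                   # x binary: x^2 = x
    B1 <- rowSums(K * Sy)
    B2 <- as.vector((K * Sy) %*% x_i)
    det <- A11 * A22 - A12^2
    new1 <- (A11 * B2 - A12 * B1) / det
    new0 <- (A22 * B1 - A12 * B2) / det
    delta <- pmax(abs(new0 - beta0), abs(new1 - beta1))
    ok <- is.finite(new0) & is.finite(new1)
    beta0[ok] <- new0[ok]; beta1[ok] <- new1[ok]
    if (max(delta[ok], 0) < tol) break
  }

  # sandwich variance of beta1 (sigma^2 dropped consistently from A and meat)
  K <- 1 / (1 + outer(rho, n_i - 1))
  W <- sweep(K, 2L, n_i, "*")
  A11 <- rowSums(W); A12 <- as.vector(W %*% x_i); A22 <- A12
  fitted_shift <- outer(beta1, x_cell)
  R_sums <- Sy - (outer(beta1, x_i * n_i) + beta0 * matrix(rep(n_i, each = n_genes), n_genes))
  U <- K * R_sums                                # u_gi scalar factor
  m11 <- rowSums(U^2)
  m12 <- as.vector(U^2 %*% x_i)
  m22 <- m12
  det <- A11 * A22 - A12^2
  a <- -A12 / det; b <- A11 / det                # second row of A^-1
  V22 <- a^2 * m11 + 2 * a * b * m12 + b^2 * m22

  ss_tot <- rowSums((Y - fitted_shift - beta0)^2)
  degenerate <- ss_tot < 1e-12
  z <- beta1 / sqrt(V22)
  p <- 2 * stats::pnorm(-abs(z))
  if (any(degenerate)) {
    # no residual variation: verdict from the raw group means
    m_case <- rowSums(sweep(Sy, 2L, x_i, "*")) / sum(n_i * x_i)
    m_ctrl <- rowSums(sweep(Sy, 2L, 1 - x_i, "*")) / sum(n_i * (1 - x_i))
    p[degenerate] <- ifelse(m_case[degenerate] == m_ctrl[degenerate], 1, 0)
  }
  bad <- !degenerate & (!is.finite(p) | !is.finite(V22) | V22 <= 0)
  p[bad] <- NA_real_
  eff <- beta1
  eff[bad] <- NA_real_
  de_result("GEE1", p, eff, dataset_checksum(ds$counts))
}
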