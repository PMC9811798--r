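#' Sum test (ST)
#'
#' The burden-type comparator: B = sum(Z_m) referred to N(0, 1'R1).
#' Identical to [burden_test()]; kept under the comparator naming so that
#' method lists read like the simulation tables.
#'
#' @param z numeric vector of Z-scores.
#' @param R LD matrix.
#' @return two-sided p-value.
#' @export
sum_test <- function(z, R) burden_test(z, R)$p.value

#' Squared sum test (S2T)
#'
#' Q = sum(Z_m^2) with the mixture-of-chi-square null (eigenvalues of R);
#' identical to [ssu_test()] without diagonal weights.
#'
#' @inheritParams sum_test
#' @param method tail method passed to [mixture_sf()].
#' @return p-value.
#' @export
squared_sum_test <- function(z, R, method = "liu") {
  ssu_test(z, R, method = method)$p.value
}

#' One-dimensional rho grid of the adaptive test
#'
#' @return the fixed sequence (0, 0.01, 0.04, 0.09, 0.16, 0.25, 0.5, 1).
#' @export
at_grid <- function() c(0, 0.01, 0.04, 0.09, 0.16, 0.25, 0.5, 1)

at_precompute <- function(R, grid = at_grid()) {
  coef <- cbind(grid, 0, 0, 1 - grid)
  colnames(coef) <- paste0("rho", 1:4)
  rownames(coef) <- paste0("rho=", format(grid, trim = TRUE))
  quad_precompute(R, coef)
}

#' Adaptive test (AT): burden/quadratic combination with a 1-D grid
#'
#' Q_rho = (1 - rho) Q + rho B^2 over the fixed [at_grid()]; the statistic
#' is the minimum mixture p-value across the grid, and its overall p-value
#' is estimated by the same Monte Carlo machinery (shared Cholesky null
#' draws, add-one estimator) as the OWC test.
#'
#' @inheritParams sum_test
#' @param grid numeric vector of rho values.
#' @param B number of null Monte Carlo draws.
#' @param seed optional integer seed.
#' @return list with `T` (min p over the grid), `pvalue`, `per_rho_p`.
#' @export
adaptive_test <- function(z, R, grid = at_grid(), B = 1000, seed = NULL) {
  pre <- at_precompute(R, grid)
  obs <- quad_minp(matrix(z, nrow = 1L), pre, return_p = TRUE)
  null_T <- with_seed(seed, null_T_draws(pre, B))
  p <- drop(obs$p)
  names(p) <- rownames(pre$coef)
  list(T = obs$T[1L],
       pvalue = (sum(null_T <= obs$T[1L]) + 1) / (B + 1),
       per_rho_p = p)
}

#' Adaptive sum of powered score tests (aSPU)
#'
#' SPU(gamma) = sum(Z_m^gamma) for finite gamma and max|Z_m| for
#' gamma = Inf.  Per-gamma p-values are computed by pooling the observed
#' vector with B null draws and ranking (two-sided via |SPU| for odd gamma,
#' upper-tailed for even gamma and Inf); the aSPU statistic is the minimum
#' per-gamma p and its p-value the add-one Monte Carlo estimate over the
#' pooled ranks.  Pooling makes the observed and null statistics exactly
#' exchangeable, so the p-value is uniform under the null by construction.
#'
#' @inheritParams sum_test
#' @param gammas powers to combine (default 1..8 and Inf).
#' @param B number of null Monte Carlo draws.
#' @param seed optional integer seed.
#' @return list with `pvalue`, `spu_stat` (named observed statistics) and
#'   `spu_p` (their pooled per-gamma p-values).
#' @export
aspu_test <- function(z, R, gammas = c(1:8, Inf), B = 1000, seed = NULL) {
  stopifnot(B >= 1)
  R <- psd_repair(as_ld_matrix(R))
  M <- length(z)
  stopifnot(M == nrow(R))
  D <- ld_cholesky(R)
  Znull <- with_seed(seed,
    matrix(stats::rnorm(B * M), B, M) %*% t(D))
  Zall <- rbind(matrix(z, nrow = 1L), Znull)   # row 1 = observed

  spu <- function(Zm, g) {
    if (is.infinite(g)) apply(abs(Zm), 1L, max) else rowSums(Zm^g)
  }
  n_all <- B + 1L
  minp <- rep(Inf, n_all)
  spu_stat <- numeric(length(gammas))
  spu_p <- numeric(length(gammas))
  for (k in seq_along(gammas)) {
    g <- gammas[k]
    s <- spu(Zall, g)
    # direction of extremeness: larger is more extreme after transform
    t_ext <- if (is.infinite(g) || g %% 2 == 0) s else abs(s)
    r <- rank(t_ext, ties.method = "min")   # r = #{t < t_i} + 1
    p_g <- (n_all - r + 1) / n_all          # = #{t >= t_i} / n_all
    minp <- pmin(minp, p_g)
    spu_stat[k] <- s[1L]
    spu_p[k] <- p_g[1L]
  }
  names(spu_stat) <- names(spu_p) <-
    paste0("gamma=", ifelse(is.infinite(gammas), "Inf", gammas))
  pvalue <- (sum(minp[-1L] <= minp[1L]) + 1) / (B + 1)
  list(pvalue = pvalue, spu_stat = spu_stat, spu_p = spu_p)
}

#' Effective number of independent tests
#'
#' Eigenvalue-based estimator on the absolute-correlation matrix:
#' m_e = M - sum_(lambda_i > 1) (lambda_i - 1).  Independent SNPs give
#' m_e = M; a fully correlated block gives m_e = 1.
#'
#' @param C correlation matrix (signs are ignored).
#' @return effective number of tests (>= 1).
#' @export
effective_tests <- function(C) {
  C <- abs(as.matrix(C))
  lam <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  max(nrow(C) - sum(pmax(lam - 1, 0)), 1)
}

# Correlation between two-sided p-values induced by genotype correlation r,
# the fitted sixth-degree polynomial of the extended Simes procedure.
pvalue_correlation <- function(r) {
  0.2982 * r^6 - 0.0127 * r^5 + 0.0588 * r^4 + 0.0099 * r^3 +
    0.6281 * r^2 - 0.0009 * r
}

#' Gene-based association test using the extended Simes procedure (GATES)
#'
#' p_GATES = min_j ( m_e p_(j) / m_e(j) ) over the sorted per-SNP p-values,
#' where m_e is the effective number of independent tests among all M SNPs
#' and m_e(j) among the top j.  The SNP correlation matrix is first mapped
#' to the correlation of the two-sided p-values through the procedure's
#' fitted sixth-degree polynomial, and the effective numbers come from the
#' eigenvalue estimator [effective_tests()] on blocks of that matrix; pass
#' a different `me_fun` to swap the estimator.
#'
#' @param pvals numeric vector of per-SNP p-values in (0, 1].
#' @param R LD matrix aligned to `pvals`.
#' @param me_fun function(p-value correlation block) -> effective number.
#' @return GATES p-value in (0, 1].
#' @export
gates_test <- function(pvals, R, me_fun = effective_tests) {
  R <- as_ld_matrix(R)
  M <- length(pvals)
  stopifnot(M == nrow(R))
  if (any(pvals <= 0 | pvals > 1)) stop("p-values must lie in (0, 1]")
  if (M == 1L) return(pvals)
  o <- order(pvals)
  ps <- pvals[o]
  Rp <- pvalue_correlation(unclass(R)[o, o, drop = FALSE])
  diag(Rp) <- 1
  me_all <- me_fun(Rp)
  me_j <- vapply(seq_len(M), function(j)
    me_fun(Rp[seq_len(j), seq_len(j), drop = FALSE]), numeric(1L))
  min(min(me_all * ps / me_j), 1)
}

# Batched GATES for simulation studies: p-value matrix (replicates x M).
# m_e(j) depends only on the unordered set of top-j SNPs, so results are
# cached by bitmask (feasible for the gene sizes this package targets).
gates_batch <- function(Pmat, R) {
  R <- as_ld_matrix(R)
  M <- ncol(Pmat)
  if (M > 30L) stop("gates_batch supports up to 30 SNPs; use gates_test()")
  Rm <- pvalue_correlation(unclass(R))
  diag(Rm) <- 1
  cache <- new.env(hash = TRUE, parent = emptyenv())
  me_of <- function(idx) {
    key <- paste(idx, collapse = ",")
    val <- cache[[key]]
    if (is.null(val)) {
      val <- effective_tests(Rm[idx, idx, drop = FALSE])
      cache[[key]] <- val
    }
    val
  }
  all_idx <- seq_len(M)
  me_all <- me_of(all_idx)
  apply(Pmat, 1L, function(p) {
    o <- order(p)
    ps <- p[o]
    me_j <- numeric(M)
    for (j in all_idx) me_j[j] <- me_of(sort(o[seq_len(j)]))
    min(min(me_all * ps / me_j), 1)
  })
}
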