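#' Weighted-sum-statistic weights from minor allele frequencies
#'
#' w_m = 1 / sqrt(p_m (1 - p_m)), the purifying-selection weighting that
#' up-weights rarer variants.
#'
#' @param maf numeric vector of minor allele frequencies in (0, 0.5].
#' @return numeric vector of strictly positive weights.
#' @export
wss_weights <- function(maf) {
  if (any(!is.finite(maf)) || any(maf <= 0) || any(maf > 0.5))
    stop("MAF must lie in (0, 0.5]")
  1 / sqrt(maf * (1 - maf))
}

#' Burden test from Z-scores
#'
#' The unweighted sum B = sum(Z_m), with null law N(0, 1'R1); the p-value is
#' P(chi^2_1 >= B^2 / 1'R1).  Powerful when effects share one direction,
#' collapses under mixed signs.
#'
#' @param z numeric vector of per-SNP Z-scores.
#' @param R LD matrix aligned to `z`.
#' @return list with `statistic` (B), `variance` (1'R1) and `p.value`.
#' @export
burden_test <- function(z, R) {
  R <- as_ld_matrix(R)
  stopifnot(length(z) == nrow(R))
  v <- sum(unclass(R))
  if (v <= 0) stop("1'R1 <= 0: invalid LD matrix")
  b <- sum(z)
  list(statistic = b, variance = v,
       p.value = stats::pchisq(b^2 / v, df = 1, lower.tail = FALSE))
}

#' MAF-weighted sum statistic (WSS)
#'
#' L_W = sum(w_m Z_m) with w from [wss_weights()]; null variance w'Rw and
#' p-value P(chi^2_1 >= L_W^2 / w'Rw).  Without MAFs the statistic is
#' undefined and an explicit unavailable result is returned rather than
#' silently falling back to equal weights.
#'
#' @param z numeric vector of Z-scores.
#' @param maf minor allele frequencies aligned to `z`, or NULL.
#' @param R LD matrix.
#' @return list with `available`, `statistic`, `variance`, `p.value`.
#' @export
wss_test <- function(z, maf, R) {
  if (is.null(maf) || any(is.na(maf)))
    return(list(available = FALSE, statistic = NA_real_,
                variance = NA_real_, p.value = NA_real_))
  R <- as_ld_matrix(R)
  stopifnot(length(z) == nrow(R), length(maf) == length(z))
  w <- wss_weights(maf)
  v <- drop(t(w) %*% unclass(R) %*% w)
  s <- sum(w * z)
  list(available = TRUE, statistic = s, variance = v,
       p.value = stats::pchisq(s^2 / v, df = 1, lower.tail = FALSE))
}

#' Maximized score test
#'
#' S_S = Z'R^{-1}Z, the supremum of (W'Z)^2 / (W'RW) over weight vectors W,
#' attained at W = R^{-1}Z; chi-square with M degrees of freedom under the
#' null.
#'
#' @param z numeric vector of Z-scores.
#' @param Rinv (regularized) inverse of the gene's LD matrix, from
#'   [ld_inverse()].
#' @return list with `statistic`, `df` and `p.value`.
#' @export
score_test <- function(z, Rinv) {
  Rinv <- as.matrix(Rinv)
  if (length(z) != nrow(Rinv)) stop("z and Rinv are not conformable")
  s <- drop(t(z) %*% Rinv %*% z)
  M <- length(z)
  list(statistic = s, df = M,
       p.value = stats::pchisq(s, df = M, lower.tail = FALSE))
}

#' Sum of squared score test (SSU)
#'
#' S_Q = sum(a_m Z_m^2) with optional non-negative diagonal weights `a`
#' (default all 1).  Under the null the statistic follows the mixture
#' sum_i lambda_i chi^2_1 with lambda the eigenvalues of R diag(a); with
#' beta(1, 25)-density MAF weights this is the SKAT rare-variant statistic,
#' and with expression-derived weights PathSPU(2).
#'
#' @param z numeric vector of Z-scores.
#' @param R LD matrix.
#' @param weights optional non-negative diagonal weights.
#' @param method tail method passed to [mixture_sf()].
#' @return list with `statistic`, `lambda` and `p.value`.
#' @export
ssu_test <- function(z, R, weights = NULL, method = "liu") {
  R <- as_ld_matrix(R)
  M <- length(z)
  stopifnot(M == nrow(R))
  if (is.null(weights)) weights <- rep(1, M)
  if (any(weights < 0)) stop("diagonal weights must be non-negative")
  stopifnot(length(weights) == M)
  s <- sum(weights * z^2)
  # eigenvalues of R diag(a) via the symmetric similarity
  # diag(sqrt(a)) R diag(sqrt(a))
  sq <- sqrt(weights)
  S <- unclass(R) * tcrossprod(sq)
  lam <- sort(pmax(eigen(S, symmetric = TRUE, only.values = TRUE)$values, 0),
              decreasing = TRUE)
  list(statistic = s, lambda = lam,
       p.value = mixture_sf(s, lam, method = method))
}

#' Simplex weights for the combination statistic
#'
#' @param rho1,rho2,rho3,rho4 non-negative weights summing to 1 (to 1e-12).
#' @return numeric vector of length 4 with class `rho_weights`.
#' @export
rho_weights <- function(rho1, rho2, rho3, rho4) {
  r <- c(rho1, rho2, rho3, rho4)
  if (any(r < 0) || any(r > 1)) stop("rho weights must lie in [0, 1]")
  if (abs(sum(r) - 1) > 1e-12) stop("rho weights must sum to 1")
  structure(r, names = paste0("rho", 1:4), class = "rho_weights")
}

#' Combination matrix of the weighted quadratic form
#'
#' A = rho1 11' + rho2 WW' + rho3 R^{-1} + rho4 I, so that Z'AZ equals
#' rho1 L_B^2 + rho2 L_W^2 + rho3 S_S + rho4 S_Q.
#'
#' @param rho a [rho_weights()] vector (or numeric length 4 summing to 1).
#' @param W WSS weight vector (required when `rho2 > 0`), or NULL.
#' @param Rinv inverse LD matrix (required when `rho3 > 0`), or NULL.
#' @param M number of SNPs.
#' @return symmetric M x M matrix with attribute `"rho"`.
#' @export
combination_matrix <- function(rho, W = NULL, Rinv = NULL, M) {
  rho <- rho_weights(rho[1], rho[2], rho[3], rho[4])
  A <- matrix(0, M, M)
  if (rho[1] > 0) A <- A + rho[1]
  if (rho[2] > 0) {
    if (is.null(W)) stop("rho2 > 0 requires WSS weights (MAF column absent?)")
    stopifnot(length(W) == M)
    A <- A + rho[2] * tcrossprod(W)
  }
  if (rho[3] > 0) {
    if (is.null(Rinv)) stop("rho3 > 0 requires the inverse LD matrix")
    A <- A + rho[3] * as.matrix(Rinv)
  }
  A <- A + diag(rho[4], M)
  A <- (A + t(A)) / 2
  attr(A, "rho") <- rho
  A
}

#' Combination quadratic-form statistic
#'
#' L_rho = Z'AZ; algebraically identical to the explicit four-term sum
#' rho1 L_B^2 + rho2 L_W^2 + rho3 S_S + rho4 S_Q.
#'
#' @param z numeric vector of Z-scores.
#' @param A combination matrix from [combination_matrix()].
#' @return scalar statistic value.
#' @export
lrho_statistic <- function(z, A) {
  A <- as.matrix(A)
  stopifnot(length(z) == nrow(A))
  drop(t(z) %*% A %*% z)
}
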