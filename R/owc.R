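#' Simplex grid of combination weights
#'
#' Enumerates every (rho1, rho2, rho3, rho4) with coordinates in
#' {0, step, 2 step, ..., 1} summing to 1, in lexicographic order
#' (rho1 slowest).  With the default step 0.1 the grid has 286 points.
#'
#' @param step grid spacing; `1/step` must be an integer.
#' @return numeric matrix (points x 4) of class `rho_grid` with attribute
#'   `"step"`.
#' @export
rho_grid <- function(step = 0.1) {
  K <- round(1 / step)
  if (abs(K * step - 1) > 1e-9) stop("1/step must be an integer")
  pts <- list()
  n <- 0L
  for (i1 in 0:K) for (i2 in 0:(K - i1)) for (i3 in 0:(K - i1 - i2)) {
    n <- n + 1L
    pts[[n]] <- c(i1, i2, i3, K - i1 - i2 - i3) / K
  }
  g <- do.call(rbind, pts)
  colnames(g) <- paste0("rho", 1:4)
  rownames(g) <- apply(g, 1L, function(r) paste(format(r, trim = TRUE),
                                                collapse = "/"))
  attr(g, "step") <- step
  class(g) <- c("rho_grid", class(g))
  g
}

#' Staged Monte Carlo parameters for the fast adaptive p-value
#'
#' The adaptive estimator starts with `B0` null draws, multiplies the draw
#' count by `mult` each stage, and stops once the p-value estimate clears
#' `p0` or the next stage would exceed `Bmax`.  Early stages reuse their
#' draws, so the final estimate at stage k is based on `B0 * mult^k`
#' cumulative samples.
#'
#' @param B0 initial number of null draws.
#' @param Bmax cap on the cumulative number of draws.
#' @param mult stage multiplier (>= 2).
#' @param p0 non-significance threshold: clearly non-significant genes stop
#'   at the first stage.
#' @return list of validated parameters.
#' @export
fast_mc_params <- function(B0 = 10, Bmax = 1e6, mult = 10, p0 = 1e-5) {
  stopifnot(B0 >= 1, mult >= 2, Bmax >= B0, p0 > 0, p0 < 1)
  k <- log(Bmax / B0) / log(mult)
  if (abs(k - round(k)) > 1e-9)
    stop("Bmax must equal B0 * mult^k for an integer k")
  list(B0 = as.integer(B0), Bmax = Bmax, mult = mult, p0 = p0)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the
# caller's .Random.seed is restored afterwards.  seed = NULL uses (and
# advances) the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# Shared precomputation for a family of quadratic-form statistics
# c1 LB^2 + c2 LW^2 + c3 SS + c4 SQ, one row of `coef` per grid point.
# Everything that depends only on the gene (Cholesky factor, inverse,
# per-point mixture eigenvalues and Liu parameters) is computed once and
# reused across all observed and null evaluations.
quad_precompute <- function(R, coef, maf = NULL, ridge = 0) {
  R <- psd_repair(as_ld_matrix(R))
  M <- nrow(R)
  coef <- as.matrix(coef)
  stopifnot(ncol(coef) == 4L)
  w <- NULL
  if (any(coef[, 2L] > 0)) {
    if (is.null(maf)) stop("coefficients on the WSS component require MAFs")
    w <- wss_weights(maf)
  }
  Rinv <- NULL
  if (any(coef[, 3L] > 0)) Rinv <- ld_inverse(R, ridge = ridge)
  D <- ld_cholesky(R)

  eR <- eigen(unclass(R), symmetric = TRUE)
  Rhalf <- eR$vectors %*% (sqrt(pmax(eR$values, 0)) * t(eR$vectors))
  u <- drop(Rhalf %*% rep(1, M))
  v <- if (!is.null(w)) drop(Rhalf %*% w) else NULL
  K3 <- if (!is.null(Rinv)) Rhalf %*% Rinv %*% Rhalf else NULL

  G <- nrow(coef)
  liu <- vector("list", G)
  lambda <- vector("list", G)
  for (g in seq_len(G)) {
    cf <- coef[g, ]
    Mg <- cf[4L] * unclass(R)
    if (cf[1L] > 0) Mg <- Mg + cf[1L] * tcrossprod(u)
    if (cf[2L] > 0) Mg <- Mg + cf[2L] * tcrossprod(v)
    if (cf[3L] > 0) Mg <- Mg + cf[3L] * K3
    lam <- eigen((Mg + t(Mg)) / 2, symmetric = TRUE, only.values = TRUE)$values
    lam <- sort(pmax(lam, 0), decreasing = TRUE)
    lambda[[g]] <- lam
    liu[[g]] <- liu_params(lam)
  }
  list(R = R, M = M, D = D, Rinv = Rinv, w = w, coef = coef,
       lambda = lambda, liu = liu,
       ridge = if (is.null(Rinv)) 0 else attr(Rinv, "ridge"))
}

# The four base statistics for each row of Zmat.
quad_stats <- function(Zmat, pre) {
  LB2 <- rowSums(Zmat)^2
  LW2 <- if (!is.null(pre$w)) drop(Zmat %*% pre$w)^2 else numeric(nrow(Zmat))
  SS <- if (!is.null(pre$Rinv)) rowSums((Zmat %*% pre$Rinv) * Zmat)
        else numeric(nrow(Zmat))
  SQ <- rowSums(Zmat^2)
  cbind(LB2, LW2, SS, SQ, deparse.level = 0)
}

# Min-p statistic over the grid for each row of Zmat.  Ties keep the first
# grid point in lexicographic order.  return_p = TRUE additionally returns
# the full n x G matrix of per-point p-values (intended for small n).
quad_minp <- function(Zmat, pre, return_p = FALSE) {
  st <- quad_stats(Zmat, pre)
  L <- st %*% t(pre$coef)
  n <- nrow(L)
  G <- ncol(L)
  Tmin <- rep(Inf, n)
  best <- rep(1L, n)
  P <- if (return_p) matrix(NA_real_, n, G) else NULL
  for (g in seq_len(G)) {
    p <- liu_sf(L[, g], pre$liu[[g]])
    if (return_p) P[, g] <- p
    upd <- p < Tmin
    if (any(upd)) {
      Tmin[upd] <- p[upd]
      best[upd] <- g
    }
  }
  list(T = Tmin, best = best, p = P)
}

# Draw B null min-p statistics T^(b) with Z^(b) = D L, in fixed-size chunks
# so the RNG stream consumed is independent of how calls are split.
null_T_draws <- function(pre, B, chunk = 20000L) {
  Tout <- numeric(B)
  done <- 0L
  while (done < B) {
    nb <- as.integer(min(chunk, B - done))
    Z <- matrix(stats::rnorm(nb * pre$M), nb, pre$M) %*% t(pre$D)
    Tout[done + seq_len(nb)] <- quad_minp(Z, pre)$T
    done <- done + nb
  }
  Tout
}

#' Per-gene precomputation for the OWC test
#'
#' Builds, once per gene, everything the grid search reuses across the
#' observed statistic and every Monte Carlo null draw: the Cholesky factor
#' of R, the (regularized) inverse, and for each grid point the mixture
#' eigenvalues and moment-matching parameters of the null law of
#' L_rho = Z'A Z.  Without MAFs, grid points with rho2 > 0 are removed
#' (with a message) because the WSS component is undefined there.
#'
#' @param R LD matrix.
#' @param maf minor allele frequencies aligned to R, or NULL.
#' @param grid a [rho_grid()].
#' @param ridge ridge passed to [ld_inverse()].
#' @return opaque precomputation list consumed by [owc_T()],
#'   [mc_pvalue()], [batch_null_reference()] and [adaptive_mc_pvalue()].
#' @export
owc_precompute <- function(R, maf = NULL, grid = rho_grid(0.1), ridge = 0) {
  grid_m <- unclass(grid)
  if (is.null(maf) && any(grid_m[, 2L] > 0)) {
    keep <- grid_m[, 2L] == 0
    message("owc_precompute: no MAFs; dropping ", sum(!keep),
            " grid points with rho2 > 0 (", sum(keep), " remain)")
    grid_m <- grid_m[keep, , drop = FALSE]
  }
  pre <- quad_precompute(R, grid_m, maf = maf, ridge = ridge)
  pre$grid <- grid_m
  pre
}

#' Observed OWC statistic: minimum p-value over the weight grid
#'
#' For each grid point rho, computes L_rho = Z'AZ and its mixture-of-chi-
#' square p-value; T is the minimum over the grid (ties broken by grid
#' order).
#'
#' @param z numeric vector of Z-scores.
#' @param R LD matrix (ignored when `precomp` is supplied).
#' @param maf minor allele frequencies or NULL.
#' @param grid a [rho_grid()].
#' @param precomp result of [owc_precompute()]; built on the fly if NULL.
#' @return list with `T`, `best_rho` (the arg-min weights) and `p`, the
#'   named vector of per-point p-values.
#' @export
owc_T <- function(z, R = NULL, maf = NULL, grid = rho_grid(0.1),
                  precomp = NULL) {
  if (is.null(precomp)) precomp <- owc_precompute(R, maf = maf, grid = grid)
  stopifnot(length(z) == precomp$M)
  res <- quad_minp(matrix(z, nrow = 1L), precomp, return_p = TRUE)
  p <- drop(res$p)
  names(p) <- rownames(precomp$coef)
  rho <- precomp$coef[res$best[1L], ]
  list(T = res$T[1L],
       best_rho = rho_weights(rho[1], rho[2], rho[3], rho[4]),
       p = p)
}

#' Plain Monte Carlo p-value for the OWC statistic
#'
#' Draws B null score vectors Z^(b) ~ MVN(0, R) through the Cholesky
#' factor, computes the null statistics T^(b), and returns
#' p = (#\{T^(b) <= T_obs\} + 1) / (B + 1) — the add-one estimator, whose
#' smallest attainable value is 1/(B+1).
#'
#' @param T_obs observed statistic from [owc_T()].
#' @param R,maf,grid gene inputs (ignored when `precomp` given).
#' @param B number of null draws.
#' @param seed optional integer seed (restores the caller's RNG state).
#' @param precomp result of [owc_precompute()].
#' @return list with `pvalue` and `null_T` (the B null statistics).
#' @export
mc_pvalue <- function(T_obs, R = NULL, maf = NULL, grid = rho_grid(0.1),
                      B = 1000, seed = NULL, precomp = NULL) {
  stopifnot(B >= 1)
  if (is.null(precomp)) precomp <- owc_precompute(R, maf = maf, grid = grid)
  null_T <- with_seed(seed, null_T_draws(precomp, B))
  list(pvalue = (sum(null_T <= T_obs) + 1) / (B + 1), null_T = null_T)
}

#' Shared sorted null reference for batched p-value lookup
#'
#' Simulates B null statistics once and sorts them; [ref_pvalue()] then
#' converts any observed T into the same add-one Monte Carlo p-value by
#' binary search.  This is how simulation studies avoid re-simulating the
#' null for every replicate.
#'
#' @inheritParams mc_pvalue
#' @return sorted numeric vector of null T values.
#' @export
batch_null_reference <- function(R = NULL, maf = NULL, grid = rho_grid(0.1),
                                 B = 1000, seed = NULL, precomp = NULL) {
  stopifnot(B >= 1)
  if (is.null(precomp)) precomp <- owc_precompute(R, maf = maf, grid = grid)
  sort(with_seed(seed, null_T_draws(precomp, B)))
}

#' Monte Carlo p-values from a sorted null reference
#'
#' @param T_obs numeric vector of observed statistics.
#' @param ref sorted null reference from [batch_null_reference()].
#' @return numeric vector of p-values, identical to [mc_pvalue()] on the
#'   same draws.
#' @export
ref_pvalue <- function(T_obs, ref) {
  (findInterval(T_obs, ref) + 1) / (length(ref) + 1)
}

#' Fast adaptive Monte Carlo p-value for the OWC test
#'
#' Staged estimator: starting from `params$B0` null draws, the cumulative
#' draw count is multiplied by `params$mult` until either the gene is
#' clearly non-significant (the fraction of null statistics at or below
#' T_obs exceeds `params$p0`) or the next stage would pass `params$Bmax`.
#' Stages extend the accumulated draw sequence — earlier draws are reused,
#' never regenerated — so the result under a pinned single stage equals
#' [mc_pvalue()] with the same seed.  The reported p-value is always the
#' add-one estimator on all accumulated draws.
#'
#' @param z numeric vector of observed Z-scores.
#' @param R,maf,grid gene inputs (ignored when `precomp` given).
#' @param params a [fast_mc_params()] list.
#' @param seed optional integer seed.
#' @param precomp result of [owc_precompute()].
#' @return object of class `owc_result`: list with `T`, `pvalue`,
#'   `best_rho`, `per_rho_p`, `n_null_used`, `seed`.
#' @export
adaptive_mc_pvalue <- function(z, R = NULL, maf = NULL, grid = rho_grid(0.1),
                               params = fast_mc_params(), seed = NULL,
                               precomp = NULL) {
  if (is.null(precomp)) precomp <- owc_precompute(R, maf = maf, grid = grid)
  obs <- owc_T(z, precomp = precomp)
  out <- with_seed(seed, {
    B <- params$B0
    null_T <- numeric(0L)
    repeat {
      null_T <- c(null_T, null_T_draws(precomp, B - length(null_T)))
      count <- sum(null_T <= obs$T)
      phat <- (count + 1) / (B + 1)
      B_next <- B * params$mult
      if (count / B > params$p0 || B_next > params$Bmax) break
      B <- B_next
    }
    list(pvalue = phat, n_null_used = B)
  })
  structure(list(T = obs$T, pvalue = out$pvalue, best_rho = obs$best_rho,
                 per_rho_p = obs$p, n_null_used = out$n_null_used,
                 seed = seed),
            class = "owc_result")
}

#' @export
print.owc_result <- function(x, ...) {
  cat("OWC gene-based combination test\n")
  cat(sprintf("  T (min p over grid) = %.6g\n", x$T))
  cat(sprintf("  Monte Carlo p-value = %.6g  (null draws: %d)\n",
              x$pvalue, x$n_null_used))
  cat(sprintf("  best rho = (%s)\n",
              paste(format(unclass(x$best_rho)), collapse = ", ")))
  invisible(x)
}

#' OWC omnibus test for one gene
#'
#' Convenience wrapper: precomputes the gene quantities, evaluates the
#' observed min-p statistic T over the rho grid, and estimates its p-value
#' either with a fixed number of null draws (`B`) or with the fast adaptive
#' scheme (default).  Component p-values at the four simplex vertices
#' (burden, WSS, score, SSU) are attached for reporting.
#'
#' @param z numeric vector of per-SNP Z-scores for the gene.
#' @param R LD matrix aligned to `z`.
#' @param maf minor allele frequencies, or NULL (disables the WSS
#'   component and the rho2 > 0 grid points).
#' @param grid a [rho_grid()].
#' @param B fixed number of null draws; NULL (default) uses the adaptive
#'   scheme.
#' @param params a [fast_mc_params()] list for the adaptive scheme.
#' @param seed optional integer seed.
#' @param ridge ridge for the LD inverse.
#' @return an `owc_result` with an extra `component_p` entry: named
#'   p-values of the burden, WSS, score and SSU tests.
#' @export
owc_test <- function(z, R, maf = NULL, grid = rho_grid(0.1), B = NULL,
                     params = fast_mc_params(), seed = NULL, ridge = 0) {
  precomp <- owc_precompute(R, maf = maf, grid = grid, ridge = ridge)
  if (is.null(B)) {
    res <- adaptive_mc_pvalue(z, params = params, seed = seed,
                              precomp = precomp)
  } else {
    obs <- owc_T(z, precomp = precomp)
    mc <- mc_pvalue(obs$T, B = B, seed = seed, precomp = precomp)
    res <- structure(list(T = obs$T, pvalue = mc$pvalue,
                          best_rho = obs$best_rho, per_rho_p = obs$p,
                          n_null_used = B, seed = seed),
                     class = "owc_result")
  }
  Rm <- precomp$R
  Rinv <- if (!is.null(precomp$Rinv)) precomp$Rinv else ld_inverse(Rm, ridge = ridge)
  res$component_p <- c(
    burden = burden_test(z, Rm)$p.value,
    wss = wss_test(z, maf, Rm)$p.value,
    score = score_test(z, Rinv)$p.value,
    ssu = ssu_test(z, Rm)$p.value)
  res$M <- precomp$M
  res
}
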