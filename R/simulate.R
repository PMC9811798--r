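#' Synthetic LD matrices for simulation studies
#'
#' Three standard correlation structures: `"ar1"` with entry (i, j) =
#' param^|i-j|; `"exchangeable"` with constant off-diagonal `param`;
#' `"block"`, two AR(1) blocks of sizes ceiling(M/2) and floor(M/2) with
#' zero cross-correlation.
#'
#' @param kind one of `"ar1"`, `"exchangeable"`, `"block"`.
#' @param M number of SNPs.
#' @param param correlation parameter, |param| < 1 (for exchangeable also
#'   above -1/(M-1) to stay positive definite).
#' @return an [as_ld_matrix()] object.
#' @export
synthetic_ld <- function(kind = c("ar1", "exchangeable", "block"), M,
                         param = 0.5) {
  kind <- match.arg(kind)
  stopifnot(M >= 1)
  ar1 <- function(m, r) r^abs(outer(seq_len(m), seq_len(m), "-"))
  R <- switch(kind,
    ar1 = {
      if (abs(param) >= 1) stop("ar1 parameter must satisfy |param| < 1")
      ar1(M, param)
    },
    exchangeable = {
      if (param >= 1 || (M > 1 && param <= -1 / (M - 1)))
        stop("exchangeable parameter outside (-1/(M-1), 1)")
      m <- matrix(param, M, M)
      diag(m) <- 1
      m
    },
    block = {
      if (abs(param) >= 1) stop("block parameter must satisfy |param| < 1")
      M1 <- ceiling(M / 2)
      m <- matrix(0, M, M)
      m[seq_len(M1), seq_len(M1)] <- ar1(M1, param)
      if (M > M1)
        m[(M1 + 1):M, (M1 + 1):M] <- ar1(M - M1, param)
      m
    })
  as_ld_matrix(R)
}

#' Effect-size configuration for power simulations
#'
#' Describes the mean shift of the alternative: Z ~ MVN(A x Delta, R) with
#' signs A in {-1, +1} at the causal positions and effect sizes Delta either
#' fixed or drawn fresh for every replicate from a uniform or normal
#' distribution (`list(kind = "uniform", min =, max =)` or
#' `list(kind = "normal", mean =, sd =)`; the normal spec is parameterized
#' by its standard deviation).
#'
#' @param causal integer indices of the causal SNPs.
#' @param signs vector of +1/-1 effect directions, one per causal SNP.
#' @param delta numeric vector of fixed effect sizes (one per causal SNP),
#'   or a distribution spec list as above.
#' @return object of class `effect_config`.
#' @export
effect_config <- function(causal, signs, delta) {
  stopifnot(length(causal) == length(signs), all(signs %in% c(-1, 1)))
  if (is.numeric(delta)) {
    stopifnot(length(delta) == length(causal))
  } else if (is.list(delta)) {
    kind <- match.arg(delta$kind, c("uniform", "normal"))
    if (kind == "uniform") stopifnot(is.numeric(delta$min), is.numeric(delta$max))
    else stopifnot(is.numeric(delta$mean), is.numeric(delta$sd))
    delta$kind <- kind
  } else stop("delta must be a numeric vector or a distribution spec list")
  structure(list(causal = as.integer(causal), signs = signs, delta = delta),
            class = "effect_config")
}

draw_means <- function(config, n, M) {
  mu <- matrix(0, n, M)
  if (is.null(config)) return(mu)
  d <- config$delta
  k <- length(config$causal)
  vals <- if (is.numeric(d)) {
    matrix(d, n, k, byrow = TRUE)
  } else if (d$kind == "uniform") {
    matrix(stats::runif(n * k, d$min, d$max), n, k)
  } else {
    matrix(stats::rnorm(n * k, d$mean, d$sd), n, k)
  }
  mu[, config$causal] <- sweep(vals, 2L, config$signs, "*")
  mu
}

#' Simulate summary-statistic Z-score vectors
#'
#' Draws n replicates of Z ~ MVN(mean, R) via the Cholesky factor of R.
#' With `config = NULL` the mean is zero (the null design); otherwise the
#' mean carries sign x delta at the causal positions, with distributional
#' deltas redrawn for every replicate.
#'
#' @param R LD matrix.
#' @param config an [effect_config()] or NULL.
#' @param n number of replicates.
#' @param seed optional integer seed.
#' @return n x M numeric matrix, one replicate per row.
#' @export
sample_z <- function(R, config = NULL, n, seed = NULL) {
  R <- psd_repair(as_ld_matrix(R))
  M <- nrow(R)
  D <- ld_cholesky(R)
  with_seed(seed, {
    mu <- draw_means(config, n, M)
    mu + matrix(stats::rnorm(n * M), n, M) %*% t(D)
  })
}

# p-values of one registered analytic test on a Z matrix (replicates x M).
analytic_pvalues <- function(method, Zmat, R, maf = NULL) {
  M <- ncol(Zmat)
  switch(method,
    st = {
      v <- sum(unclass(R))
      stats::pchisq(rowSums(Zmat)^2 / v, df = 1, lower.tail = FALSE)
    },
    s2t = {
      lam <- sort(pmax(eigen(unclass(R), symmetric = TRUE,
                             only.values = TRUE)$values, 0), decreasing = TRUE)
      par <- liu_params(lam)
      liu_sf(rowSums(Zmat^2), par)
    },
    gates = {
      Pmat <- 2 * stats::pnorm(abs(Zmat), lower.tail = FALSE)
      Pmat[Pmat == 0] <- .Machine$double.xmin
      gates_batch(Pmat, R)
    },
    stop("unknown analytic method: ", method))
}

# Monte Carlo p-values for the min-p engines (owc, at) through a shared
# sorted null reference computed from `null_B` draws.
engine_precompute <- function(method, R, maf = NULL, grid = rho_grid(0.1)) {
  switch(method,
    owc = owc_precompute(R, maf = maf, grid = grid),
    at = at_precompute(R),
    stop("unknown engine method: ", method))
}

# aSPU p-values for many replicates against one shared null draw set.
# Component p-values of replicates and of the null draws themselves are
# ranked against the same reference (leave-self-in for the reference),
# mirroring the pooled single-gene estimator at scale.
aspu_ref_pvalues <- function(Zmat, Znull, gammas = c(1:8, Inf)) {
  B <- nrow(Znull)
  spu <- function(Zm, g) {
    if (is.infinite(g)) apply(abs(Zm), 1L, max) else rowSums(Zm^g)
  }
  minp_obs <- rep(Inf, nrow(Zmat))
  minp_null <- rep(Inf, B)
  for (g in gammas) {
    t_null <- spu(Znull, g)
    t_obs <- spu(Zmat, g)
    if (!(is.infinite(g) || g %% 2 == 0)) {
      t_null <- abs(t_null)
      t_obs <- abs(t_obs)
    }
    s <- sort(t_null)
    # findInterval(., left.open = TRUE) counts strictly smaller reference
    # values, so B minus it is the self-inclusive exceedance count.
    p_obs <- (B - findInterval(t_obs, s, left.open = TRUE) + 1) / (B + 1)
    p_null <- (B - findInterval(t_null, s, left.open = TRUE)) / B
    minp_obs <- pmin(minp_obs, p_obs)
    minp_null <- pmin(minp_null, p_null)
  }
  s <- sort(minp_null)
  (findInterval(minp_obs, s) + 1) / (B + 1)
}

sim_pvalues <- function(method, Zmat, R, maf = NULL, grid = rho_grid(0.1),
                        null_B = 20000L, seed = NULL, chunk = 20000L) {
  if (is.function(method)) return(method(Zmat, R, maf))
  if (method %in% c("st", "s2t", "gates"))
    return(analytic_pvalues(method, Zmat, R, maf))
  if (method == "aspu") {
    D <- ld_cholesky(psd_repair(as_ld_matrix(R)))
    Znull <- with_seed(seed,
      matrix(stats::rnorm(null_B * ncol(Zmat)), null_B) %*% t(D))
    return(aspu_ref_pvalues(Zmat, Znull))
  }
  pre <- engine_precompute(method, R, maf = maf, grid = grid)
  ref <- batch_null_reference(B = null_B, seed = seed, precomp = pre)
  n <- nrow(Zmat)
  out <- numeric(n)
  done <- 0L
  while (done < n) {
    nb <- min(chunk, n - done)
    idx <- done + seq_len(nb)
    out[idx] <- ref_pvalue(quad_minp(Zmat[idx, , drop = FALSE], pre)$T, ref)
    done <- done + nb
  }
  out
}

#' Type-I error ratio of a registered test
#'
#' Simulates `n_reps` null Z vectors from MVN(0, R), applies the test, and
#' returns the fraction of p-values at or below `alpha` divided by `alpha`
#' (1.0 = perfect calibration), with Monte Carlo standard errors.  Methods
#' with Monte Carlo p-values (`"owc"`, `"at"`, `"aspu"`) share one null
#' reference of `null_B` draws across all replicates; `se_total`
#' additionally propagates the reference noise for those methods.
#'
#' @param method one of `"owc"`, `"st"`, `"s2t"`, `"at"`, `"aspu"`,
#'   `"gates"`.
#' @param R LD matrix of the simulated gene.
#' @param maf minor allele frequencies or NULL.
#' @param n_reps number of null replicates.
#' @param alpha significance level.
#' @param seed integer seed (drives both the reference and the replicates).
#' @param null_B size of the shared null reference for Monte Carlo methods.
#' @param grid rho grid for `"owc"`.
#' @return list with `ratio`, `mc_se` (binomial s.e. of the ratio),
#'   `se_total`, `rate`, `n_reps`, `alpha`.
#' @export
type1_ratio <- function(method, R, maf = NULL, n_reps = 1e5, alpha = 1e-3,
                        seed = NULL, null_B = 20000L, grid = rho_grid(0.1)) {
  mc_method <- is.character(method) && method %in% c("owc", "at", "aspu")
  if (mc_method && alpha < 1 / (null_B + 1))
    stop("alpha below the 1/(null_B + 1) resolution; increase null_B")
  seed_ref <- if (is.null(seed)) NULL else seed
  seed_rep <- if (is.null(seed)) NULL else seed + 1L
  Zmat <- sample_z(R, config = NULL, n = n_reps, seed = seed_rep)
  p <- sim_pvalues(method, Zmat, R, maf = maf, grid = grid,
                   null_B = null_B, seed = seed_ref)
  rate <- mean(p <= alpha)
  mc_se <- sqrt(alpha * (1 - alpha) / n_reps) / alpha
  se_total <- if (mc_method)
    sqrt(mc_se^2 + alpha * (1 - alpha) / null_B / alpha^2) else mc_se
  list(ratio = rate / alpha, mc_se = mc_se, se_total = se_total,
       rate = rate, n_reps = n_reps, alpha = alpha)
}

#' Power of a registered test under a mean-shifted alternative
#'
#' Simulates `n_reps` replicates of Z ~ MVN(A x Delta, R) per the effect
#' configuration and returns the percentage of p-values at or below
#' `alpha`, with its binomial standard error (also in percent).
#'
#' @inheritParams type1_ratio
#' @param config an [effect_config()].
#' @return list with `power` (percent), `mc_se` (percent), `n_reps`,
#'   `alpha`.
#' @export
power_estimate <- function(method, R, config, maf = NULL, n_reps = 1e4,
                           alpha = 2.5e-6, seed = NULL, null_B = 1e6,
                           grid = rho_grid(0.1)) {
  mc_method <- is.character(method) && method %in% c("owc", "at", "aspu")
  if (mc_method && alpha < 1 / (null_B + 1))
    stop("alpha below the 1/(null_B + 1) resolution; increase null_B")
  seed_ref <- if (is.null(seed)) NULL else seed
  seed_rep <- if (is.null(seed)) NULL else seed + 1L
  Zmat <- sample_z(R, config = config, n = n_reps, seed = seed_rep)
  p <- sim_pvalues(method, Zmat, R, maf = maf, grid = grid,
                   null_B = null_B, seed = seed_ref)
  pow <- mean(p <= alpha)
  list(power = 100 * pow,
       mc_se = 100 * sqrt(pow * (1 - pow) / n_reps),
       n_reps = n_reps, alpha = alpha)
}
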