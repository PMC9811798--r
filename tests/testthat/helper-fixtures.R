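# Shared fixtures and small oracles used across the suite.

toy_R2 <- function(r = 0.5) as_ld_matrix(matrix(c(1, r, r, 1), 2))

# random well-conditioned correlation matrix
rand_corr <- function(M, seed) {
  set.seed(seed)
  X <- matrix(rnorm((M + 10) * M), M + 10, M)
  as_ld_matrix(stats::cov2cor(crossprod(X)))
}

# exact two-sided Kolmogorov statistic against Uniform(0,1)
ks_stat <- function(p) {
  ps <- sort(p)
  n <- length(ps)
  i <- seq_len(n)
  max(pmax(i / n - ps, ps - (i - 1) / n))
}

# 0.001-level critical value of the Kolmogorov statistic
ks_crit <- function(n, alpha = 0.001) sqrt(-log(alpha / 2) / 2) / sqrt(n)

# accurate mixture survival probabilities for large vectors: exact
# characteristic-function inversion on a fine quantile grid, interpolated
# on the log scale
mixture_sf_interp <- function(x, lambda, n_knots = 600) {
  hi <- max(x) * 1.05 + 1
  knots <- seq(0, hi, length.out = n_knots)
  logp <- log(pmax(mixture_sf(knots, lambda, method = "imhof"), 1e-300))
  exp(stats::approx(knots, logp, xout = pmax(x, 0))$y)
}

# the synthetic 11-SNP study gene: AR(1) LD with parameter 0.5 and MAFs
# spanning the common-variant range
study_gene <- function() {
  list(R = synthetic_ld("ar1", 11, 0.5),
       maf = seq(0.067, 0.453, length.out = 11))
}

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
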