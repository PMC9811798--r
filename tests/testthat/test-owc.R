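test_that("rho_grid enumerates the simplex lattice", {
  g <- rho_grid(0.1)
  expect_equal(nrow(g), 286L)
  expect_true(all(abs(rowSums(g) - 1) < 1e-12))
  expect_false(any(duplicated(g)))

  v <- rho_grid(1)
  expect_equal(nrow(v), 4L)
  expect_equal(unclass(v), diag(4)[4:1, ], ignore_attr = TRUE)  # the 4 vertices

  expect_error(rho_grid(0.3), "integer")
})

test_that("without MAFs the rho2 > 0 grid points are dropped", {
  R <- synthetic_ld("ar1", 4, 0.3)
  expect_message(pre <- owc_precompute(R, maf = NULL), "dropping 220")
  expect_equal(nrow(pre$coef), 66L)
  expect_true(all(pre$coef[, 2] == 0))
})

test_that("per-grid-point p-values at the vertices equal the component tests", {
  gs <- study_gene()
  set.seed(5)
  z <- drop(ld_cholesky(gs$R) %*% rnorm(11))
  pre <- owc_precompute(gs$R, maf = gs$maf)
  ot <- owc_T(z, precomp = pre)
  vertex <- function(r) which(apply(pre$coef, 1, function(x) all(x == r)))
  expect_equal(unname(ot$p[vertex(c(1, 0, 0, 0))]),
               burden_test(z, gs$R)$p.value, tolerance = 1e-10)
  expect_equal(unname(ot$p[vertex(c(0, 1, 0, 0))]),
               wss_test(z, gs$maf, gs$R)$p.value, tolerance = 1e-10)
  expect_equal(unname(ot$p[vertex(c(0, 0, 1, 0))]),
               score_test(z, ld_inverse(gs$R))$p.value, tolerance = 1e-8)
  expect_equal(unname(ot$p[vertex(c(0, 0, 0, 1))]),
               ssu_test(z, gs$R)$p.value, tolerance = 1e-10)
  expect_equal(ot$T, min(ot$p))
})

test_that("a single-SNP gene collapses to the two-sided normal p-value", {
  z1 <- 1.7
  R1 <- as_ld_matrix(matrix(1))
  ot <- owc_T(z1, R = R1, maf = 0.3)
  expect_equal(ot$T, 2 * pnorm(abs(z1), lower.tail = FALSE),
               tolerance = 1e-10)
  expect_lt(diff(range(ot$p)), 1e-10)  # every grid point gives the same p

  expect_equal(owc_T(rep(0, 4), R = synthetic_ld("ar1", 4, 0.4),
                     maf = rep(0.2, 4))$T, 1)
})

test_that("a degenerate single-point grid reduces to the component test", {
  gs <- study_gene()
  set.seed(6)
  z <- drop(ld_cholesky(gs$R) %*% rnorm(11))
  pre1 <- quad_precompute(gs$R, matrix(c(0, 0, 0, 1), 1))
  expect_equal(quad_minp(matrix(z, 1), pre1)$T[1],
               ssu_test(z, gs$R)$p.value, tolerance = 1e-10)
})

test_that("T is invariant to joint SNP reordering", {
  gs <- study_gene()
  set.seed(7)
  z <- drop(ld_cholesky(gs$R) %*% rnorm(11))
  perm <- sample(11)
  T1 <- owc_T(z, R = gs$R, maf = gs$maf)$T
  Rp <- as_ld_matrix(unclass(gs$R)[perm, perm])
  T2 <- owc_T(z[perm], R = Rp, maf = gs$maf[perm])$T
  expect_lt(abs(T1 - T2), 1e-12)
})

test_that("mc_pvalue implements the add-one estimator with a 1/(B+1) floor", {
  gs <- study_gene()
  pre <- owc_precompute(gs$R, maf = gs$maf)
  mc <- mc_pvalue(0, B = 999, seed = 1, precomp = pre)  # T below all nulls
  expect_equal(mc$pvalue, 1 / 1000)
  expect_equal(mc_pvalue(1, B = 50, seed = 1, precomp = pre)$pvalue, 1)
  expect_length(mc$null_T, 999L)
})

test_that("the adaptive estimator stops early, escalates, and matches a pinned stage", {
  gs <- study_gene()
  pre <- owc_precompute(gs$R, maf = gs$maf)
  # unremarkable gene (large true p): stops at the first stage of 10 draws
  z_null <- rep(0.1, 11)
  res <- adaptive_mc_pvalue(z_null, precomp = pre, seed = 3)
  expect_equal(res$n_null_used, 10L)
  expect_gte(res$pvalue, 1 / 11)

  # overwhelming signal escalates to the cap with the floor p-value
  z_big <- rep(8, 11)
  res_big <- adaptive_mc_pvalue(z_big, precomp = pre, seed = 3,
                                params = fast_mc_params(B0 = 10, Bmax = 1000))
  expect_equal(res_big$n_null_used, 1000)
  expect_equal(res_big$pvalue, 1 / 1001)

  # a single pinned stage is exactly mc_pvalue under the same seed
  obs <- owc_T(z_null, precomp = pre)
  mc <- mc_pvalue(obs$T, B = 50, seed = 7, precomp = pre)
  ad <- adaptive_mc_pvalue(z_null, precomp = pre, seed = 7,
                           params = fast_mc_params(B0 = 50, Bmax = 50))
  expect_identical(ad$pvalue, mc$pvalue)
  expect_gte(ad$pvalue, 1 / (ad$n_null_used + 1))
})

test_that("the sorted null reference reproduces mc_pvalue on identical draws", {
  gs <- study_gene()
  pre <- owc_precompute(gs$R, maf = gs$maf)
  ref <- batch_null_reference(B = 200, seed = 9, precomp = pre)
  expect_false(is.unsorted(ref))
  for (T_obs in c(0.01, 0.2, 0.9)) {
    expect_equal(ref_pvalue(T_obs, ref),
                 mc_pvalue(T_obs, B = 200, seed = 9, precomp = pre)$pvalue)
  }
  ref1 <- batch_null_reference(B = 1, seed = 2, precomp = pre)
  expect_true(all(ref_pvalue(c(0, 1), ref1) %in% c(1 / 2, 1)))
})

test_that("restricting the grid to burden and SSU gives the SKAT-O family", {
  gs <- study_gene()
  set.seed(15)
  z <- drop(ld_cholesky(gs$R) %*% rnorm(11)) + 1.0
  pre <- quad_precompute(gs$R, rbind(c(1, 0, 0, 0), c(0, 0, 0, 1)))
  T2 <- quad_minp(matrix(z, 1), pre)$T[1]
  expect_equal(T2, min(burden_test(z, gs$R)$p.value,
                       ssu_test(z, gs$R)$p.value), tolerance = 1e-10)
})

test_that("owc_test wires components, seeds, and the report fields together", {
  gs <- study_gene()
  set.seed(21)
  z <- drop(ld_cholesky(gs$R) %*% rnorm(11))
  r1 <- owc_test(z, gs$R, maf = gs$maf, B = 200, seed = 5)
  r2 <- owc_test(z, gs$R, maf = gs$maf, B = 200, seed = 5)
  expect_identical(r1$pvalue, r2$pvalue)
  expect_equal(r1$M, 11L)
  expect_named(r1$component_p, c("burden", "wss", "score", "ssu"))
  expect_equal(unname(r1$component_p["burden"]),
               burden_test(z, gs$R)$p.value)
  expect_gte(r1$pvalue, 1 / 201)
  expect_output(print(r1), "OWC")
})
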