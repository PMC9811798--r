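test_that("read_sumstats parses the standard schema and drops bad rows", {
  path <- write_lines_tmp(c(
    "SNP\tCHR\tBP\tMAF\tBETA\tP",
    "rs1\t1\t100\t0.10\t0.2\t0.01",
    "rs2\t1\t200\t0.30\t-0.1\t0.50",
    "rs3\t1\t300\t0.45\t0.05\t0.90"), ext = ".tsv")
  ss <- read_sumstats(path)
  expect_equal(nrow(ss), 3L)
  expect_equal(ss$snp_id, c("rs1", "rs2", "rs3"))
  expect_equal(ss$pvalue, c(0.01, 0.5, 0.9))
  expect_equal(attr(ss, "n_dropped"), 0L)

  path2 <- write_lines_tmp(c(
    "SNP\tCHR\tBP\tMAF\tBETA\tP",
    "rs1\t1\t100\t0.10\t0.2\t0.01",
    "rs2\t1\t200\t0.30\t-0.1\tNA"), ext = ".tsv")
  expect_message(ss2 <- read_sumstats(path2), "dropped 1")
  expect_equal(nrow(ss2), 1L)
  expect_equal(attr(ss2, "n_dropped"), 1L)
})

test_that("read_sumstats accepts a Z-only schema and odds ratios", {
  path <- write_lines_tmp(c("SNP,Z", "rs1,1.5", "rs2,-0.7"), ext = ".csv")
  ss <- read_sumstats(path, columns = c(snp_id = "SNP", z = "Z"))
  expect_equal(ss$z, c(1.5, -0.7))
  expect_true(all(is.na(ss$pvalue)))

  path2 <- write_lines_tmp(c("SNP,OR,P", "rs1,1.5,0.05", "rs2,0.8,0.2"),
                           ext = ".csv")
  ss2 <- read_sumstats(path2, columns = c(snp_id = "SNP", or = "OR",
                                          pvalue = "P"))
  expect_equal(ss2$beta, log(c(1.5, 0.8)))
})

test_that("read_sumstats errors on missing mandatory columns and empty files", {
  path <- write_lines_tmp(c("ID,P", "rs1,0.5"), ext = ".csv")
  expect_error(read_sumstats(path), "snp_id")
  path2 <- write_lines_tmp(c("SNP,P,BETA"), ext = ".csv")
  expect_error(read_sumstats(path2, columns = c(snp_id = "SNP", pvalue = "P",
                                                beta = "BETA")))
})

test_that("zscore_from_p matches the normal quantile and is an exact inverse", {
  expect_equal(zscore_from_p(1, 1), 0)
  expect_equal(zscore_from_p(0.05, 1), 1.95996, tolerance = 1e-5)
  expect_equal(zscore_from_p(0.05, -1), -1.95996, tolerance = 1e-5)
  expect_equal(zscore_from_p(0.3, 0), 0)

  p <- 10^seq(-10, 0, length.out = 50)
  z <- zscore_from_p(p, rep(1, 50))
  back <- 2 * pnorm(abs(z), lower.tail = FALSE)
  expect_lt(max(abs(back - p) / p), 1e-10)

  expect_error(zscore_from_p(0, 1), "0, 1")
  expect_error(zscore_from_p(1.2, 1), "0, 1")
  expect_warning(zscore_from_p(1e-320, 1), "clamped")
})

test_that("gene windows are inclusive at both flank boundaries", {
  genes <- data.frame(gene_id = "G", chrom = "1", start = 100000L,
                      end = 110000L, stringsAsFactors = FALSE)
  mk <- function(pos) data.frame(snp_id = paste0("rs", seq_along(pos)),
                                 chrom = "1", pos = pos, maf = 0.2,
                                 beta = 0.1, pvalue = 0.5,
                                 z = rnorm(length(pos)))
  inside <- assign_snps_to_genes(mk(c(80000L, 90001L, 130000L)), genes)
  expect_equal(nrow(inside$G$snps), 3L)
  outside <- assign_snps_to_genes(mk(c(79999L, 130001L)), genes)
  expect_length(outside, 0L)
})

test_that("a SNP shared by overlapping genes appears in both summaries", {
  genes <- data.frame(gene_id = c("A", "B"), chrom = "1",
                      start = c(1000L, 4000L), end = c(5000L, 9000L),
                      stringsAsFactors = FALSE)
  snps <- data.frame(snp_id = "rs1", chrom = "1", pos = 4500L, maf = 0.2,
                     beta = 0.1, pvalue = 0.5, z = 1.0)
  out <- assign_snps_to_genes(snps, genes, window_bp = 0L)
  expect_named(out, c("A", "B"))
  expect_equal(out$A$snps$snp_id, "rs1")
  expect_equal(out$B$snps$snp_id, "rs1")
})

test_that("BED annotations are converted to 1-based closed intervals", {
  path <- write_lines_tmp(c("1\t999\t2000\tG1"), ext = ".bed")
  g <- read_gene_annotations(path, format = "bed")
  expect_equal(g$start, 1000L)
  expect_equal(g$end, 2000L)
})

make_gene3 <- function(maf = c(0.02, 0.30, 0.40), z = c(0.5, 1.2, -0.3)) {
  gene_summary("G", data.frame(
    snp_id = c("a", "b", "c"), chrom = "1", pos = c(10L, 20L, 30L),
    maf = maf, beta = 0.1, pvalue = 0.5, z = z, stringsAsFactors = FALSE))
}

R3_corr <- function(r23 = sqrt(0.6)) {
  as_ld_matrix(matrix(c(1, 0.1, 0.1,
                        0.1, 1, r23,
                        0.1, r23, 1), 3, byrow = TRUE),
               snp_ids = c("a", "b", "c"))
}

test_that("qc_filter applies the MAF cutoff then greedy position-order pruning", {
  out <- qc_filter(make_gene3(), R3_corr())
  expect_false(out$empty)
  expect_equal(out$gene$snps$snp_id, "b")
  expect_equal(out$dropped_maf, "a")
  expect_equal(out$dropped_ld, "c")
  expect_equal(nrow(out$R), 1L)
})

test_that("qc_filter is a no-op on clean input, idempotent, order-preserving", {
  gene <- make_gene3(maf = c(0.1, 0.3, 0.4))
  R <- as_ld_matrix(matrix(c(1, .2, .1, .2, 1, .3, .1, .3, 1), 3),
                    snp_ids = c("a", "b", "c"))
  out <- qc_filter(gene, R)
  expect_equal(out$gene$snps$snp_id, c("a", "b", "c"))
  expect_equal(unclass(out$R), unclass(R), ignore_attr = TRUE)

  once <- qc_filter(make_gene3(), R3_corr())
  twice <- qc_filter(once$gene, once$R)
  expect_equal(twice$gene$snps$snp_id, once$gene$snps$snp_id)
  expect_equal(unclass(twice$R), unclass(once$R))
})

test_that("qc_filter reports an explicit empty result and supports |Z| pruning", {
  all_rare <- make_gene3(maf = c(0.01, 0.02, 0.03))
  out <- qc_filter(all_rare, R3_corr())
  expect_true(out$empty)
  expect_null(out$gene)

  # under the |Z| policy the more significant member of the correlated
  # pair (b, c) is kept even though it comes later in position
  gene <- make_gene3(maf = c(0.2, 0.3, 0.4), z = c(0.5, 0.8, -2.5))
  out2 <- qc_filter(gene, R3_corr(), prune = "zscore")
  expect_setequal(out2$gene$snps$snp_id, c("a", "c"))
  # and output stays in genomic order regardless of scan order
  expect_equal(out2$gene$snps$snp_id, c("a", "c"))
})
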