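#' Read GWAS summary statistics
#'
#' Reads a delimited summary-statistic file (tab or comma, header required)
#' and standardizes it to columns `snp_id`, `chrom`, `pos`, `maf`, `beta`,
#' `pvalue`, `z`.  The `columns` mapping names the file's columns for each
#' field; at least `snp_id` plus either `z` or (`pvalue` and one of `beta` /
#' `or`) must be mapped.  When only an odds ratio is given, `beta = log(OR)`.
#' Rows whose mandatory fields fail to parse are dropped and counted in a
#' message.
#'
#' @param path file path.
#' @param columns named character vector mapping internal field names
#'   (`snp_id`, `chrom`, `pos`, `maf`, `beta`, `or`, `pvalue`, `z`) to column
#'   names in the file.
#' @return data.frame with one row per retained SNP and attribute
#'   `"n_dropped"` counting discarded rows.
#' @export
read_sumstats <- function(path,
                          columns = c(snp_id = "SNP", chrom = "CHR",
                                      pos = "BP", maf = "MAF", beta = "BETA",
                                      pvalue = "P")) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          na.strings = c("NA", "", "."))
  if (nrow(dt) == 0L) stop("empty summary-statistic file: ", path)
  fields <- c("snp_id", "chrom", "pos", "maf", "beta", "or", "pvalue", "z")
  columns <- columns[names(columns) %in% fields]
  present <- columns[columns %in% names(dt)]

  need <- function(f) f %in% names(present)
  if (!need("snp_id"))
    stop("summary file lacks mapped column for 'snp_id' (looked for '",
         columns[["snp_id"]], "')")
  if (!need("z") && !(need("pvalue") && (need("beta") || need("or"))))
    stop("summary file must provide either a 'z' column or 'pvalue' plus ",
         "'beta'/'or' columns; available: ", paste(names(dt), collapse = ", "))

  out <- data.frame(snp_id = as.character(dt[[present[["snp_id"]]]]),
                    stringsAsFactors = FALSE)
  grab <- function(f, as = as.numeric) {
    if (need(f)) as(dt[[present[[f]]]]) else rep(NA_real_, nrow(dt))
  }
  out$chrom <- if (need("chrom")) as.character(dt[[present[["chrom"]]]]) else NA_character_
  out$pos <- suppressWarnings(grab("pos"))
  out$maf <- suppressWarnings(grab("maf"))
  out$beta <- suppressWarnings(grab("beta"))
  if (!need("beta") && need("or")) {
    or <- suppressWarnings(as.numeric(dt[[present[["or"]]]]))
    out$beta <- log(or)
  }
  out$pvalue <- suppressWarnings(grab("pvalue"))
  out$z <- suppressWarnings(grab("z"))

  ok <- !is.na(out$snp_id) & nzchar(out$snp_id)
  if (need("z")) {
    ok <- ok & !is.na(out$z)
  } else {
    ok <- ok & !is.na(out$pvalue) & !is.na(out$beta)
  }
  bad_maf <- !is.na(out$maf) & (out$maf <= 0 | out$maf > 0.5)
  if (any(bad_maf)) {
    message("read_sumstats: ", sum(bad_maf), " row(s) with MAF outside (0, 0.5] dropped")
    ok <- ok & !bad_maf
  }
  n_dropped <- sum(!ok)
  if (n_dropped > 0L)
    message("read_sumstats: dropped ", n_dropped,
            " row(s) with unparseable mandatory fields")
  out <- out[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Convert a two-sided p-value and effect direction to a signed Z-score
#'
#' Computes `sign(beta) * qnorm(1 - p/2)`.  A zero sign yields a zero
#' Z-score.  P-values below `1e-300` are clamped to that floor with a
#' warning (guard against quantile overflow).
#'
#' @param pvalue numeric vector of two-sided p-values in (0, 1].
#' @param beta_sign numeric vector of effect-size signs (-1, 0, +1); any
#'   numeric is reduced to its sign.
#' @return numeric vector of signed Z-scores.
#' @export
zscore_from_p <- function(pvalue, beta_sign) {
  if (any(!is.finite(pvalue)) || any(pvalue <= 0) || any(pvalue > 1))
    stop("pvalue must lie in (0, 1]")
  if (any(pvalue < 1e-300)) {
    warning("p-value(s) below 1e-300 clamped to the 1e-300 floor")
    pvalue <- pmax(pvalue, 1e-300)
  }
  sign(beta_sign) * stats::qnorm(pvalue / 2, lower.tail = FALSE)
}

#' Read gene annotations
#'
#' Two dialects: `"bed"` is BED-like 4-column text (chrom, start, end,
#' gene_id) in 0-based half-open coordinates, converted on input to the
#' package-internal 1-based closed convention (`start + 1`); `"tsv"` is
#' 4-column (gene_id, chrom, start, end) already 1-based closed.
#'
#' @param path file path.
#' @param format `"bed"` or `"tsv"`.
#' @return data.frame with columns gene_id, chrom, start, end (1-based,
#'   closed intervals).
#' @export
read_gene_annotations <- function(path, format = c("bed", "tsv")) {
  format <- match.arg(format)
  dt <- data.table::fread(path, header = FALSE, data.table = FALSE)
  if (ncol(dt) < 4L) stop("gene annotation file needs 4 columns")
  if (format == "bed") {
    out <- data.frame(gene_id = as.character(dt[[4L]]),
                      chrom = as.character(dt[[1L]]),
                      start = as.integer(dt[[2L]]) + 1L,
                      end = as.integer(dt[[3L]]),
                      stringsAsFactors = FALSE)
  } else {
    out <- data.frame(gene_id = as.character(dt[[1L]]),
                      chrom = as.character(dt[[2L]]),
                      start = as.integer(dt[[3L]]),
                      end = as.integer(dt[[4L]]),
                      stringsAsFactors = FALSE)
  }
  if (any(out$start > out$end)) stop("gene annotation with start > end")
  out
}

#' Per-gene summary-statistic container
#'
#' Aligned vectors of SNP ids, Z-scores and (optionally) minor allele
#' frequencies for one gene.
#'
#' @param gene_id gene identifier.
#' @param snps data.frame of SNP records (as from [read_sumstats()]) with a
#'   `z` column; ordering defines the gene's SNP order.
#' @return object of class `gene_summary`: list with `gene_id`, `snps`, `z`,
#'   `maf` (or NULL when any MAF is missing).
#' @export
gene_summary <- function(gene_id, snps) {
  if (nrow(snps) < 1L) stop("gene_summary needs at least one SNP")
  if (!"z" %in% names(snps) || any(is.na(snps$z)))
    stop("gene_summary requires a complete z column; convert p-values first ",
         "with zscore_from_p()")
  maf <- snps$maf
  if (is.null(maf) || any(is.na(maf))) maf <- NULL
  structure(list(gene_id = gene_id, snps = snps,
                 z = as.numeric(snps$z), maf = maf),
            class = "gene_summary")
}

#' @export
print.gene_summary <- function(x, ...) {
  cat(sprintf("gene %s: %d SNP(s)%s\n", x$gene_id, length(x$z),
              if (is.null(x$maf)) ", MAF absent" else ""))
  invisible(x)
}

#' Assign SNPs to genes with a flanking window
#'
#' A SNP belongs to a gene when their chromosomes match and the SNP position
#' falls in `[start - window_bp, end + window_bp]` (1-based, closed, both
#' boundaries inclusive).  A SNP may land in several overlapping genes; genes
#' capturing no SNPs are omitted.
#'
#' @param snps data.frame of SNP records with `chrom` and `pos` (and `z`).
#' @param genes data.frame from [read_gene_annotations()].
#' @param window_bp flank size in base pairs (default 20 kb on each side).
#' @return named list of [gene_summary()] objects.
#' @export
assign_snps_to_genes <- function(snps, genes, window_bp = 20000L) {
  if (any(is.na(snps$pos)) || any(is.na(snps$chrom)))
    stop("SNP records need chrom and pos for gene assignment")
  out <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    hit <- snps$chrom == g$chrom &
      snps$pos >= g$start - window_bp &
      snps$pos <= g$end + window_bp
    if (!any(hit)) next
    sub <- snps[hit, , drop = FALSE]
    sub <- sub[order(sub$pos), , drop = FALSE]
    out[[g$gene_id]] <- gene_summary(g$gene_id, sub)
  }
  out
}

#' Quality-control filter for a gene: MAF cutoff and greedy LD pruning
#'
#' Drops SNPs with MAF below `maf_min`, then prunes LD: SNPs are scanned in
#' order (genomic position by default) and, for any pair with squared
#' correlation above `r2_max`, the later-scanned member is dropped.  The
#' position-based scan keeps the pruning independent of the observed
#' Z-scores, leaving the null distribution untouched; `prune = "zscore"`
#' instead scans by decreasing |Z| (keeps the most significant member of
#' each correlated pair).
#'
#' @param gene a [gene_summary()] object.
#' @param R LD matrix aligned to the gene's SNP order.
#' @param maf_min minimum minor allele frequency (SNPs with missing MAF are
#'   kept when `maf_min > 0` only if the gene carries MAFs).
#' @param r2_max squared-correlation pruning threshold.
#' @param prune scan order policy, `"position"` (default) or `"zscore"`.
#' @return list with elements `gene` (filtered, original SNP order),
#'   `R` (conformally subset), `dropped_maf`, `dropped_ld` (SNP ids), and
#'   `empty` (TRUE when no SNP survives; `gene` and `R` are then NULL).
#' @export
qc_filter <- function(gene, R, maf_min = 0.05, r2_max = 0.5,
                      prune = c("position", "zscore")) {
  prune <- match.arg(prune)
  R <- as_ld_matrix(R)
  M <- length(gene$z)
  if (nrow(R) != M) stop("LD matrix not aligned to gene (", nrow(R),
                         " vs ", M, " SNPs)")
  keep <- rep(TRUE, M)
  dropped_maf <- character()
  if (!is.null(gene$maf)) {
    low <- gene$maf < maf_min
    dropped_maf <- gene$snps$snp_id[low]
    keep[low] <- FALSE
  }
  idx <- which(keep)
  scan_order <- if (prune == "position") idx else idx[order(-abs(gene$z[idx]))]
  r2 <- unclass(R)^2
  alive <- rep(TRUE, M)
  alive[!keep] <- FALSE
  for (k in seq_along(scan_order)) {
    i <- scan_order[k]
    if (!alive[i]) next
    later <- scan_order[-seq_len(k)]
    prune_away <- later[alive[later] & r2[i, later] > r2_max]
    alive[prune_away] <- FALSE
  }
  dropped_ld <- gene$snps$snp_id[keep & !alive]
  survivors <- which(alive)
  if (length(survivors) == 0L)
    return(list(gene = NULL, R = NULL, dropped_maf = dropped_maf,
                dropped_ld = dropped_ld, empty = TRUE))
  sub <- gene$snps[survivors, , drop = FALSE]
  list(gene = gene_summary(gene$gene_id, sub),
       R = as_ld_matrix(unclass(R)[survivors, survivors, drop = FALSE],
                        snp_ids = rownames(R)[survivors]),
       dropped_maf = dropped_maf, dropped_ld = dropped_ld, empty = FALSE)
}

#' Write a gene summary as TSV (audit output)
#'
#' @param gene a [gene_summary()] object.
#' @param path output path.
#' @export
write_gene_summary <- function(gene, path) {
  utils::write.table(gene$snps, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
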