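#' Construct and validate an LD (SNP correlation) matrix
#'
#' An `ld_matrix` is a symmetric, unit-diagonal correlation matrix of SNP
#' dosages, the covariance of the per-SNP Z-scores under the null of no
#' association.  The constructor validates symmetry (to `tol`), forces the
#' diagonal to exactly 1, and attaches SNP identifiers as dimnames.
#'
#' @param x numeric square matrix of pairwise correlations.
#' @param snp_ids optional character vector of SNP identifiers; defaults to
#'   existing row names or `snp1..snpM`.
#' @param psd_repaired logical flag recording whether eigenvalue flooring was
#'   applied (see [psd_repair()]).
#' @param tol symmetry / diagonal tolerance.
#' @return an object of class `ld_matrix` (a numeric matrix).
#' @seealso [ld_from_genotypes()], [psd_repair()], [ld_cholesky()],
#'   [ld_inverse()]
#' @export
as_ld_matrix <- function(x, snp_ids = NULL, psd_repaired = FALSE, tol = 1e-8) {
  x <- as.matrix(x)
  if (nrow(x) != ncol(x)) stop("LD matrix must be square")
  if (max(abs(x - t(x))) > tol) stop("LD matrix is not symmetric (tol ", tol, ")")
  if (max(abs(diag(x) - 1)) > tol) stop("LD matrix diagonal must be 1 (tol ", tol, ")")
  if (max(abs(x)) > 1 + tol) stop("LD matrix entries must lie in [-1, 1]")
  x <- (x + t(x)) / 2
  diag(x) <- 1
  if (is.null(snp_ids)) snp_ids <- rownames(x)
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(nrow(x)))
  if (length(snp_ids) != nrow(x)) stop("snp_ids length does not match matrix dimension")
  dimnames(x) <- list(snp_ids, snp_ids)
  attr(x, "psd_repaired") <- isTRUE(psd_repaired)
  class(x) <- c("ld_matrix", class(matrix()))
  x
}

is_ld_matrix <- function(x) inherits(x, "ld_matrix")

#' @export
print.ld_matrix <- function(x, ...) {
  cat(sprintf("LD matrix: %d SNPs%s\n", nrow(x),
              if (isTRUE(attr(x, "psd_repaired"))) " (PSD-repaired)" else ""))
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x))), drop = FALSE])
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' Estimate an LD matrix from genotype dosages
#'
#' Computes the Pearson correlation matrix of mean-centered dosage columns,
#' the standard LD estimate R = diag(D)^{-1/2} D diag(D)^{-1/2} with
#' D = X'PX and P the centering projection.
#'
#' @param dosages numeric n x M matrix of genotype dosages (individuals in
#'   rows, SNPs in columns); column names are used as SNP ids.
#' @return an [as_ld_matrix()] object with exact unit diagonal.
#' @export
ld_from_genotypes <- function(dosages) {
  dosages <- as.matrix(dosages)
  if (nrow(dosages) < 2L) stop("need at least 2 individuals to estimate LD")
  sds <- apply(dosages, 2L, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(dosages)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop("constant dosage column(s): ", paste(bad, collapse = ", "))
  }
  R <- stats::cor(dosages)
  diag(R) <- 1
  as_ld_matrix(R, snp_ids = colnames(dosages))
}

#' Repair an indefinite correlation matrix by eigenvalue flooring
#'
#' Eigenvalues below `floor` are raised to `floor` and the result is rescaled
#' back to unit diagonal.  A no-op (flag stays `FALSE`) when the matrix is
#' already positive semi-definite at the floor.  Flooring is a deterministic
#' approximation to the nearest-correlation-matrix problem; it is adequate
#' here because downstream use only needs a factorizable null covariance.
#'
#' @param R an LD matrix (see [as_ld_matrix()]).
#' @param floor smallest admissible eigenvalue.
#' @return an `ld_matrix`; `attr(, "psd_repaired")` is `TRUE` when flooring
#'   was applied.
#' @export
psd_repair <- function(R, floor = 1e-8) {
  R <- as_ld_matrix(R)
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) >= floor) return(R)
  v <- pmax(e$values, floor)
  M <- e$vectors %*% (v * t(e$vectors))
  s <- 1 / sqrt(diag(M))
  M <- M * tcrossprod(s)
  diag(M) <- 1
  as_ld_matrix((M + t(M)) / 2, snp_ids = rownames(R), psd_repaired = TRUE)
}

#' Lower-triangular Cholesky factor of an LD matrix
#'
#' Returns lower-triangular D with D D' = R, used to turn i.i.d. standard
#' normal draws L into correlated null Z-scores Z = D L.
#'
#' @param R a positive semi-definite LD matrix.
#' @return lower-triangular numeric matrix with the SNP ids of `R`.
#' @export
ld_cholesky <- function(R) {
  R <- as_ld_matrix(R)
  U <- tryCatch(chol(R), error = function(e)
    stop("LD matrix is not positive definite; run psd_repair() first (",
         conditionMessage(e), ")", call. = FALSE))
  D <- t(U)
  dimnames(D) <- dimnames(R)
  D
}

#' Regularized inverse of an LD matrix
#'
#' Inverts R via its Cholesky factor.  With `ridge = 0` the plain inverse is
#' returned provided the reciprocal condition number exceeds `1e-8`;
#' otherwise, when `auto = TRUE`, a ridge of `1e-6` is added to the diagonal
#' (and noted in a message and the `"ridge"` attribute), else an error asks
#' for explicit regularization or more aggressive LD pruning.
#'
#' @param R a positive semi-definite LD matrix.
#' @param ridge non-negative diagonal inflation; `(R + ridge I)^{-1}` is
#'   returned when positive.
#' @param auto logical; escalate `ridge` to `1e-6` automatically when R is
#'   near-singular and `ridge = 0`.
#' @return the inverse matrix, with attribute `"ridge"` recording the ridge
#'   actually used.
#' @export
ld_inverse <- function(R, ridge = 0, auto = TRUE) {
  R <- as_ld_matrix(psd_repair(R))
  M <- unclass(R)
  if (ridge == 0) {
    rc <- rcond(M)
    if (rc < 1e-8) {
      if (!auto)
        stop("LD matrix is near-singular (rcond = ", signif(rc, 3),
             "); supply a ridge or prune correlated SNPs")
      message("ld_inverse: near-singular LD matrix, escalating ridge to 1e-6")
      ridge <- 1e-6
    }
  }
  Minv <- chol2inv(chol(M + diag(ridge, nrow(M))))
  dimnames(Minv) <- dimnames(R)
  attr(Minv, "ridge") <- ridge
  Minv
}

#' Read a plain-text LD matrix
#'
#' Whitespace-delimited square matrix, with an optional first row of SNP ids
#' (detected by non-numeric tokens).  [write_ld_matrix()] emits the same
#' dialect.
#'
#' @param path file path.
#' @return an `ld_matrix`.
#' @export
read_ld_matrix <- function(path) {
  first <- scan(path, what = character(), nlines = 1L, quiet = TRUE)
  has_header <- any(is.na(suppressWarnings(as.numeric(first))))
  M <- as.matrix(utils::read.table(path, header = has_header,
                                   check.names = FALSE))
  ids <- if (has_header) colnames(M) else NULL
  as_ld_matrix(unname(M), snp_ids = ids)
}

#' Write a plain-text LD matrix
#'
#' @param R an `ld_matrix`.
#' @param path output file path.
#' @param header write the SNP-id header row.
#' @export
write_ld_matrix <- function(R, path, header = TRUE) {
  R <- as_ld_matrix(R)
  con <- file(path, "w")
  on.exit(close(con))
  if (header) writeLines(paste(rownames(R), collapse = " "), con)
  utils::write.table(format(unclass(R), digits = 10, trim = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a genotype dosage matrix
#'
#' Delimited text with a header of SNP ids; rows are individuals.  Variant
#' call format (VCF) parsing is deliberately out of scope: convert to dosages
#' upstream.
#'
#' @param path file path.
#' @return numeric matrix, individuals x SNPs.
#' @export
read_dosages <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  as.matrix(dt)
}
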