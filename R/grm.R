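#' Genomic relatedness matrix (allele-frequency standardized)
#'
#' Computes the standard SNP-based relatedness matrix
#' `G[j,k] = (1/m) * sum_i (x_ij - 2 p_i)(x_ik - 2 p_i) / (2 p_i (1 - p_i))`
#' with `p_i` the alternate-allele frequency estimated from the analyzed
#' lines themselves. Monomorphic SNPs (and SNPs with MAF at or below
#' `maf_floor`) are skipped and the divisor `m` reduced accordingly. The
#' result is symmetric with diagonal close to 1 in expectation for an
#' outbred panel and close to 2 for fully inbred doubled haplotypes.
#'
#' @param geno a [genotype_matrix()] or a complete dosage matrix
#'   (lines x SNPs, no missing values).
#' @param maf_floor SNPs with MAF at or below this are excluded.
#' @return symmetric numeric matrix with line ids as dimnames.
#' @export
compute_grm <- function(geno, maf_floor = 0.0) {
  X <- if (inherits(geno, "genotype_matrix")) geno$dosage else as.matrix(geno)
  if (anyNA(X)) stop("dosages contain missing values; impute first")
  p <- colMeans(X) / 2
  maf <- pmin(p, 1 - p)
  keep <- maf > maf_floor & maf > 0
  if (sum(keep) < 2) stop("fewer than 2 polymorphic SNPs after the MAF floor")
  X <- X[, keep, drop = FALSE]
  p <- p[keep]
  W <- sweep(X, 2, 2 * p, `-`)
  W <- sweep(W, 2, sqrt(2 * p * (1 - p)), `/`)
  G <- tcrossprod(W) / ncol(W)
  dimnames(G) <- list(rownames(X), rownames(X))
  G
}

#' Stabilize a GRM to positive semidefiniteness
#'
#' If the smallest eigenvalue of `grm` is negative, a constant
#' `|min eigenvalue| + epsilon` is added to the diagonal, shifting the whole
#' spectrum upward without changing the eigenvectors. An already-PSD matrix
#' is returned unchanged.
#'
#' @param grm symmetric matrix.
#' @param epsilon diagonal margin added beyond the smallest eigenvalue.
#' @return the (possibly shifted) matrix, with attribute `"shift"` giving
#'   the amount added to the diagonal.
#' @export
stabilize_grm <- function(grm, epsilon = 1e-6) {
  ev <- eigen(grm, symmetric = TRUE, only.values = TRUE)$values
  lam_min <- min(ev)
  if (lam_min >= 0) {
    attr(grm, "shift") <- 0
    return(grm)
  }
  shift <- -lam_min + epsilon
  out <- grm + diag(shift, nrow(grm))
  dimnames(out) <- dimnames(grm)
  attr(out, "shift") <- shift
  out
}

#' Write a GRM in GCTA binary-triple format
#'
#' Writes `<prefix>.grm.bin` (lower-triangle values, single precision),
#' `<prefix>.grm.N.bin` (number of SNPs per pair) and `<prefix>.grm.id`.
#'
#' @param grm symmetric matrix with line ids as dimnames.
#' @param prefix output path prefix.
#' @param n_snps number of SNPs the GRM was computed from.
#' @return `prefix`, invisibly.
#' @export
write_grm_gcta <- function(grm, prefix, n_snps) {
  n <- nrow(grm)
  idx <- which(lower.tri(grm, diag = TRUE), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  vals <- grm[idx]
  con <- file(paste0(prefix, ".grm.bin"), "wb")
  writeBin(as.numeric(vals), con, size = 4)
  close(con)
  con <- file(paste0(prefix, ".grm.N.bin"), "wb")
  writeBin(rep(as.numeric(n_snps), length(vals)), con, size = 4)
  close(con)
  ids <- rownames(grm) %||% paste0("L", seq_len(n))
  utils::write.table(data.frame(fid = ids, iid = ids), paste0(prefix, ".grm.id"),
                     sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}
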