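#' Minor allele frequency of one SNP
#'
#' The alternate-allele frequency is computed over non-missing calls as
#' `sum(dosage) / (2 * n_nonmissing)`; the MAF is the smaller of that
#' frequency and its complement, so it is invariant to swapping the allele
#' labels (`maf(x) == maf(2 - x)`).
#'
#' @param dosages numeric vector of dosages in `{0, 1, 2, NA}`.
#' @return MAF in `[0, 0.5]`.
#' @export
snp_maf <- function(dosages) {
  ok <- !is.na(dosages)
  if (!any(ok)) stop("all dosages missing")
  p <- sum(dosages[ok]) / (2 * sum(ok))
  min(p, 1 - p)
}

qc_report <- function(n_lines_removed = 0L, n_snps_removed_callrate = 0L,
                      n_snps_removed_maf = 0L, n_imputed_cells = 0L,
                      n_modal_fallback = 0L, imputation_concordance = NA_real_) {
  structure(list(n_lines_removed = n_lines_removed,
                 n_snps_removed_callrate = n_snps_removed_callrate,
                 n_snps_removed_maf = n_snps_removed_maf,
                 n_imputed_cells = n_imputed_cells,
                 n_modal_fallback = n_modal_fallback,
                 imputation_concordance = imputation_concordance),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report:\n")
  cat("  lines removed (missingness):", x$n_lines_removed, "\n")
  cat("  SNPs removed (call rate):   ", x$n_snps_removed_callrate, "\n")
  cat("  SNPs removed (MAF):         ", x$n_snps_removed_maf, "\n")
  cat("  cells imputed:              ", x$n_imputed_cells, "\n")
  if (!is.na(x$imputation_concordance))
    cat("  imputation concordance:     ", round(x$imputation_concordance, 4), "\n")
  invisible(x)
}

#' Remove lines with excessive missingness
#'
#' Lines whose fraction of missing calls is strictly greater than
#' `max_missing` are dropped; a line at exactly the threshold is kept. Line
#' missingness is assessed on the unfiltered SNP set, i.e. this filter runs
#' before [filter_snps()].
#'
#' @param geno a [genotype_matrix()].
#' @param max_missing highest tolerated missing fraction per line.
#' @return list with elements `geno` (filtered) and `report` (`qc_report`).
#' @export
filter_lines <- function(geno, max_missing = 0.40) {
  miss <- rowMeans(is.na(geno$dosage))
  keep <- miss <= max_missing
  if (!any(keep)) stop("all lines exceed the missingness threshold")
  out <- geno
  out$dosage <- geno$dosage[keep, , drop = FALSE]
  list(geno = out,
       report = qc_report(n_lines_removed = sum(!keep)))
}

#' Remove SNPs by call rate and minor allele frequency
#'
#' SNPs with call rate strictly below `min_call_rate` are removed first;
#' among the survivors, SNPs with MAF strictly below `min_maf` are removed.
#' Boundary values are retained (strict inequalities).
#'
#' @param geno a [genotype_matrix()].
#' @param min_call_rate minimum fraction of non-missing calls.
#' @param min_maf minimum minor allele frequency.
#' @return list with elements `geno` and `report`.
#' @export
filter_snps <- function(geno, min_call_rate = 0.60, min_maf = 0.05) {
  d <- geno$dosage
  cr <- colMeans(!is.na(d))
  keep1 <- cr >= min_call_rate
  n_cr <- sum(!keep1)
  maf <- rep(0, ncol(d))
  maf[keep1] <- apply(d[, keep1, drop = FALSE], 2, snp_maf)
  keep <- keep1 & maf >= min_maf
  n_maf <- sum(keep1 & !keep)
  if (!any(keep)) stop("all SNPs removed by the call-rate/MAF filters")
  out <- genotype_matrix(d[, keep, drop = FALSE], geno$map[keep, , drop = FALSE])
  list(geno = out,
       report = qc_report(n_snps_removed_callrate = n_cr,
                          n_snps_removed_maf = n_maf))
}

#' LD-kNN imputation of missing genotypes
#'
#' Re-implementation of LD-kNN imputation: for each SNP with missing calls,
#' the `l_snps` SNPs in highest r2 with it are selected; for each line
#' missing that SNP, a missing-aware Manhattan distance to every line
#' observed at the SNP is computed over those `l_snps` markers, and the
#' dosage is imputed by an inverse-distance-weighted vote among the
#' `k_neighbors` nearest lines. Observed cells are never altered. Accuracy
#' is estimated by masking cross-validation: a fraction `cv_fraction` of
#' observed cells is hidden, re-imputed, and compared with the truth.
#'
#' @param geno a [genotype_matrix()]; should already have passed
#'   [filter_snps()] (no monomorphic SNPs).
#' @param k_neighbors number of nearest lines voting.
#' @param l_snps number of LD-informative SNPs used for the distance.
#' @param cv_fraction fraction of observed cells masked for the concordance
#'   estimate (0 disables the cross-validation).
#' @param seed integer seed (controls the masking only).
#' @return list with elements `geno` (complete matrix) and `report`.
#' @export
impute_ld_knn <- function(geno, k_neighbors = 5L, l_snps = 30L,
                          cv_fraction = 0.01, seed = 1L) {
  d <- geno$dosage
  n <- nrow(d); m <- ncol(d)
  ## r2 used only to RANK candidate predictor SNPs: computed on standardized
  ## dosages with missing entries zero-filled (one BLAS crossprod instead of
  ## a pairwise-complete correlation pass over all SNP pairs)
  Z <- scale(d)
  Z[is.na(Z)] <- 0
  Z[, !is.finite(colSums(Z))] <- 0
  r2 <- (crossprod(Z) / (n - 1))^2
  diag(r2) <- -Inf
  r2[is.na(r2)] <- -Inf

  impute_matrix <- function(x, only_cells = NULL) {
    ## returns list(filled matrix, n_modal fallbacks); only_cells (linear
    ## indices) restricts the work to those cells (masking cross-validation)
    n_modal <- 0L
    if (is.null(only_cells)) {
      miss_per_snp <- which(colSums(is.na(x)) > 0)
      target_line <- NULL
    } else {
      cell_snp <- (only_cells - 1L) %/% nrow(x) + 1L
      cell_line <- (only_cells - 1L) %% nrow(x) + 1L
      target_line <- split(cell_line, cell_snp)
      miss_per_snp <- as.integer(names(target_line))
    }
    for (s in miss_per_snp) {
      nb <- order(r2[, s], decreasing = TRUE)[seq_len(min(l_snps, m - 1L))]
      miss_lines <- if (is.null(target_line)) which(is.na(x[, s]))
                    else target_line[[as.character(s)]]
      obs_lines <- which(!is.na(x[, s]))
      if (length(obs_lines) == 0L) { n_modal <- n_modal + length(miss_lines); next }
      A <- x[miss_lines, nb, drop = FALSE]
      B <- x[obs_lines, nb, drop = FALSE]
      obs_votes <- x[obs_lines, s]
      ## missing-aware Manhattan distance, vectorized over the l SNPs:
      ## D[ii, jj] = sum_k |A[ii,k] - B[jj,k]| over pairs observed in both,
      ## rescaled to the full l-SNP length
      n_mi <- length(miss_lines); n_ob <- length(obs_lines)
      ## Manhattan distance over the l SNPs via indicator-matrix products:
      ## |a-b| for a,b in {0,1,2} decomposes as 1*(cross terms at distance 1)
      ## + 2*(0 vs 2); missing entries contribute nothing and the pair count
      ## rescales the sum to the full l-SNP length
      A0 <- (!is.na(A) & A == 0) + 0; A1 <- (!is.na(A) & A == 1) + 0
      A2 <- (!is.na(A) & A == 2) + 0
      B0 <- (!is.na(B) & B == 0) + 0; B1 <- (!is.na(B) & B == 1) + 0
      B2 <- (!is.na(B) & B == 2) + 0
      D <- tcrossprod(A0, B1 + 2 * B2) + tcrossprod(A1, B0 + B2) +
           tcrossprod(A2, 2 * B0 + B1)
      CNT <- tcrossprod(A0 + A1 + A2, B0 + B1 + B2)
      D <- D * length(nb) / pmax(CNT, 1)
      D[CNT == 0] <- Inf
      ## inverse-distance-weighted vote of the k nearest lines, vectorized
      ## across missing lines; ties in distance broken by line order
      W <- matrix(0, n_mi, 3)
      Dw <- D
      rows <- seq_len(n_mi)
      for (t in seq_len(min(k_neighbors, n_ob))) {
        jmin <- max.col(-Dw, ties.method = "first")
        dmin <- Dw[cbind(rows, jmin)]
        w <- 1 / (dmin + 1e-6)
        w[!is.finite(w)] <- 0
        v <- obs_votes[jmin]
        W[, 1] <- W[, 1] + w * (v == 0)
        W[, 2] <- W[, 2] + w * (v == 1)
        W[, 3] <- W[, 3] + w * (v == 2)
        Dw[cbind(rows, jmin)] <- Inf
      }
      tot <- rowSums(W)
      imputed <- c(0, 1, 2)[max.col(W, ties.method = "first")]
      if (any(tot == 0)) {  # no usable neighbor: modal dosage fallback
        tab <- table(obs_votes)
        imputed[tot == 0] <- as.numeric(names(tab)[which.max(tab)])
        n_modal <- n_modal + sum(tot == 0)
      }
      x[cbind(miss_lines, s)] <- imputed
    }
    list(x = x, n_modal = n_modal)
  }

  conc <- NA_real_
  if (cv_fraction > 0) {
    set.seed(derive_seed(seed, "impute_cv"))
    obs_cells <- which(!is.na(d))
    n_mask <- max(1L, round(cv_fraction * length(obs_cells)))
    mask <- sample(obs_cells, n_mask)
    dm <- d
    dm[mask] <- NA
    filled <- impute_matrix(dm, only_cells = mask)$x
    conc <- mean(filled[mask] == d[mask])
  }

  res <- impute_matrix(d)
  n_imputed <- sum(is.na(d))
  out <- geno
  out$dosage <- res$x
  list(geno = out,
       report = qc_report(n_imputed_cells = n_imputed,
                          n_modal_fallback = res$n_modal,
                          imputation_concordance = conc))
}

#' Full genotype quality control
#'
#' Applies, in order, the line-missingness filter, the SNP call-rate and MAF
#' filters, and LD-kNN imputation, merging the three reports.
#'
#' @inheritParams filter_lines
#' @inheritParams filter_snps
#' @inheritParams impute_ld_knn
#' @return list with `geno` (complete, filtered) and `report`.
#' @export
qc_genotypes <- function(geno, max_missing = 0.40, min_call_rate = 0.60,
                         min_maf = 0.05, k_neighbors = 5L, l_snps = 30L,
                         cv_fraction = 0.01, seed = 1L) {
  a <- filter_lines(geno, max_missing)
  b <- filter_snps(a$geno, min_call_rate, min_maf)
  c_ <- impute_ld_knn(b$geno, k_neighbors, l_snps, cv_fraction, seed)
  rep <- qc_report(n_lines_removed = a$report$n_lines_removed,
                   n_snps_removed_callrate = b$report$n_snps_removed_callrate,
                   n_snps_removed_maf = b$report$n_snps_removed_maf,
                   n_imputed_cells = c_$report$n_imputed_cells,
                   n_modal_fallback = c_$report$n_modal_fallback,
                   imputation_concordance = c_$report$imputation_concordance)
  list(geno = c_$geno, report = rep)
}
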