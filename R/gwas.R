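#' Null-model variance-ratio fit for the mixed-model scan
#'
#' REML estimate of `lambda = vg / ve` under the covariate-only model
#' (intercept), via the GRM eigendecomposition and a one-dimensional
#' profile-likelihood search. This is the variance ratio reused across all
#' SNPs in the `null_lambda` scan mode.
#'
#' @param y named numeric vector of line values (BLUEs).
#' @param grm GRM covering the lines of `y`.
#' @param eig optional precomputed eigendecomposition.
#' @return list with `lambda_ratio` (on the scale of the GRM as supplied,
#'   ready for the scan's covariance `lambda G + I`), `loglik`, `h2`
#'   (unit-mean-diagonal scale), `n_used`, `boundary`.
#' @export
fit_null <- function(y, grm, eig = NULL) {
  fit <- greml_univariate(y, grm, eig = eig)
  ## greml_univariate works on the unit-mean-diagonal rescaling of G;
  ## convert the variance ratio back to the raw-G scale used by the scan
  tr_fac <- if (is.null(eig)) {
    ids <- if (!is.null(names(y)) && !is.null(rownames(grm)))
      intersect(names(y)[!is.na(y)], rownames(grm)) else which(!is.na(y))
    length(ids) / sum(diag(grm[ids, ids]))
  } else length(eig$values) / sum(eig$values)
  list(lambda_ratio = fit$vg / fit$ve * tr_fac, loglik = fit$loglik,
       h2 = fit$h2, n_used = fit$n_used, boundary = fit$boundary)
}

## REML criterion for the two-fixed-effect (intercept + SNP) model, vectorized
## over SNPs at a single lambda. Returns per-SNP loglik, beta, se, sigma2.
scan_at_lambda <- function(lambda, d, ystar, onestar, Xs, poly) {
  n <- length(ystar)
  v <- lambda * d + 1
  w <- 1 / v
  S11 <- sum(w * onestar^2)
  S1y <- sum(w * onestar * ystar)
  Syy <- sum(w * ystar^2)
  wX <- Xs * w
  S1x <- as.numeric(crossprod(wX, onestar))
  Sxx <- colSums(Xs * wX)
  Sxy <- as.numeric(crossprod(wX, ystar))
  det <- S11 * Sxx - S1x^2
  det[!poly] <- NA
  beta <- (S11 * Sxy - S1x * S1y) / det
  b0 <- (Sxx * S1y - S1x * Sxy) / det
  rss <- Syy - (b0 * S1y + beta * Sxy)
  rss[rss < 0] <- 0
  sigma2 <- rss / (n - 2)
  se <- sqrt(sigma2 * S11 / det)
  ll <- -0.5 * ((n - 2) * (log(2 * pi * sigma2) + 1) + sum(log(v)) + log(det))
  list(ll = ll, beta = beta, se = se, sigma2 = sigma2)
}

#' Mixed-linear-model association scan
#'
#' For each SNP, tests the fixed allelic-substitution effect in
#' `y = mu + x beta + g + e`, `g ~ N(0, ve * lambda * G)`, by generalized
#' least squares under the covariance `ve * (lambda G + I)`. Two modes:
#'
#' * `per_snp_lambda` (default): `lambda` is re-optimized by REML for every
#'   SNP on a 61-point log grid spanning `1e-5 .. 1e5`, followed by local
#'   golden-section refinement — the exact-mixed-model strategy.
#' * `null_lambda`: the null-model `lambda` from [fit_null()] (or the
#'   `lambda` argument) is reused for all SNPs — the fast approximation in
#'   the EMMAX/P3D tradition.
#'
#' The Wald statistic `t = beta / se(beta)` is referred to a Student-t
#' distribution with `n - 2` degrees of freedom. The alternate allele is the
#' effect allele throughout, so signs are comparable across analyses.
#' Monomorphic SNPs in the analyzed line subset are reported with
#' `beta = 0`, `p = 1` and flagged, keeping downstream t-matrices
#' rectangular.
#'
#' @param y named numeric vector of line values; `NA`s dropped pairwise.
#' @param geno [genotype_matrix()] with complete dosages.
#' @param grm GRM covering the lines of `y`.
#' @param mode `"per_snp_lambda"` or `"null_lambda"`.
#' @param lambda optional fixed variance ratio for `null_lambda` mode
#'   (default: estimated by [fit_null()]).
#' @param refine refine the per-SNP grid optimum by golden-section search.
#' @param eig optional precomputed eigendecomposition of `grm` over the
#'   analyzed lines.
#' @return data.frame with columns `snp_id`, `chrom`, `pos_bp`, `pos_cm`,
#'   `allele_ref`, `allele_alt`, `af`, `n_used`, `beta`, `se`, `t`, `p`,
#'   `lambda`, `flag`.
#' @export
mlm_scan <- function(y, geno, grm, mode = c("per_snp_lambda", "null_lambda"),
                     lambda = NULL, refine = TRUE, eig = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(geno, "genotype_matrix"))
  if (anyNA(geno$dosage)) stop("dosages contain missing values; impute first")
  ids <- names(y)[!is.na(y)]
  if (is.null(ids)) stop("y must be a named vector of line values")
  ids <- intersect(ids, rownames(geno$dosage))
  if (!is.null(rownames(grm))) ids <- intersect(ids, rownames(grm))
  y <- y[ids]
  X <- geno$dosage[ids, , drop = FALSE]
  n <- length(ids)
  m <- ncol(X)
  if (is.null(eig)) eig <- grm_eigen(grm[ids, ids])
  d <- eig$values
  U <- eig$vectors
  ystar <- as.numeric(crossprod(U, y))
  onestar <- colSums(U)
  Xs <- crossprod(U, X)
  af <- colMeans(X) / 2
  poly <- apply(X, 2, function(x) length(unique(x)) > 1)

  lam_vec <- rep(NA_real_, m)
  if (mode == "null_lambda") {
    if (is.null(lambda)) lambda <- fit_null(y, grm, eig = eig)$lambda_ratio
    res <- scan_at_lambda(lambda, d, ystar, onestar, Xs, poly)
    beta <- res$beta; se <- res$se
    lam_vec[] <- lambda
  } else {
    grid <- 10^seq(-5, 5, length.out = 61)
    best_ll <- rep(-Inf, m)
    best_lam <- rep(grid[1], m)
    for (lam in grid) {
      r <- scan_at_lambda(lam, d, ystar, onestar, Xs, poly)
      upd <- !is.na(r$ll) & r$ll > best_ll
      best_ll[upd] <- r$ll[upd]
      best_lam[upd] <- lam
    }
    if (refine) {
      gi <- match(best_lam, grid)
      lo <- grid[pmax(gi - 1L, 1L)]
      hi <- grid[pmin(gi + 1L, length(grid))]
      for (j in which(poly)) {
        xsj <- Xs[, j, drop = FALSE]
        o <- stats::optimize(function(ll_lam)
          scan_at_lambda(exp(ll_lam), d, ystar, onestar, xsj, TRUE)$ll,
          c(log(lo[j]), log(hi[j])), maximum = TRUE, tol = 1e-6)
        if (o$objective > best_ll[j]) {
          best_ll[j] <- o$objective
          best_lam[j] <- exp(o$maximum)
        }
      }
    }
    beta <- se <- rep(NA_real_, m)
    for (lam in unique(best_lam)) {
      jj <- which(best_lam == lam & poly)
      if (!length(jj)) next
      r <- scan_at_lambda(lam, d, ystar, onestar, Xs[, jj, drop = FALSE],
                          rep(TRUE, length(jj)))
      beta[jj] <- r$beta
      se[jj] <- r$se
    }
    lam_vec <- best_lam
  }

  t_stat <- beta / se
  p <- 2 * stats::pt(-abs(t_stat), df = n - 2)
  flag <- ifelse(poly, "", "monomorphic")
  beta[!poly] <- 0
  t_stat[!poly] <- 0
  p[!poly] <- 1
  se[!poly] <- NA_real_
  lam_vec[!poly] <- NA_real_
  data.frame(snp_id = geno$map$snp_id, chrom = geno$map$chrom,
             pos_bp = geno$map$pos_bp, pos_cm = geno$map$pos_cm,
             allele_ref = geno$map$allele_ref, allele_alt = geno$map$allele_alt,
             af = af, n_used = n, beta = beta, se = se, t = t_stat, p = p,
             lambda = lam_vec, flag = flag,
             stringsAsFactors = FALSE, row.names = NULL)
}
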