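## Shared eigen-rotation helper: GREML and the MLM scan both work in the
## basis that diagonalizes the GRM, where the covariance lambda*G + I is
## diagonal and every likelihood evaluation costs O(n).
grm_eigen <- function(grm) {
  ed <- eigen(grm, symmetric = TRUE)
  ed$values <- pmax(ed$values, 0)
  ed
}

## REML log-likelihood of y = X b + g + e with Var = sigma_e^2 (lambda G + I),
## evaluated in the rotated basis. Profiles sigma_e^2 out. Returns the
## criterion and the profiled quantities.
reml_profile <- function(lambda, d, ystar, Xstar) {
  n <- length(ystar)
  p <- ncol(Xstar)
  v <- lambda * d + 1
  w <- 1 / v
  XtWX <- crossprod(Xstar, Xstar * w)
  XtWy <- crossprod(Xstar, ystar * w)
  b <- solve(XtWX, XtWy)
  r <- ystar - Xstar %*% b
  ypy <- sum(r^2 * w)
  sigma2 <- ypy / (n - p)
  ll <- -0.5 * ((n - p) * (log(2 * pi * sigma2) + 1) +
                sum(log(v)) + determinant(XtWX, logarithm = TRUE)$modulus[1])
  list(ll = as.numeric(ll), sigma2 = sigma2, b = b, XtWX = XtWX)
}

#' Univariate GREML: SNP-based heritability
#'
#' Fits `y = mu + g + e` with `g ~ N(0, vg G)` and `e ~ N(0, ve I)` by
#' restricted maximum likelihood. After one eigendecomposition of the GRM
#' the likelihood is profiled over `h2 = vg / (vg + ve)` on `[0, 1]` and
#' maximized by golden-section/parabolic search; the standard error of
#' `h2` comes from the numerical curvature of the profile likelihood.
#'
#' The GRM is rescaled to unit mean diagonal before fitting (when
#' `normalize = TRUE`, the default), so `h2 = vg / (vg + ve)` reads as the
#' fraction of line-value variance that is genetic irrespective of the
#' panel's inbreeding: a fully inbred panel has a raw relatedness diagonal
#' near 2, which would otherwise halve the apparent `vg`.
#'
#' @param y named numeric vector of line values (BLUEs); `NA`s dropped.
#' @param grm GRM covering (at least) the lines of `y`.
#' @param eig optional precomputed `eigen()` of the GRM restricted to the
#'   used lines, to amortize across many fits on one line set.
#' @param normalize rescale the GRM to unit mean diagonal (see Details).
#' @return object of class `h2_estimate`: list with `vg`, `ve`, `h2`,
#'   `se_h2`, `loglik`, `n_used`, `converged`, `boundary`.
#' @export
greml_univariate <- function(y, grm, eig = NULL, normalize = TRUE) {
  if (!is.null(names(y)) && !is.null(rownames(grm))) {
    ids <- intersect(names(y)[!is.na(y)], rownames(grm))
    y <- y[ids]
    if (is.null(eig)) grm <- grm[ids, ids]
  } else {
    keep <- !is.na(y)
    y <- y[keep]
    if (is.null(eig)) grm <- grm[keep, keep]
  }
  n <- length(y)
  if (n < 10) stop("too few lines with phenotype and GRM entry")
  if (is.null(eig)) eig <- grm_eigen(grm)
  d <- eig$values
  if (normalize) d <- d * length(d) / sum(d)  # trace(G)/n -> 1
  ystar <- as.numeric(crossprod(eig$vectors, y))
  Xstar <- matrix(colSums(eig$vectors), ncol = 1)  # rotated intercept

  obj <- function(h2) {
    lam <- h2 / (1 - h2)
    reml_profile(lam, d, ystar, Xstar)$ll
  }
  lo <- 1e-6; hi <- 1 - 1e-6
  opt <- stats::optimize(obj, c(lo, hi), maximum = TRUE, tol = 1e-9)
  h2 <- opt$maximum; ll <- opt$objective
  boundary <- FALSE
  for (hb in c(lo, hi)) {
    llb <- obj(hb)
    if (llb > ll) { h2 <- hb; ll <- llb; boundary <- TRUE }
  }
  if (h2 < 2 * lo || h2 > 1 - 2 * lo) boundary <- TRUE
  prof <- reml_profile(h2 / (1 - h2), d, ystar, Xstar)
  ve <- prof$sigma2
  vg <- ve * h2 / (1 - h2)
  ## curvature-based SE on the interior only
  se_h2 <- NA_real_
  if (!boundary) {
    eps <- 1e-4
    curv <- (obj(h2 + eps) - 2 * ll + obj(h2 - eps)) / eps^2
    if (is.finite(curv) && curv < 0) se_h2 <- sqrt(-1 / curv)
  }
  structure(list(vg = vg, ve = ve, h2 = h2, se_h2 = se_h2, loglik = ll,
                 n_used = n, converged = TRUE, boundary = boundary),
            class = "h2_estimate")
}

#' @export
print.h2_estimate <- function(x, ...) {
  cat(sprintf("GREML h2 = %.4f (se %.4f), vg = %.4f, ve = %.4f, n = %d%s\n",
              x$h2, x$se_h2, x$vg, x$ve, x$n_used,
              if (x$boundary) " [boundary]" else ""))
  invisible(x)
}

## Bivariate REML log-likelihood in the rotated basis: per eigenvalue d_i the
## 2x2 covariance is d_i*Vg + Ve; fixed effects are one intercept per trait.
biv_loglik <- function(Vg, Ve, d, Y, xst) {
  g11 <- Vg[1, 1]; g12 <- Vg[1, 2]; g22 <- Vg[2, 2]
  e11 <- Ve[1, 1]; e12 <- Ve[1, 2]; e22 <- Ve[2, 2]
  a <- d * g11 + e11
  b <- d * g12 + e12
  cc <- d * g22 + e22
  det <- a * cc - b * b
  if (any(det <= 0) || any(a <= 0) || any(cc <= 0)) return(-Inf)
  ia <- cc / det; ib <- -b / det; ic <- a / det
  x2 <- xst^2
  ## X' V^-1 X for X = diag-per-trait intercepts (2x2)
  A11 <- sum(x2 * ia); A12 <- sum(x2 * ib); A22 <- sum(x2 * ic)
  r1 <- sum(xst * (ia * Y[, 1] + ib * Y[, 2]))
  r2 <- sum(xst * (ib * Y[, 1] + ic * Y[, 2]))
  detA <- A11 * A22 - A12^2
  if (detA <= 0) return(-Inf)
  b1 <- (A22 * r1 - A12 * r2) / detA
  b2 <- (A11 * r2 - A12 * r1) / detA
  e1 <- Y[, 1] - xst * b1
  e2 <- Y[, 2] - xst * b2
  quad <- sum(ia * e1^2 + 2 * ib * e1 * e2 + ic * e2^2)
  n2 <- 2 * length(d)
  -0.5 * (quad + sum(log(det)) + log(detA) + (n2 - 2) * log(2 * pi))
}

theta_to_cov <- function(th) {
  L <- matrix(c(exp(th[1]), th[2], 0, exp(th[3])), 2, 2)
  tcrossprod(L)
}

#' Bivariate GREML: genetic correlation between two traits
#'
#' Fits the two-trait model with 2x2 genetic and residual covariance
#' matrices (Cholesky-parameterized, so both stay positive definite during
#' optimization) by REML in the GRM eigenbasis, and reports
#' `rg = Vg12 / sqrt(Vg11 Vg22)`, clipped to `[-1, 1]`.
#'
#' Lines are used complete-case: only lines observed for both traits enter.
#' Exactly collinear traits make the bivariate likelihood unbounded
#' (residual correlation tends to 1); that degenerate case is detected and
#' the fit collapses to the univariate model, returning `rg = +/-1` and the
#' univariate heritability for both traits.
#'
#' @param y1,y2 named numeric vectors of line values.
#' @param grm GRM covering the shared lines.
#' @param eig optional precomputed eigen decomposition for the shared line
#'   set (as from `eigen(grm[ids, ids], symmetric = TRUE)`).
#' @return object of class `rg_estimate`: list with `rg`, `Vg`, `Ve`,
#'   `h2_1`, `h2_2`, `loglik`, `n_used`, `converged`, `collinear`,
#'   `clipped`.
#' @export
greml_bivariate <- function(y1, y2, grm, eig = NULL) {
  if (!is.null(names(y1)) && !is.null(names(y2))) {
    ids <- intersect(names(y1)[!is.na(y1)], names(y2)[!is.na(y2)])
    if (!is.null(rownames(grm))) ids <- intersect(ids, rownames(grm))
    y1 <- y1[ids]; y2 <- y2[ids]
    if (is.null(eig)) grm <- grm[ids, ids]
  } else {
    keep <- !is.na(y1) & !is.na(y2)
    y1 <- y1[keep]; y2 <- y2[keep]
    if (is.null(eig)) grm <- grm[keep, keep]
  }
  n <- length(y1)
  if (n < 10) stop("too few lines observed for both traits")

  r_pheno <- stats::cor(y1, y2)
  if (abs(r_pheno) > 1 - 1e-8) {
    uni <- greml_univariate(y = stats::setNames(y1, NULL), grm = grm, eig = eig)
    rg <- sign(r_pheno)
    Vg <- matrix(c(uni$vg, rg * uni$vg, rg * uni$vg, uni$vg), 2)
    Ve <- matrix(c(uni$ve, rg * uni$ve, rg * uni$ve, uni$ve), 2)
    return(structure(list(rg = rg, Vg = Vg, Ve = Ve,
                          h2_1 = uni$h2, h2_2 = uni$h2,
                          loglik = NA_real_, n_used = n, converged = TRUE,
                          collinear = TRUE, clipped = FALSE),
                     class = "rg_estimate"))
  }

  if (is.null(eig)) eig <- grm_eigen(grm)
  d <- eig$values * length(eig$values) / sum(eig$values)  # unit mean diagonal
  U <- eig$vectors
  Y <- cbind(as.numeric(crossprod(U, y1)), as.numeric(crossprod(U, y2)))
  xst <- colSums(U)

  ## initialize from univariate fits
  u1 <- greml_univariate(stats::setNames(y1, NULL), grm, eig = eig)
  u2 <- greml_univariate(stats::setNames(y2, NULL), grm, eig = eig)
  init <- c(0.5 * log(max(u1$vg, 1e-4)), 0, 0.5 * log(max(u2$vg, 1e-4)),
            0.5 * log(max(u1$ve, 1e-4)), 0, 0.5 * log(max(u2$ve, 1e-4)))
  nll <- function(th) {
    ll <- biv_loglik(theta_to_cov(th[1:3]), theta_to_cov(th[4:6]), d, Y, xst)
    if (!is.finite(ll)) 1e10 else -ll
  }
  o1 <- stats::optim(init, nll, method = "Nelder-Mead",
                     control = list(maxit = 2000, reltol = 1e-12))
  o2 <- stats::optim(o1$par, nll, method = "BFGS",
                     control = list(maxit = 200, reltol = 1e-12))
  best <- if (o2$value <= o1$value) o2 else o1
  Vg <- theta_to_cov(best$par[1:3])
  Ve <- theta_to_cov(best$par[4:6])
  denom <- sqrt(Vg[1, 1] * Vg[2, 2])
  h2_1 <- Vg[1, 1] / (Vg[1, 1] + Ve[1, 1])
  h2_2 <- Vg[2, 2] / (Vg[2, 2] + Ve[2, 2])
  if (denom < 1e-8 || h2_1 < 1e-4 || h2_2 < 1e-4) {
    return(structure(list(rg = NA_real_, Vg = Vg, Ve = Ve,
                          h2_1 = h2_1, h2_2 = h2_2, loglik = -best$value,
                          n_used = n, converged = FALSE, collinear = FALSE,
                          clipped = FALSE),
                     class = "rg_estimate"))
  }
  rg_raw <- Vg[1, 2] / denom
  rg <- max(-1, min(1, rg_raw))
  structure(list(rg = rg, Vg = Vg, Ve = Ve, h2_1 = h2_1, h2_2 = h2_2,
                 loglik = -best$value, n_used = n,
                 converged = o2$convergence == 0 || o1$convergence == 0,
                 collinear = FALSE, clipped = rg != rg_raw),
            class = "rg_estimate")
}

#' @export
print.rg_estimate <- function(x, ...) {
  cat(sprintf("bivariate GREML rg = %.4f (h2: %.3f / %.3f, n = %d)%s%s\n",
              x$rg, x$h2_1, x$h2_2, x$n_used,
              if (!x$converged) " [not converged]" else "",
              if (isTRUE(x$collinear)) " [collinear traits]" else ""))
  invisible(x)
}

#' Average genetic-correlation estimates across trials
#'
#' Implements the trial-averaging step: each pairwise genetic correlation is
#' estimated per field trial (or per trial pair, for the same element across
#' environments) and the estimates are combined by an unweighted arithmetic
#' mean. Non-converged estimates are excluded and counted.
#'
#' @param estimates list of `rg_estimate` objects, or a numeric vector of rg
#'   values with an optional logical `converged` attribute vector.
#' @return list with `mean_rg`, `n_used`, `n_excluded`.
#' @export
average_rg <- function(estimates) {
  if (length(estimates) == 0L) stop("no estimates to average")
  if (is.numeric(estimates)) {
    vals <- estimates
    conv <- rep(TRUE, length(vals))
  } else {
    vals <- vapply(estimates, function(e) e$rg, 0.0)
    conv <- vapply(estimates, function(e) isTRUE(e$converged), TRUE)
  }
  use <- conv & !is.na(vals)
  if (!any(use)) stop("no converged estimates to average")
  list(mean_rg = mean(vals[use]), n_used = sum(use), n_excluded = sum(!use))
}

#' Group elements by their averaged genetic correlations
#'
#' Clusters elements by average-linkage hierarchical clustering on the
#' distance `1 - rg`, cuts the tree into `k` groups, then applies any manual
#' `overrides` (element -> group index) last, recording them. Group labels
#' are canonicalized so that group 1 is the one containing the
#' alphabetically first element.
#'
#' @param avg_rg square symmetric matrix of averaged genetic correlations,
#'   with element names as dimnames.
#' @param k number of groups.
#' @param overrides named list or vector mapping element names to group
#'   indices, applied after clustering.
#' @return object of class `element_grouping`: list with `groups` (named
#'   integer vector), `members` (list of element vectors per group),
#'   `overrides`, `hclust`.
#' @export
group_elements <- function(avg_rg, k = 2L, overrides = NULL) {
  stopifnot(is.matrix(avg_rg), nrow(avg_rg) == ncol(avg_rg))
  if (k > nrow(avg_rg)) stop("k exceeds the number of elements")
  el <- rownames(avg_rg) %||% paste0("E", seq_len(nrow(avg_rg)))
  dmat <- 1 - avg_rg
  dmat[dmat < 0] <- 0
  hc <- stats::hclust(stats::as.dist(dmat), method = "average")
  grp <- stats::cutree(hc, k = k)
  names(grp) <- el
  ## canonical labels (relabel so the alphabetically first element sits in
  ## group 1) applied before overrides, so an override group index refers to
  ## the canonical numbering
  seen <- unique(unname(grp[order(names(grp))]))
  relab <- stats::setNames(seq_along(seen), seen)
  grp <- stats::setNames(as.integer(relab[as.character(grp)]), names(grp))
  if (!is.null(overrides)) {
    for (nm in names(overrides)) {
      if (!nm %in% el) stop("override for unknown element: ", nm)
      grp[nm] <- as.integer(overrides[[nm]])
    }
  }
  members <- split(names(grp), grp)
  structure(list(groups = grp, members = members,
                 overrides = overrides, hclust = hc),
            class = "element_grouping")
}

#' @export
print.element_grouping <- function(x, ...) {
  for (g in names(x$members))
    cat("group ", g, ": ", paste(x$members[[g]], collapse = ", "), "\n", sep = "")
  if (length(x$overrides))
    cat("overrides: ", paste(names(x$overrides), unlist(x$overrides),
                             sep = "->", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Heritability and genetic-correlation survey across all trials
#'
#' Runs univariate GREML for every element-by-environment analysis and
#' bivariate GREML for every element pair within each environment, then
#' averages the correlations across trials into an element-by-element
#' matrix (the between-element analogue of a trial-averaged correlation
#' table).
#'
#' @param blues_mat matrix from [blues_matrix()] (lines x `element:env`).
#' @param grm full-panel GRM.
#' @param elements optional element order; defaults to those found.
#' @param min_lines minimum complete-case lines for a bivariate fit.
#' @param verbose print progress.
#' @return list with `h2` (data.frame env, element, vg, ve, h2, se_h2),
#'   `rg` (data.frame env, element_a, element_b, rg, n, converged), and
#'   `avg_rg` (elements x elements matrix; diagonal holds the per-element
#'   mean across-environment correlation where computable, else 1).
#' @export
greml_survey <- function(blues_mat, grm, elements = NULL, min_lines = 30L,
                         verbose = FALSE) {
  parts <- strsplit(colnames(blues_mat), ":", fixed = TRUE)
  el <- vapply(parts, `[`, "", 1L)
  env <- vapply(parts, `[`, "", 2L)
  if (is.null(elements)) elements <- unique(el)
  envs <- unique(env)

  ## per-environment eigendecomposition, shared across fits on one line set
  eig_cache <- list()
  eig_for <- function(ids) {
    key <- paste(length(ids), ids[1], ids[length(ids)])
    if (is.null(eig_cache[[key]]))
      eig_cache[[key]] <<- grm_eigen(grm[ids, ids])
    eig_cache[[key]]
  }

  h2_rows <- list(); rg_rows <- list()
  for (e_i in envs) {
    cols <- which(env == e_i)
    for (ci in cols) {
      y <- blues_mat[, ci]
      ids <- names(y)[!is.na(y)]
      ids <- intersect(ids, rownames(grm))
      fit <- greml_univariate(y[ids], grm[ids, ids], eig = eig_for(ids))
      h2_rows[[length(h2_rows) + 1L]] <-
        data.frame(env = e_i, element = el[ci], vg = fit$vg, ve = fit$ve,
                   h2 = fit$h2, se_h2 = fit$se_h2, stringsAsFactors = FALSE)
    }
    if (length(cols) >= 2) {
      for (ai in seq_along(cols)) for (bi in seq_along(cols)) {
        if (bi <= ai) next
        ca <- cols[ai]; cb <- cols[bi]
        ya <- blues_mat[, ca]; yb <- blues_mat[, cb]
        ids <- intersect(names(ya)[!is.na(ya)], names(yb)[!is.na(yb)])
        ids <- intersect(ids, rownames(grm))
        if (length(ids) < min_lines) next
        if (verbose) message(e_i, ": ", el[ca], " x ", el[cb])
        fit <- tryCatch(
          greml_bivariate(ya[ids], yb[ids], grm[ids, ids], eig = eig_for(ids)),
          error = function(e) NULL)
        if (is.null(fit)) next
        rg_rows[[length(rg_rows) + 1L]] <-
          data.frame(env = e_i, element_a = el[ca], element_b = el[cb],
                     rg = fit$rg, n = fit$n_used, converged = fit$converged,
                     stringsAsFactors = FALSE)
      }
    }
  }
  h2 <- do.call(rbind, h2_rows)
  rg <- do.call(rbind, rg_rows)

  avg <- matrix(NA_real_, length(elements), length(elements),
                dimnames = list(elements, elements))
  diag(avg) <- 1
  if (!is.null(rg)) {
    for (a in elements) for (b in elements) {
      if (a == b) next
      sub <- rg[(rg$element_a == a & rg$element_b == b) |
                (rg$element_a == b & rg$element_b == a), ]
      sub <- sub[sub$converged & !is.na(sub$rg), ]
      if (nrow(sub)) avg[a, b] <- mean(sub$rg)
    }
  }
  list(h2 = h2, rg = rg, avg_rg = avg)
}
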