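#' Pairwise linkage disequilibrium r2 of two SNPs
#'
#' Squared Pearson correlation of dosages over pairwise-complete lines —
#' the genotype-correlation form of the classical r2, which needs no
#' phasing and is invariant to allele relabeling of either SNP.
#'
#' @param x,y dosage vectors over the same lines (`NA` allowed).
#' @return r2 in `[0, 1]`, or `NA` if either SNP is monomorphic on the
#'   shared non-missing lines.
#' @export
pair_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) return(NA_real_)
  xs <- x[ok]; ys <- y[ok]
  if (stats::var(xs) == 0 || stats::var(ys) == 0) return(NA_real_)
  stats::cor(xs, ys)^2
}

## fast r2 for many pairs on a complete dosage matrix: standardized columns,
## then colSums of products, chunked to bound memory
pairs_r2_fast <- function(X, i_idx, j_idx, chunk = 20000L) {
  Z <- scale(X)
  n <- nrow(X)
  sd0 <- attr(Z, "scaled:scale") == 0
  out <- numeric(length(i_idx))
  for (s in seq(1L, length(i_idx), by = chunk)) {
    e <- min(s + chunk - 1L, length(i_idx))
    ii <- i_idx[s:e]; jj <- j_idx[s:e]
    r <- colSums(Z[, ii, drop = FALSE] * Z[, jj, drop = FALSE]) / (n - 1)
    out[s:e] <- r^2
  }
  out[sd0[i_idx] | sd0[j_idx]] <- NA_real_
  out
}

#' Sample intra-chromosomal SNP pairs with their distances and r2
#'
#' All same-chromosome pairs when the per-chromosome total is at or below
#' `max_pairs_per_chrom`; otherwise a uniform random subset of that size.
#'
#' @param geno [genotype_matrix()]; complete dosages give the fast path,
#'   missing values fall back to pairwise-complete correlations.
#' @param max_pairs_per_chrom sampling cap per chromosome.
#' @param seed integer seed for the subsampling.
#' @return data.frame `snp_a`, `snp_b`, `chrom`, `dist_bp`, `r2`.
#' @export
sample_intra_pairs <- function(geno, max_pairs_per_chrom = 200000L, seed = 1L) {
  set.seed(derive_seed(seed, "intra_pairs"))
  map <- geno$map
  X <- geno$dosage
  complete <- !anyNA(X)
  out <- list()
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    m <- length(idx)
    if (m < 2) next
    total <- m * (m - 1) / 2
    if (total <= max_pairs_per_chrom) {
      cmb <- utils::combn(m, 2L)
      ii <- cmb[1, ]; jj <- cmb[2, ]
    } else {
      k <- sample(total, max_pairs_per_chrom)
      ## map linear index k (1-based, column-major over i<j) to (i, j)
      jj <- ceiling((1 + sqrt(1 + 8 * k)) / 2)
      ii <- k - (jj - 1) * (jj - 2) / 2
    }
    gi <- idx[ii]; gj <- idx[jj]
    r2 <- if (complete) pairs_r2_fast(X, gi, gj)
          else mapply(function(a, b) pair_r2(X[, a], X[, b]), gi, gj)
    out[[ch]] <- data.frame(snp_a = map$snp_id[gi], snp_b = map$snp_id[gj],
                            chrom = ch,
                            dist_bp = abs(map$pos_bp[gj] - map$pos_bp[gi]),
                            r2 = r2, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Background (critical) LD from inter-chromosomal SNP pairs
#'
#' r2 is computed for `n_pairs` random pairs of SNPs on different
#' chromosomes; the background LD is the `quantile` empirical quantile of
#' those values (linear-interpolation convention, R type 7). LD above this
#' value is attributed to linkage rather than chance or structure.
#'
#' @param geno [genotype_matrix()] with at least two chromosomes.
#' @param n_pairs number of inter-chromosomal pairs sampled.
#' @param quantile empirical quantile reported.
#' @param seed integer seed.
#' @return the background r2 value, with attribute `"r2"` holding the
#'   sampled values.
#' @export
background_ld <- function(geno, n_pairs = 100000L, quantile = 0.99, seed = 1L) {
  map <- geno$map
  if (length(unique(map$chrom)) < 2)
    stop("background LD needs at least two chromosomes")
  set.seed(derive_seed(seed, "background_ld"))
  m <- nrow(map)
  ii <- sample.int(m, n_pairs, replace = TRUE)
  jj <- sample.int(m, n_pairs, replace = TRUE)
  bad <- map$chrom[ii] == map$chrom[jj]
  while (any(bad)) {
    jj[bad] <- sample.int(m, sum(bad), replace = TRUE)
    bad <- map$chrom[ii] == map$chrom[jj]
  }
  X <- geno$dosage
  r2 <- if (!anyNA(X)) pairs_r2_fast(X, ii, jj)
        else mapply(function(a, b) pair_r2(X[, a], X[, b]), ii, jj)
  r2 <- r2[!is.na(r2)]
  bg <- as.numeric(stats::quantile(r2, quantile, type = 7))
  attr(bg, "r2") <- r2
  bg
}

#' Loess-smoothed LD decay curve
#'
#' Local quadratic (degree-2) regression of r2 on inter-SNP distance with
#' tricube weights, evaluated on a uniform grid from 0 to the maximum
#' distance. If the span is too small for the local fits it is widened with
#' a warning.
#'
#' @param pairs data.frame from [sample_intra_pairs()] (`dist_bp`, `r2`).
#' @param span loess span (fraction of points in each local fit).
#' @param grid_points number of grid evaluations.
#' @param background optional background r2, stored in the curve and used
#'   by [block_size()].
#' @return object of class `ld_decay`: list with `grid_bp`, `smoothed_r2`,
#'   `span`, `degree`, `background`, `block_size_bp`.
#' @export
loess_decay <- function(pairs, span = 0.5, grid_points = 200L,
                        background = NULL) {
  d <- pairs[!is.na(pairs$r2), c("dist_bp", "r2")]
  if (nrow(d) < 10) stop("need at least 10 intra-chromosomal pairs")
  fit <- NULL
  sp <- span
  while (is.null(fit) && sp <= 1) {
    fit <- tryCatch(
      suppressWarnings(stats::loess(r2 ~ dist_bp, data = d, span = sp,
                                    degree = 2, family = "gaussian")),
      error = function(e) NULL)
    if (is.null(fit)) {
      sp <- min(1, sp * 2)
      warning("loess span widened to ", sp)
    }
  }
  if (is.null(fit)) stop("loess fit failed even at span 1")
  grid <- seq(0, max(d$dist_bp), length.out = grid_points)
  sm <- stats::predict(fit, newdata = data.frame(dist_bp = grid))
  sm <- pmax(as.numeric(sm), 0)
  ## extrapolation at the grid edges can return NA; carry nearest values
  if (anyNA(sm)) {
    ok <- which(!is.na(sm))
    sm <- stats::approx(grid[ok], sm[ok], xout = grid, rule = 2)$y
  }
  curve <- structure(list(grid_bp = grid, smoothed_r2 = sm, span = sp,
                          degree = 2L, background = background,
                          block_size_bp = NA_real_),
                     class = "ld_decay")
  if (!is.null(background)) curve$block_size_bp <- block_size(curve, background)
  curve
}

#' LD block size: where the decay curve crosses the background LD
#'
#' Returns the smallest grid distance at which the smoothed r2 falls to or
#' below the background value, linearly interpolated between the straddling
#' grid points. A curve that starts at or below the background gives 0; a
#' curve that never reaches it gives `NA` (reported explicitly).
#'
#' @param curve an `ld_decay` object.
#' @param background background r2 (defaults to the one stored in `curve`).
#' @return crossing distance in bp, 0, or `NA`.
#' @export
block_size <- function(curve, background = curve$background) {
  if (is.null(background)) stop("no background LD value supplied")
  sm <- curve$smoothed_r2
  g <- curve$grid_bp
  if (sm[1] <= background) return(0)
  below <- which(sm <= background)
  if (!length(below)) return(NA_real_)
  i <- below[1]
  x0 <- g[i - 1]; x1 <- g[i]
  y0 <- sm[i - 1]; y1 <- sm[i]
  if (y0 == y1) return(x1)
  x0 + (y0 - background) / (y0 - y1) * (x1 - x0)
}

#' End-to-end LD analysis of a panel
#'
#' @param geno [genotype_matrix()].
#' @param span,grid_points passed to [loess_decay()].
#' @param quantile background quantile.
#' @param max_pairs_per_chrom,n_inter_pairs sampling caps.
#' @param seed integer seed.
#' @return list with `pairs`, `background`, `curve`, `block_size_bp`.
#' @export
ld_analysis <- function(geno, span = 0.5, grid_points = 200L,
                        quantile = 0.99, max_pairs_per_chrom = 200000L,
                        n_inter_pairs = 100000L, seed = 1L) {
  pairs <- sample_intra_pairs(geno, max_pairs_per_chrom, seed)
  bg <- background_ld(geno, n_inter_pairs, quantile, seed)
  curve <- loess_decay(pairs, span, grid_points, background = as.numeric(bg))
  list(pairs = pairs, background = as.numeric(bg), curve = curve,
       block_size_bp = curve$block_size_bp)
}
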