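#' Assemble the signed-t matrix from univariate association tables
#'
#' Takes one association table per analysis (the [mlm_scan()] output
#' contract) and builds the SNPs-by-analyses matrix of signed t-values
#' `t = beta / se(beta)`. SNPs absent from an analysis are `NA`; flagged
#' monomorphic records contribute `t = 0` and are tracked. Allele
#' orientation must agree across tables (hard error otherwise).
#'
#' @param assoc_list named list of association data.frames; names are the
#'   analysis labels (conventionally `"element:env"`).
#' @param info optional data.frame with columns `label`, `element`, `env`
#'   describing each analysis; derived by splitting labels on `":"` when
#'   omitted.
#' @return object of class `t_matrix`: list with `t` (matrix), `map`
#'   (snp_id, chrom, pos_bp, pos_cm, allele_ref, allele_alt), `analyses`
#'   (the info data.frame), `monomorphic` (logical matrix).
#' @export
build_t_matrix <- function(assoc_list, info = NULL) {
  stopifnot(length(assoc_list) >= 1, !is.null(names(assoc_list)))
  labels <- names(assoc_list)
  if (is.null(info)) {
    parts <- strsplit(labels, ":", fixed = TRUE)
    info <- data.frame(label = labels,
                       element = vapply(parts, `[`, "", 1L),
                       env = vapply(parts, function(p) p[2] %||% NA_character_, ""),
                       stringsAsFactors = FALSE)
  }
  for (a in assoc_list) {
    if (anyDuplicated(a$snp_id)) stop("duplicated snp_id within one analysis")
  }
  all_map <- do.call(rbind, lapply(assoc_list, function(a)
    a[, c("snp_id", "chrom", "pos_bp", "pos_cm", "allele_ref", "allele_alt")]))
  map <- unique(all_map)
  if (anyDuplicated(map$snp_id))
    stop("inconsistent map or allele orientation for some SNP across analyses")
  map <- map[order(match(map$chrom, chrom_sort(map$chrom)), map$pos_bp), ]
  rownames(map) <- NULL

  tmat <- matrix(NA_real_, nrow(map), length(assoc_list),
                 dimnames = list(map$snp_id, labels))
  mono <- matrix(FALSE, nrow(map), length(assoc_list),
                 dimnames = list(map$snp_id, labels))
  for (j in seq_along(assoc_list)) {
    a <- assoc_list[[j]]
    idx <- match(a$snp_id, map$snp_id)
    tv <- a$beta / a$se
    is_mono <- !is.null(a$flag) & (a$flag %||% "") == "monomorphic"
    tv[is_mono] <- 0
    tmat[idx, j] <- tv
    mono[idx, j] <- is_mono
  }
  structure(list(t = tmat, map = map, analyses = info, monomorphic = mono),
            class = "t_matrix")
}

#' Correlation matrix of signed t-values across analyses
#'
#' Pairwise Pearson correlation of the t-value columns over SNPs observed in
#' both analyses. `trim_quantile < 1` excludes, per column, SNPs whose |t|
#' exceeds that column quantile before correlating, guarding the estimate
#' against large-effect signal; the default uses every SNP.
#'
#' @param tmat a `t_matrix`.
#' @param subset optional analysis labels to restrict to.
#' @param trim_quantile per-column |t| quantile above which SNPs are
#'   excluded (1 = no trimming).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
estimate_v <- function(tmat, subset = NULL, trim_quantile = 1.0) {
  t_ <- tmat$t
  if (!is.null(subset)) t_ <- t_[, subset, drop = FALSE]
  if (ncol(t_) < 1) stop("no analyses selected")
  if (nrow(t_) < 100)
    warning("fewer than 100 SNPs: the t-correlation matrix will be noisy")
  if (trim_quantile < 1) {
    for (j in seq_len(ncol(t_))) {
      thr <- stats::quantile(abs(t_[, j]), trim_quantile, na.rm = TRUE)
      t_[which(abs(t_[, j]) > thr), j] <- NA
    }
  }
  sds <- apply(t_, 2, stats::sd, na.rm = TRUE)
  if (any(!is.finite(sds) | sds == 0))
    stop("zero-variance t column(s): ",
         paste(colnames(t_)[!is.finite(sds) | sds == 0], collapse = ", "))
  V <- suppressWarnings(stats::cor(t_, use = "pairwise.complete.obs"))
  V[is.na(V)] <- 0
  diag(V) <- 1
  (V + t(V)) / 2
}

#' Multi-trait meta-analysis chi-square per SNP
#'
#' For each SNP, `chi2 = t' V^-1 t` over the analyses where the SNP has a
#' t-value; `V` is restricted to those analyses and inverted by Moore-Penrose
#' pseudo-inverse (eigenvalues below `1e-10 * max` treated as zero), with the
#' degrees of freedom equal to the rank of the restricted matrix. The global
#' p-value is the upper tail of the chi-square distribution at that df.
#'
#' @param tmat a `t_matrix`.
#' @param V correlation matrix from [estimate_v()] over the same analysis
#'   set (its dimnames select the columns used).
#' @return data.frame with `snp_id`, `chrom`, `pos_bp`, `pos_cm`, `chi2`,
#'   `df`, `p`, `minus_log10_p`, `n_analyses`.
#' @export
meta_chi2 <- function(tmat, V) {
  labels <- colnames(V)
  if (is.null(labels)) {
    stopifnot(ncol(V) == ncol(tmat$t))
    labels <- colnames(tmat$t)
    dimnames(V) <- list(labels, labels)
  }
  t_ <- tmat$t[, labels, drop = FALSE]
  obs <- !is.na(t_)
  keep <- rowSums(obs) > 0
  t_ <- t_[keep, , drop = FALSE]
  obs <- obs[keep, , drop = FALSE]
  map <- tmat$map[keep, , drop = FALSE]

  ## group SNPs by missingness pattern: one pseudo-inverse per pattern
  pat <- apply(obs, 1, function(z) paste(which(z), collapse = ","))
  chi2 <- df <- rep(NA_real_, nrow(t_))
  for (pp in unique(pat)) {
    cols <- as.integer(strsplit(pp, ",", fixed = TRUE)[[1]])
    rows <- which(pat == pp)
    Vs <- V[cols, cols, drop = FALSE]
    ev <- eigen(Vs, symmetric = TRUE)
    tol <- 1e-10 * max(ev$values)
    pos <- ev$values > tol
    rk <- sum(pos)
    ## pseudo-inverse quadratic form via the retained eigenpairs
    Usub <- ev$vectors[, pos, drop = FALSE]
    Ts <- t_[rows, cols, drop = FALSE]
    proj <- Ts %*% Usub
    chi2[rows] <- rowSums(sweep(proj^2, 2, ev$values[pos], `/`))
    df[rows] <- rk
  }
  p <- stats::pchisq(chi2, df, lower.tail = FALSE)
  data.frame(snp_id = map$snp_id, chrom = map$chrom, pos_bp = map$pos_bp,
             pos_cm = map$pos_cm, chi2 = chi2, df = df, p = p,
             minus_log10_p = -log10(pmax(p, .Machine$double.xmin)),
             n_analyses = rowSums(obs),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Bonferroni significance threshold
#'
#' @param alpha family-wise error rate.
#' @param m number of tests (SNPs).
#' @return `alpha / m`; SNPs are declared significant when `p <= alpha / m`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  if (m < 1) stop("m must be >= 1")
  alpha / m
}

#' Cluster significant SNPs into QTL by LD with the lead SNP
#'
#' Per chromosome: the most significant unassigned SNP seeds a cluster (the
#' lead); every unassigned significant SNP on that chromosome with
#' `r2(lead, snp) > r2_threshold` joins it; repeat until all significant
#' SNPs are assigned. Ties in significance are broken by position. Clusters
#' never span chromosomes.
#'
#' @param meta data.frame from [meta_chi2()].
#' @param geno [genotype_matrix()] covering the significant SNPs (used for
#'   the dosage-correlation r2).
#' @param threshold significance threshold on `p` (e.g. from
#'   [bonferroni_threshold()]).
#' @param r2_threshold LD threshold for joining the lead's cluster.
#' @return data.frame with one row per QTL: `qtl_id`, `chrom`, `lead_snp`,
#'   `lead_p`, `n_snps`, `members` (comma-separated), `span_bp_min`,
#'   `span_bp_max`, `span_cm_min`, `span_cm_max`.
#' @export
cluster_qtl <- function(meta, geno, threshold, r2_threshold = 0.5) {
  sig <- meta[!is.na(meta$p) & meta$p <= threshold, , drop = FALSE]
  if (nrow(sig) == 0L)
    return(data.frame(qtl_id = character(), chrom = character(),
                      lead_snp = character(), lead_p = numeric(),
                      n_snps = integer(), members = character(),
                      span_bp_min = numeric(), span_bp_max = numeric(),
                      span_cm_min = numeric(), span_cm_max = numeric(),
                      stringsAsFactors = FALSE))
  miss <- setdiff(sig$snp_id, colnames(geno$dosage))
  if (length(miss)) stop("genotypes missing for significant SNP(s): ", miss[1])
  out <- list()
  qnum <- 0L
  for (ch in chrom_sort(sig$chrom)) {
    sub <- sig[sig$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$pos_bp), , drop = FALSE]
    unassigned <- rep(TRUE, nrow(sub))
    while (any(unassigned)) {
      cand <- which(unassigned)
      lead <- cand[order(sub$p[cand], sub$pos_bp[cand])][1]
      x_lead <- geno$dosage[, sub$snp_id[lead]]
      r2 <- vapply(cand, function(i)
        pair_r2(x_lead, geno$dosage[, sub$snp_id[i]]), 0.0)
      members <- cand[cand == lead | (!is.na(r2) & r2 > r2_threshold)]
      unassigned[members] <- FALSE
      qnum <- qnum + 1L
      out[[qnum]] <- data.frame(
        qtl_id = sprintf("Q%03d", qnum), chrom = ch,
        lead_snp = sub$snp_id[lead], lead_p = sub$p[lead],
        n_snps = length(members),
        members = paste(sub$snp_id[members], collapse = ","),
        span_bp_min = min(sub$pos_bp[members]),
        span_bp_max = max(sub$pos_bp[members]),
        span_cm_min = min(sub$pos_cm[members]),
        span_cm_max = max(sub$pos_cm[members]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Run the three-way meta-analysis design
#'
#' Executes the meta-analysis over group-one analyses (`Meta1`), group-two
#' analyses (`Meta2`), and all analyses (`Meta`), each across all
#' environments, at a shared Bonferroni threshold, and labels every SNP
#' significant anywhere by which analyses detect it.
#'
#' @param tmat a `t_matrix` whose `analyses` table has an `element` column.
#' @param grouping an `element_grouping` from [group_elements()].
#' @param alpha family-wise error rate.
#' @param m number of tests for the Bonferroni correction (default: number
#'   of SNPs in `tmat`).
#' @param trim_quantile passed to [estimate_v()].
#' @return list with `meta1`, `meta2`, `meta` (each a [meta_chi2()]
#'   data.frame with a `significant` flag), `threshold`, and `comparison`
#'   (per-SNP detection flags across the three analyses).
#' @export
run_meta_design <- function(tmat, grouping, alpha = 0.05,
                            m = nrow(tmat$t), trim_quantile = 1.0) {
  el <- tmat$analyses$element
  g1_el <- grouping$members[["1"]]
  g2_el <- grouping$members[["2"]] %||% character()
  cols1 <- tmat$analyses$label[el %in% g1_el]
  cols2 <- tmat$analyses$label[el %in% g2_el]
  if (!length(cols1)) stop("group 1 selects no analyses")
  thr <- bonferroni_threshold(alpha, m)
  run1 <- function(cols) {
    V <- estimate_v(tmat, subset = cols, trim_quantile = trim_quantile)
    res <- meta_chi2(tmat, V)
    res$significant <- !is.na(res$p) & res$p <= thr
    res
  }
  meta1 <- run1(cols1)
  meta2 <- if (length(cols2)) run1(cols2) else NULL
  meta_all <- run1(tmat$analyses$label)
  any_sig <- unique(c(meta1$snp_id[meta1$significant],
                      if (!is.null(meta2)) meta2$snp_id[meta2$significant],
                      meta_all$snp_id[meta_all$significant]))
  comparison <- data.frame(
    snp_id = any_sig,
    meta1 = any_sig %in% meta1$snp_id[meta1$significant],
    meta2 = if (!is.null(meta2)) any_sig %in% meta2$snp_id[meta2$significant]
            else rep(FALSE, length(any_sig)),
    meta = any_sig %in% meta_all$snp_id[meta_all$significant],
    stringsAsFactors = FALSE)
  list(meta1 = meta1, meta2 = meta2, meta = meta_all,
       threshold = thr, comparison = comparison)
}

#' Allelic effect in phenotypic standard deviations
#'
#' For one SNP, contrasts the two homozygote classes within each
#' environment-by-element BLUE set: `(mean BLUE of alternate homozygotes -
#' mean BLUE of reference homozygotes) / SD of all BLUEs` in that set.
#' Heterozygotes are excluded; a contrast needs at least two lines per
#' class, otherwise it is `NA` and flagged.
#'
#' @param blues BLUE data.frame (`env`, `element`, `line_id`, `blue`).
#' @param dosages named dosage vector for the SNP (names = line ids).
#' @return data.frame `env`, `element`, `effect_sd`, `n_ref`, `n_alt`,
#'   `flag`.
#' @export
allelic_effect_sd <- function(blues, dosages) {
  stopifnot(!is.null(names(dosages)))
  combos <- unique(blues[, c("env", "element")])
  out <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    sub <- blues[blues$env == combos$env[i] & blues$element == combos$element[i], ]
    dd <- dosages[sub$line_id]
    ref <- sub$blue[!is.na(dd) & dd == 0]
    alt <- sub$blue[!is.na(dd) & dd == 2]
    sdv <- stats::sd(sub$blue)
    ok <- length(ref) >= 2 && length(alt) >= 2 && is.finite(sdv) && sdv > 0
    out[[i]] <- data.frame(
      env = combos$env[i], element = combos$element[i],
      effect_sd = if (ok) (mean(alt) - mean(ref)) / sdv else NA_real_,
      n_ref = length(ref), n_alt = length(alt),
      flag = if (ok) "" else "insufficient_class",
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Manhattan plot of a meta-analysis result
#'
#' @param meta data.frame from [meta_chi2()].
#' @param threshold significance threshold on p (drawn as a horizontal line).
#' @param main plot title.
#' @return invisibly, the plotted data.frame with cumulative positions.
#' @export
plot_manhattan <- function(meta, threshold = NULL, main = "MetaGWAS") {
  chroms <- chrom_sort(meta$chrom)
  offs <- 0
  meta$cum <- NA_real_
  cols <- rep(c("grey30", "steelblue"), length.out = length(chroms))
  meta$colr <- "grey30"
  for (i in seq_along(chroms)) {
    sel <- meta$chrom == chroms[i]
    meta$cum[sel] <- meta$pos_bp[sel] + offs
    meta$colr[sel] <- cols[i]
    offs <- offs + max(meta$pos_bp[sel]) + 1e6
  }
  graphics::plot(meta$cum, meta$minus_log10_p, pch = 16, cex = 0.5,
                 col = meta$colr, xlab = "chromosome", ylab = "-log10(p)",
                 main = main, xaxt = "n")
  if (!is.null(threshold))
    graphics::abline(h = -log10(threshold), lty = 2, col = "red")
  invisible(meta)
}
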