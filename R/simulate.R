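#' Simulate inbred-line genotypes with block-wise linkage disequilibrium
#'
#' Generates fully homozygous (doubled-haplotype) dosages by a
#' founder-haplotype copying process: along each chromosome a line copies one
#' of `n_founders` founder haplotypes, switching founders between adjacent
#' SNPs with probability `1 - exp(-d / ld_scale)` where `d` is the inter-SNP
#' distance in bp. Larger `ld_scale` gives longer shared segments and hence
#' larger LD blocks; the default is tuned so the loess-smoothed r2 decay
#' curve of a typical panel crosses its background LD near 7 Mb.
#'
#' @param n_lines number of inbred lines (>= 2).
#' @param chrom_plan data.frame with columns `chrom`, `n_snps`, `length_bp`;
#'   one row per chromosome.
#' @param ld_scale exponential length scale of founder switching, in bp.
#' @param maf_min SNPs with realized minor-allele frequency below this are
#'   dropped (must be < 0.5).
#' @param missing_rate fraction of entries set missing uniformly at random.
#' @param n_founders number of founder haplotypes.
#' @param cm_per_mb genetic-map scaling used to derive `pos_cm` from
#'   `pos_bp` (reporting only, never used in computation).
#' @param seed integer seed; all randomness in this function flows from it.
#' @return a [genotype_matrix()] with dosages in `{0, 2, NA}`.
#' @export
simulate_genotypes <- function(n_lines,
                               chrom_plan = data.frame(
                                 chrom = c("1A", "2B", "3D"),
                                 n_snps = 400L, length_bp = 8e7),
                               ld_scale = 3.5e6,
                               maf_min = 0.05,
                               missing_rate = 0,
                               n_founders = 30L,
                               cm_per_mb = 1 / 4.5,
                               seed = 1L) {
  if (n_lines < 2) stop("n_lines must be >= 2")
  if (ld_scale <= 0) stop("ld_scale must be > 0")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  if (maf_min >= 0.5) stop("maf_min must be < 0.5")
  if (any(chrom_plan$n_snps < 1) || any(chrom_plan$length_bp < 1))
    stop("chrom_plan counts and lengths must be positive")

  set.seed(derive_seed(seed, "genotypes"))
  dos_list <- vector("list", nrow(chrom_plan))
  map_list <- vector("list", nrow(chrom_plan))
  for (c_i in seq_len(nrow(chrom_plan))) {
    m <- as.integer(chrom_plan$n_snps[c_i])
    len <- chrom_plan$length_bp[c_i]
    pos <- sort(sample.int(len, m, replace = FALSE))
    ## founder haplotypes carry internal LD: along the chromosome each
    ## founder keeps its previous allele with probability exp(-d/ld_scale)
    ## and otherwise redraws from the site frequency, so allele identity
    ## itself decays with distance (independent per-site founder alleles
    ## would cap r2 at ~1/n_founders regardless of distance)
    p <- stats::runif(m, 0.15, 0.85)
    pkeep <- exp(-diff(pos) / ld_scale)
    founders <- matrix(0L, n_founders, m)
    founders[, 1] <- stats::rbinom(n_founders, 1L, p[1])
    for (j in 2:m) {
      keep <- stats::runif(n_founders) < pkeep[j - 1]
      founders[, j] <- ifelse(keep, founders[, j - 1],
                              stats::rbinom(n_founders, 1L, p[j]))
    }
    psw <- 1 - exp(-diff(pos) / ld_scale)
    hap <- matrix(0L, n_lines, m)
    for (i in seq_len(n_lines)) {
      sw <- c(TRUE, stats::runif(m - 1L) < psw)
      seg <- cumsum(sw)
      fo <- sample.int(n_founders, seg[m], replace = TRUE)
      hap[i, ] <- founders[cbind(fo[seg], seq_len(m))]
    }
    dos_list[[c_i]] <- 2 * hap  # doubled haplotypes: fully homozygous
    map_list[[c_i]] <- data.frame(
      snp_id = sprintf("%s_%09d", chrom_plan$chrom[c_i], pos),
      chrom = as.character(chrom_plan$chrom[c_i]),
      pos_bp = pos, stringsAsFactors = FALSE)
  }
  dosage <- do.call(cbind, dos_list)
  map <- do.call(rbind, map_list)
  ## MAF filter on the realized panel
  maf <- apply(dosage, 2, snp_maf)
  keep <- maf >= maf_min
  if (!any(keep)) stop("no SNP passed the maf_min filter; increase n_founders or lower maf_min")
  dosage <- dosage[, keep, drop = FALSE]
  map <- map[keep, , drop = FALSE]
  if (missing_rate > 0) {
    nmiss <- round(missing_rate * length(dosage))
    dosage[sample.int(length(dosage), nmiss)] <- NA
  }
  map$pos_cm <- map$pos_bp * cm_per_mb / 1e6
  map$allele_ref <- "A"
  map$allele_alt <- "B"
  rownames(dosage) <- sprintf("L%04d", seq_len(n_lines))
  genotype_matrix(dosage, map)
}

#' Simulate a two-group pleiotropic trait architecture
#'
#' Draws QTL and per-element allelic effects so that the expected genetic
#' correlation structure matches the targets: `rg_within` within each element
#' group, `rg_between` (typically negative) between groups. Three QTL kinds
#' are placed: *shared* QTL whose effect vectors are drawn from a
#' multivariate normal with the target correlation matrix; *private* QTL
#' affecting a single element each; and *antagonistic* QTL whose allele
#' raises every group-one element and lowers every group-two element
#' (or vice versa). Effects are then rescaled per element so that the
#' realized genetic variance equals `h2 / (1 - h2)` — i.e. heritability
#' `h2_target` against a unit effective residual variance.
#'
#' @param geno a [genotype_matrix()] (missing dosages allowed; QTL are drawn
#'   from SNPs with complete calls and MAF >= `qtl_maf_min`).
#' @param elements character vector of trait labels.
#' @param group1 subset of `elements` forming group one; the rest are group two.
#' @param n_shared,n_private,n_antagonistic QTL counts; `n_private` is per
#'   element.
#' @param h2_target per-element target heritability in (0, 1); recycled.
#' @param rg_within,rg_between target genetic correlations.
#' @param env_scalers optional named vector of per-environment multipliers of
#'   the genetic values (default: 1 for every environment).
#' @param qtl_maf_min minimum MAF of candidate QTL SNPs.
#' @param seed integer seed.
#' @return an object of class `trait_architecture`: list with `elements`,
#'   `groups` (named list `group1`, `group2`), `qtl` (data.frame: snp_id,
#'   type, one effect column per element), `h2_target`, `rg_within`,
#'   `rg_between`, `env_scalers`, and `genetic_values` (lines x elements
#'   matrix of true additive values on the scaled effects).
#' @export
simulate_architecture <- function(geno,
                                  elements = c("B", "Ca", "Co", "Cu", "Fe", "K", "Mg",
                                               "Mn", "Mo", "Na", "Ni", "P", "Zn"),
                                  group1 = c("Ca", "Co", "K", "Na"),
                                  n_shared = 20L,
                                  n_private = 2L,
                                  n_antagonistic = 1L,
                                  h2_target = 0.42,
                                  rg_within = 0.45,
                                  rg_between = -0.20,
                                  env_scalers = NULL,
                                  qtl_maf_min = 0.05,
                                  seed = 1L) {
  stopifnot(all(group1 %in% elements))
  h2 <- rep_len(h2_target, length(elements))
  if (any(h2 <= 0 | h2 >= 1)) stop("h2_target must lie in (0, 1)")
  group2 <- setdiff(elements, group1)
  n_el <- length(elements)
  set.seed(derive_seed(seed, "architecture"))

  dos <- geno$dosage
  maf <- apply(dos, 2, function(x) if (all(is.na(x))) 0 else snp_maf(x))
  callrate <- 1 - colMeans(is.na(dos))
  cand <- which(callrate >= 0.8 & maf >= qtl_maf_min)
  n_qtl <- n_shared + n_private * n_el + n_antagonistic
  if (n_qtl > length(cand))
    stop("requested ", n_qtl, " QTL but only ", length(cand),
         " polymorphic complete-call SNPs available")
  qtl_idx <- sample(cand, n_qtl)

  ## target correlation of per-QTL effects across elements
  R <- matrix(rg_between, n_el, n_el, dimnames = list(elements, elements))
  R[elements %in% group1, elements %in% group1] <- rg_within
  R[elements %in% group2, elements %in% group2] <- rg_within
  diag(R) <- 1
  er <- eigen(R, symmetric = TRUE)
  if (min(er$values) < -1e-8)
    stop("rg targets do not form a positive semidefinite correlation matrix")
  Rhalf <- er$vectors %*% (sqrt(pmax(er$values, 0)) * t(er$vectors))

  eff <- matrix(0, n_qtl, n_el, dimnames = list(NULL, elements))
  type <- character(n_qtl)
  k <- 0L
  if (n_shared > 0) {
    eff[k + seq_len(n_shared), ] <-
      matrix(stats::rnorm(n_shared * n_el), n_shared) %*% Rhalf
    type[k + seq_len(n_shared)] <- "shared"
    k <- k + n_shared
  }
  if (n_private > 0) {
    for (e in seq_len(n_el)) {
      rows <- k + seq_len(n_private)
      eff[cbind(rows, e)] <- stats::rnorm(n_private)
      type[rows] <- "private"
      k <- k + n_private
    }
  }
  if (n_antagonistic > 0) {
    ## antagonistic loci are simulated as major-effect: their real-world
    ## analogue is a single locus standing out far above the polygenic
    ## background, with opposite allele effects across the two groups
    sgn <- ifelse(elements %in% group1, 1, -1)
    for (a in seq_len(n_antagonistic)) {
      k <- k + 1L
      eff[k, ] <- sgn * abs(stats::rnorm(n_el, mean = 2, sd = 0.5))
      type[k] <- "antagonistic"
    }
  }

  ## realized genetic values, then per-element scaling to the h2 target;
  ## rare missing dosages at QTL are mean-imputed for the truth values
  X <- dos[, qtl_idx, drop = FALSE]
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    na_idx <- which(is.na(X), arr.ind = TRUE)
    X[na_idx] <- mu[na_idx[, 2]]
  }
  Xc <- scale(X, center = TRUE, scale = FALSE)
  g <- Xc %*% eff
  vg <- apply(g, 2, stats::var)
  if (any(vg <= 0)) stop("an element has zero genetic variance; add QTL")
  s <- sqrt(h2 / (1 - h2) / vg)
  eff <- sweep(eff, 2, s, `*`)
  g <- sweep(g, 2, s, `*`)
  rownames(g) <- rownames(dos)

  qtl <- data.frame(snp_id = geno$map$snp_id[qtl_idx], type = type,
                    stringsAsFactors = FALSE)
  qtl <- cbind(qtl, as.data.frame(eff))
  structure(list(elements = elements,
                 groups = list(group1 = group1, group2 = group2),
                 qtl = qtl,
                 h2_target = stats::setNames(h2, elements),
                 rg_within = rg_within, rg_between = rg_between,
                 env_scalers = env_scalers,
                 genetic_values = g),
            class = "trait_architecture")
}

#' Default six-trial layout
#'
#' Two replicated randomized-complete-block trials on the full panel and four
#' trials (two sites by two times of sowing) on a diversity subset, mirroring
#' a multi-site wheat evaluation. Each entry gives the trial label, the line
#' ids grown, replicate count and field dimensions.
#'
#' @param lines character vector of all line ids.
#' @param n_subset size of the subset grown in the four smaller trials.
#' @param n_reps replicates per trial.
#' @param seed seed for drawing the subset.
#' @return list of environment descriptors consumed by [simulate_trials()].
#' @export
default_env_plan <- function(lines, n_subset = 200L, n_reps = 2L, seed = 1L) {
  set.seed(derive_seed(seed, "env_plan"))
  subset <- sort(sample(lines, min(n_subset, length(lines))))
  mk <- function(label, ids) {
    n_col <- ceiling(sqrt(length(ids)))
    n_row <- ceiling(length(ids) / n_col) * n_reps
    list(label = label, lines = ids, n_reps = n_reps,
         n_row = n_row, n_col = n_col)
  }
  list(mk("NAR17_TOS1", lines), mk("NAR17_TOS2", lines),
       mk("MER18_TOS1", subset), mk("MER18_TOS2", subset),
       mk("HOR18_TOS1", subset), mk("HOR18_TOS2", subset))
}

#' Simulate plot-level field-trial data
#'
#' Every trial is a randomized complete block: lines are assigned at random
#' to plots within each replicate block. A plot value is
#' `intercept + g * env_scaler + rep effect + row trend + column trend +
#' residual`, with the row and column trends independent random quadratic
#' polynomials scaled so their summed SD equals `spatial_sd`.
#'
#' @param geno a [genotype_matrix()] (supplies the line ids).
#' @param arch a `trait_architecture` from [simulate_architecture()].
#' @param envs list of environment descriptors (see [default_env_plan()]);
#'   each a list with `label`, `lines`, `n_reps`, `n_row`, `n_col`.
#' @param spatial_sd SD of the row+column trend surface, trait units.
#' @param rep_sd SD of replicate effects.
#' @param resid_sd plot residual SD. The architecture scales genetic values
#'   against a unit effective residual; with `n_reps` replicates a residual
#'   SD of `sqrt(n_reps)` keeps the per-line BLUE error variance at one so
#'   BLUE-level heritability matches the architecture's `h2_target`.
#' @param intercept grand mean added to every plot.
#' @param seed integer seed.
#' @return a `plot_table` data.frame with columns `env`, `row`, `col`, `rep`,
#'   `line_id`, `element`, `value`.
#' @export
simulate_trials <- function(geno, arch,
                            envs = default_env_plan(rownames(geno$dosage)),
                            spatial_sd = 0.5,
                            rep_sd = 0.25,
                            resid_sd = sqrt(2),
                            intercept = 10,
                            seed = 1L) {
  g <- arch$genetic_values
  elements <- arch$elements
  scal <- arch$env_scalers
  out <- vector("list", length(envs) * length(elements))
  set.seed(derive_seed(seed, "trials"))
  idx <- 0L
  for (env in envs) {
    ids <- env$lines
    if (!all(ids %in% rownames(g)))
      stop("environment ", env$label, " requests lines absent from the genotypes")
    n_l <- length(ids)
    n_reps <- env$n_reps
    if (env$n_row * env$n_col < n_l * n_reps)
      stop("layout of ", env$label, " too small for ", n_l, " lines x ",
           n_reps, " reps")
    mult <- if (is.null(scal)) 1 else scal[[env$label]] %||% 1
    ## grid positions, consecutive blocks of n_l plots per replicate
    grid <- expand.grid(col = seq_len(env$n_col), row = seq_len(env$n_row))
    plots <- data.frame(
      row = grid$row[seq_len(n_l * n_reps)],
      col = grid$col[seq_len(n_l * n_reps)],
      rep = rep(seq_len(n_reps), each = n_l),
      line_id = unlist(lapply(seq_len(n_reps), function(r) sample(ids))),
      stringsAsFactors = FALSE)
    for (el in elements) {
      rep_eff <- stats::rnorm(n_reps, 0, rep_sd)
      rtr <- stats::rnorm(2)
      ctr <- stats::rnorm(2)
      zr <- scale(plots$row)[, 1]; zc <- scale(plots$col)[, 1]
      if (any(!is.finite(zr))) zr <- rep(0, nrow(plots))
      if (any(!is.finite(zc))) zc <- rep(0, nrow(plots))
      f_r <- rtr[1] * zr + rtr[2] * zr^2
      f_c <- ctr[1] * zc + ctr[2] * zc^2
      surf <- f_r + f_c
      sds <- stats::sd(surf)
      surf <- if (spatial_sd > 0 && sds > 0) surf / sds * spatial_sd else surf * 0
      val <- intercept +
        g[plots$line_id, el] * mult +
        rep_eff[plots$rep] +
        surf +
        stats::rnorm(nrow(plots), 0, resid_sd)
      idx <- idx + 1L
      out[[idx]] <- data.frame(env = env$label, row = plots$row,
                               col = plots$col, rep = plots$rep,
                               line_id = plots$line_id, element = el,
                               value = as.numeric(val),
                               stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out[seq_len(idx)])
  rownames(res) <- NULL
  class(res) <- c("plot_table", "data.frame")
  res
}

#' Simulate a complete study
#'
#' Convenience wrapper chaining [simulate_genotypes()],
#' [simulate_architecture()], and [simulate_trials()] with a shared seed.
#' Defaults emulate the structure of a large inbred wheat panel: 1,470 lines,
#' 13 elements in two negatively correlated groups, six trials with a
#' 200-line subset in four of them, and ~7 Mb LD blocks. All sizes are
#' overridable for desk-scale work.
#'
#' @param n_lines,chrom_plan,ld_scale,missing_rate passed to
#'   [simulate_genotypes()].
#' @param n_subset subset size for the four smaller trials.
#' @param seed master seed.
#' @param ... further arguments to [simulate_architecture()].
#' @return list with `geno`, `arch`, `plots`, and `envs`.
#' @export
simulate_study <- function(n_lines = 1470L,
                           chrom_plan = data.frame(
                             chrom = c("1A", "2B", "3D", "5A", "7D"),
                             n_snps = 500L, length_bp = 8e7),
                           ld_scale = 3.5e6,
                           missing_rate = 0.02,
                           n_subset = 200L,
                           seed = 1L, ...) {
  geno <- simulate_genotypes(n_lines, chrom_plan, ld_scale = ld_scale,
                             missing_rate = missing_rate, seed = seed)
  arch <- simulate_architecture(geno, seed = seed, ...)
  envs <- default_env_plan(rownames(geno$dosage), n_subset = n_subset,
                           seed = seed)
  plots <- simulate_trials(geno, arch, envs, seed = seed)
  list(geno = geno, arch = arch, plots = plots, envs = envs)
}
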