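## Shared fixtures, built in code.

## tiny genotype matrix from explicit dosages (one chromosome by default)
toy_geno <- function(dosage, chrom = NULL, pos = NULL) {
  m <- ncol(dosage)
  if (is.null(chrom)) chrom <- rep("1A", m)
  if (is.null(pos)) pos <- seq_len(m) * 1e6
  genotype_matrix(dosage, data.frame(
    snp_id = paste0("S", seq_len(m)), chrom = chrom, pos_bp = pos,
    stringsAsFactors = FALSE))
}

## outbred HWE panel: dosages ~ Binomial(2, p) per SNP, independent SNPs
hwe_geno <- function(n, m, seed = 1) {
  set.seed(seed)
  p <- runif(m, 0.1, 0.9)
  d <- matrix(rbinom(n * m, 2L, rep(p, rep(n, m))), nrow = n)
  rownames(d) <- paste0("L", seq_len(n))
  toy_geno(d)
}

## draw y with a given h2 from the GREML model on a unit-mean-diagonal GRM
sim_pheno_h2 <- function(grm, h2, seed) {
  set.seed(seed)
  n <- nrow(grm)
  Gn <- grm * n / sum(diag(grm))
  ed <- eigen(Gn, symmetric = TRUE)
  L <- ed$vectors %*% (sqrt(pmax(ed$values, 0)) * t(ed$vectors))
  y <- as.numeric(sqrt(h2) * (L %*% rnorm(n)) + sqrt(1 - h2) * rnorm(n))
  names(y) <- rownames(grm)
  y
}

## minimal association table for meta tests
mk_assoc <- function(snp_ids, beta, se, chrom = "1A", pos = NULL,
                     flag = "") {
  if (is.null(pos)) pos <- seq_along(snp_ids) * 1e6
  data.frame(snp_id = snp_ids, chrom = chrom, pos_bp = pos,
             pos_cm = pos / 4.5e6, allele_ref = "A", allele_alt = "B",
             beta = beta, se = se, flag = flag, stringsAsFactors = FALSE)
}
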