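#' Genotype matrix container
#'
#' Bundles a lines-by-SNPs dosage matrix (count of the alternate allele:
#' 0, 1, 2 or `NA` for missing) with its SNP map. Inbred material is fully
#' homozygous (dosages 0/2 only) but heterozygous calls are accepted
#' everywhere downstream.
#'
#' @param dosage numeric matrix, lines in rows and SNPs in columns, with
#'   values in `{0, 1, 2, NA}`. Row names are line ids, column names SNP ids.
#' @param map data.frame with columns `snp_id`, `chrom`, `pos_bp`, `pos_cm`,
#'   `allele_ref`, `allele_alt`; one row per column of `dosage`, same order.
#' @return an object of class `genotype_matrix`: a list with elements
#'   `dosage` and `map`.
#' @export
genotype_matrix <- function(dosage, map) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  if (is.null(rownames(dosage)))
    rownames(dosage) <- paste0("L", seq_len(nrow(dosage)))
  stopifnot(is.data.frame(map),
            all(c("snp_id", "chrom", "pos_bp") %in% names(map)),
            nrow(map) == ncol(dosage))
  if (is.null(map$pos_cm)) map$pos_cm <- map$pos_bp / 4.5e6
  if (is.null(map$allele_ref)) map$allele_ref <- "A"
  if (is.null(map$allele_alt)) map$allele_alt <- "B"
  map$snp_id <- as.character(map$snp_id)
  map$chrom <- as.character(map$chrom)
  if (anyDuplicated(map$snp_id))
    stop("duplicated snp_id in map")
  colnames(dosage) <- map$snp_id
  bad <- dosage[!is.na(dosage) & !(dosage %in% c(0, 1, 2))]
  if (length(bad))
    stop("dosage values outside {0, 1, 2, NA}: e.g. ", bad[1])
  for (ch in unique(map$chrom)) {
    p <- map$pos_bp[map$chrom == ch]
    if (is.unsorted(p, strictly = TRUE))
      stop("pos_bp not strictly increasing on chromosome ", ch)
  }
  structure(list(dosage = dosage, map = map), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  d <- x$dosage
  cat(sprintf("genotype_matrix: %d lines x %d SNPs on %d chromosome(s)\n",
              nrow(d), ncol(d), length(unique(x$map$chrom))))
  miss <- mean(is.na(d))
  cat(sprintf("  missing: %.2f%%; het: %.2f%% of calls\n",
              100 * miss, 100 * mean(d[!is.na(d)] == 1)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix
#'
#' @param geno a [genotype_matrix()].
#' @param lines line ids or indices to keep (default all).
#' @param snps SNP ids or indices to keep (default all).
#' @return a `genotype_matrix` restricted to the selection, order preserved
#'   as given.
#' @export
subset_genotypes <- function(geno, lines = NULL, snps = NULL) {
  d <- geno$dosage
  map <- geno$map
  if (!is.null(lines)) d <- d[lines, , drop = FALSE]
  if (!is.null(snps)) {
    idx <- if (is.character(snps)) match(snps, map$snp_id) else snps
    if (anyNA(idx)) stop("unknown snp id(s)")
    d <- d[, idx, drop = FALSE]
    map <- map[idx, , drop = FALSE]
  }
  genotype_matrix(d, map)
}
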