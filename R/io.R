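#' Read genotypes from VCF, PLINK text, or TSV dosage
#'
#' * **vcf**: biallelic sites only (multi-allelic records are dropped with a
#'   message); dosage is the alternate-allele count from the GT field
#'   (`0/0` = 0, `0/1` = 1, `1/1` = 2, `./.` = missing; phased separators
#'   accepted).
#' * **plink**: `.ped`/`.map` pair (pass the `.ped` path). The `.map` cM
#'   column populates `pos_cm`. PLINK text carries no ref/alt designation,
#'   so the alternate allele is taken as the minor allele (ties broken
#'   lexicographically).
#' * **tsv**: dosage matrix (lines x SNPs, first column `line_id`) with a
#'   companion map file `<path>.map.tsv` (written by [write_genotypes()]).
#'
#' @param path input file path.
#' @param format one of `"auto"`, `"vcf"`, `"plink"`, `"tsv"`.
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "plink", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf"
              else if (grepl("\\.ped$", path)) "plink"
              else "tsv"
  }
  switch(format,
         vcf = read_genotypes_vcf(path),
         plink = read_genotypes_plink(path),
         tsv = read_genotypes_tsv(path))
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT)
  if (any(multi))
    message(sum(multi), " multi-allelic record(s) dropped")
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  code <- function(g) {
    g <- gsub("|", "/", g, fixed = TRUE)
    out <- rep(NA_real_, length(g))
    out[g == "0/0"] <- 0
    out[g %in% c("0/1", "1/0")] <- 1
    out[g == "1/1"] <- 2
    out
  }
  cd <- code(c(gt))
  dim(cd) <- dim(gt)  # variants x samples
  dosage <- t(cd)
  rownames(dosage) <- colnames(gt)
  map <- data.frame(snp_id = fix$ID, chrom = fix$CHROM,
                    pos_bp = as.integer(fix$POS),
                    allele_ref = fix$REF, allele_alt = fix$ALT,
                    stringsAsFactors = FALSE)
  genotype_matrix(dosage, map)
}

read_genotypes_plink <- function(ped_path) {
  map_path <- sub("\\.ped$", ".map", ped_path)
  mp <- utils::read.table(map_path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("chrom", "snp_id", "pos_cm", "pos_bp"))
  ped <- utils::read.table(ped_path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  m <- nrow(mp)
  if (ncol(ped) != 6 + 2 * m)
    stop("malformed .ped: expected ", 6 + 2 * m, " columns, found ", ncol(ped))
  ids <- ped[[2]]
  a1 <- as.matrix(ped[, 6 + 2 * seq_len(m) - 1, drop = FALSE])
  a2 <- as.matrix(ped[, 6 + 2 * seq_len(m), drop = FALSE])
  dosage <- matrix(NA_real_, nrow(ped), m)
  ref <- alt <- character(m)
  for (j in seq_len(m)) {
    g1 <- a1[, j]; g2 <- a2[, j]
    obs <- g1 != "0" & g2 != "0"
    alleles <- sort(unique(c(g1[obs], g2[obs])))
    if (length(alleles) == 0) { ref[j] <- "A"; alt[j] <- "B"; next }
    if (length(alleles) == 1) {
      ref[j] <- alleles; alt[j] <- alleles
      dosage[obs, j] <- 0
      next
    }
    cnt1 <- sum(g1[obs] == alleles[1]) + sum(g2[obs] == alleles[1])
    ## alt = minor allele; tie broken lexicographically (second allele)
    if (cnt1 < length(g1[obs]) + length(g2[obs]) - cnt1) {
      alt[j] <- alleles[1]; ref[j] <- alleles[2]
    } else {
      alt[j] <- alleles[2]; ref[j] <- alleles[1]
    }
    dosage[obs, j] <- (g1[obs] == alt[j]) + (g2[obs] == alt[j])
  }
  rownames(dosage) <- ids
  map <- data.frame(snp_id = mp$snp_id, chrom = as.character(mp$chrom),
                    pos_bp = mp$pos_bp, pos_cm = mp$pos_cm,
                    allele_ref = ref, allele_alt = alt,
                    stringsAsFactors = FALSE)
  genotype_matrix(dosage, map)
}

read_genotypes_tsv <- function(path) {
  d <- read_tsv_dot(path)
  ids <- d[[1]]
  dosage <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(dosage) <- "double"
  rownames(dosage) <- ids
  map_path <- paste0(path, ".map.tsv")
  if (file.exists(map_path)) {
    map <- read_tsv_dot(map_path, numeric_cols = c("pos_bp", "pos_cm"))
  } else {
    map <- data.frame(snp_id = colnames(dosage), chrom = "1",
                      pos_bp = seq_len(ncol(dosage)), stringsAsFactors = FALSE)
  }
  genotype_matrix(dosage, map)
}

#' Write genotypes to VCF v4.2, PLINK text, or TSV dosage
#'
#' VCF output encodes dosages as homozygous/heterozygous diploid GT calls;
#' PLINK output writes the allele letters from the map (missing as `0 0`);
#' TSV output writes the dosage matrix plus a `<path>.map.tsv` companion.
#'
#' @param geno a [genotype_matrix()].
#' @param path output path (`.ped` for plink; its `.map` sits alongside).
#' @param format `"vcf"`, `"plink"`, or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(geno, path, format = c("tsv", "vcf", "plink")) {
  format <- match.arg(format)
  d <- geno$dosage
  map <- geno$map
  if (format == "tsv") {
    df <- data.frame(line_id = rownames(d), as.data.frame(d),
                     check.names = FALSE, stringsAsFactors = FALSE)
    write_tsv_dot(df, path)
    write_tsv_dot(map, paste0(path, ".map.tsv"))
  } else if (format == "vcf") {
    con <- file(path, "w")
    writeLines(c("##fileformat=VCFv4.2",
                 "##source=pleiometa",
                 '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
                 paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                         "INFO", "FORMAT", rownames(d)), collapse = "\t")), con)
    gt_code <- c("0/0", "0/1", "1/1")
    for (j in seq_len(ncol(d))) {
      g <- d[, j]
      gs <- ifelse(is.na(g), "./.", gt_code[g + 1])
      writeLines(paste(c(map$chrom[j], map$pos_bp[j], map$snp_id[j],
                         map$allele_ref[j], map$allele_alt[j], ".", "PASS",
                         ".", "GT", gs), collapse = "\t"), con)
    }
    close(con)
  } else {
    map_path <- sub("\\.ped$", ".map", path)
    utils::write.table(
      data.frame(map$chrom, map$snp_id, map$pos_cm, map$pos_bp),
      map_path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    n <- nrow(d)
    ped <- matrix("0", n, 6 + 2 * ncol(d))
    ped[, 1] <- ped[, 2] <- rownames(d)
    ped[, 5] <- "0"; ped[, 6] <- "-9"
    for (j in seq_len(ncol(d))) {
      g <- d[, j]
      a <- rep("0", n); b <- rep("0", n)
      a[!is.na(g) & g >= 1] <- map$allele_alt[j]
      a[!is.na(g) & g == 0] <- map$allele_ref[j]
      b[!is.na(g) & g == 2] <- map$allele_alt[j]
      b[!is.na(g) & g <= 1] <- map$allele_ref[j]
      b[is.na(g)] <- "0"
      ped[, 6 + 2 * j - 1] <- a
      ped[, 6 + 2 * j] <- b
    }
    utils::write.table(ped, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read or write a plot-level phenotype table
#'
#' TSV with columns `env`, `row`, `col`, `rep`, `line_id`, `element`,
#' `value`; missing values written as `.`.
#'
#' @param path file path.
#' @return a `plot_table` data.frame.
#' @export
read_plot_table <- function(path) {
  df <- read_tsv_dot(path, numeric_cols = c("row", "col", "rep", "value"))
  need <- c("env", "row", "col", "rep", "line_id", "element", "value")
  if (!all(need %in% names(df)))
    stop("plot table must have columns: ", paste(need, collapse = ", "))
  class(df) <- c("plot_table", "data.frame")
  df
}

#' @rdname read_plot_table
#' @param plots a `plot_table` data.frame.
#' @export
write_plot_table <- function(plots, path) {
  write_tsv_dot(as.data.frame(plots), path)
}
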