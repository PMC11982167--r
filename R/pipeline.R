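#' Run the full analysis workflow
#'
#' Orders the stages end to end: genotype QC (line filter, SNP filters,
#' LD-kNN imputation) -> per-trial BLUEs -> GRM -> GREML heritability and
#' genetic-correlation survey -> element grouping -> per-analysis MLM scans
#' -> three-way meta-analysis -> QTL clustering -> LD decay analysis. All
#' outputs are TSV files in `out_dir` plus a JSON manifest recording inputs,
#' parameters, seed, package version, and per-file checksums; rerunning with
#' the same config reproduces identical files.
#'
#' @param config list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{genotypes}{path to a genotype file, or a `genotype_matrix`.}
#'     \item{genotype_format}{`"auto"`, `"vcf"`, `"plink"`, `"tsv"`.}
#'     \item{plots}{path to a plot-table TSV, or a `plot_table`.}
#'     \item{out_dir}{output directory (created).}
#'     \item{qc}{list: `max_missing`, `min_call_rate`, `min_maf`,
#'       `k_neighbors`, `l_snps`.}
#'     \item{gwas}{list: `mode` (`"per_snp_lambda"` or `"null_lambda"`).}
#'     \item{meta}{list: `alpha`, `r2_cluster`, `overrides` (named list of
#'       element -> group).}
#'     \item{ld}{list: `span`, `quantile`, `max_pairs_per_chrom`,
#'       `n_inter_pairs`.}
#'     \item{seed}{integer master seed.}
#'   }
#' @param verbose print stage progress.
#' @return the output directory, invisibly; side effect: files written.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- config$seed %||% 1L
  out_dir <- config$out_dir %||% stop("config$out_dir required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message("[pleiometa] ", ...)
  t_start <- Sys.time()

  geno <- config$genotypes
  if (is.character(geno))
    geno <- read_genotypes(geno, config$genotype_format %||% "auto")
  plots <- config$plots
  if (is.character(plots)) plots <- read_plot_table(plots)

  qc_cfg <- config$qc %||% list()
  say("QC")
  qc <- qc_genotypes(geno,
                     max_missing = qc_cfg$max_missing %||% 0.40,
                     min_call_rate = qc_cfg$min_call_rate %||% 0.60,
                     min_maf = qc_cfg$min_maf %||% 0.05,
                     k_neighbors = qc_cfg$k_neighbors %||% 5L,
                     l_snps = qc_cfg$l_snps %||% 30L,
                     seed = derive_seed(seed, "qc"))
  geno <- qc$geno
  write_genotypes(geno, file.path(out_dir, "genotypes_qc.tsv"), "tsv")
  write_tsv_dot(as.data.frame(unclass(qc$report)),
                file.path(out_dir, "qc_report.tsv"))

  say("BLUEs")
  bl <- blues_all(plots)
  write_tsv_dot(bl$blues, file.path(out_dir, "blues.tsv"))
  write_tsv_dot(bl$fits, file.path(out_dir, "trial_fits.tsv"))
  bm <- blues_matrix(bl$blues)
  bm <- bm[intersect(rownames(geno$dosage), rownames(bm)), , drop = FALSE]

  say("GRM")
  grm <- stabilize_grm(compute_grm(geno))
  utils::write.table(data.frame(line_id = rownames(grm), grm,
                                check.names = FALSE),
                     file.path(out_dir, "grm.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_grm_gcta(grm, file.path(out_dir, "grm"), ncol(geno$dosage))

  say("GREML survey")
  surv <- greml_survey(bm, grm)
  write_tsv_dot(surv$h2, file.path(out_dir, "heritability.tsv"))
  write_tsv_dot(surv$rg, file.path(out_dir, "genetic_correlations.tsv"))
  utils::write.table(data.frame(element = rownames(surv$avg_rg), surv$avg_rg,
                                check.names = FALSE),
                     file.path(out_dir, "avg_rg.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  say("element grouping")
  meta_cfg <- config$meta %||% list()
  avg <- surv$avg_rg
  avg[is.na(avg)] <- 0
  grouping <- group_elements(avg, k = 2L, overrides = meta_cfg$overrides)
  write_tsv_dot(data.frame(element = names(grouping$groups),
                           group = grouping$groups),
                file.path(out_dir, "element_groups.tsv"))

  say("GWAS scans")
  gwas_cfg <- config$gwas %||% list()
  mode <- gwas_cfg$mode %||% "per_snp_lambda"
  eig_cache <- list()
  assoc <- list()
  for (cn in colnames(bm)) {
    y <- bm[, cn]
    ids <- names(y)[!is.na(y)]
    key <- paste(length(ids), ids[1], ids[length(ids)])
    if (is.null(eig_cache[[key]]))
      eig_cache[[key]] <- grm_eigen(grm[ids, ids])
    assoc[[cn]] <- mlm_scan(y[ids], geno, grm, mode = mode,
                            eig = eig_cache[[key]])
    write_tsv_dot(assoc[[cn]],
                  file.path(out_dir, paste0("assoc_", gsub(":", "_", cn), ".tsv")))
  }

  say("meta-analysis")
  tmat <- build_t_matrix(assoc)
  design <- run_meta_design(tmat, grouping,
                            alpha = meta_cfg$alpha %||% 0.05,
                            m = nrow(tmat$t))
  for (nm in c("meta1", "meta2", "meta")) {
    if (is.null(design[[nm]])) next
    write_tsv_dot(design[[nm]], file.path(out_dir, paste0(nm, ".tsv")))
  }
  write_tsv_dot(design$comparison, file.path(out_dir, "meta_comparison.tsv"))

  say("QTL clustering")
  qtl_all <- list()
  for (nm in c("meta1", "meta2", "meta")) {
    if (is.null(design[[nm]])) next
    q <- cluster_qtl(design[[nm]], geno, design$threshold,
                     r2_threshold = meta_cfg$r2_cluster %||% 0.5)
    if (nrow(q)) { q$analysis <- nm; qtl_all[[nm]] <- q }
  }
  qtl <- if (length(qtl_all)) do.call(rbind, qtl_all) else
    data.frame(qtl_id = character(), analysis = character())
  write_tsv_dot(qtl, file.path(out_dir, "qtl.tsv"))

  say("LD analysis")
  ld_cfg <- config$ld %||% list()
  ld <- ld_analysis(geno,
                    span = ld_cfg$span %||% 0.5,
                    quantile = ld_cfg$quantile %||% 0.99,
                    max_pairs_per_chrom = ld_cfg$max_pairs_per_chrom %||% 200000L,
                    n_inter_pairs = ld_cfg$n_inter_pairs %||% 100000L,
                    seed = derive_seed(seed, "ld"))
  write_tsv_dot(data.frame(dist_bp = ld$curve$grid_bp,
                           smoothed_r2 = ld$curve$smoothed_r2),
                file.path(out_dir, "ld_decay_curve.tsv"))
  write_tsv_dot(data.frame(background_ld = ld$background,
                           block_size_bp = ld$block_size_bp),
                file.path(out_dir, "ld_summary.tsv"))

  tsvs <- list.files(out_dir, pattern = "\\.tsv$", full.names = TRUE)
  manifest <- list(
    package = "pleiometa",
    version = as.character(utils::packageVersion("pleiometa")),
    seed = seed,
    n_meta_analyses = sum(!vapply(design[c("meta1", "meta2", "meta")],
                                  is.null, TRUE)),
    parameters = config[setdiff(names(config), c("genotypes", "plots"))],
    elapsed_sec = as.numeric(difftime(Sys.time(), t_start, units = "secs")),
    checksums = as.list(tools::md5sum(tsvs)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
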