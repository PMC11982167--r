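test_that("the t-matrix assembles signed t-values with the fixed column order", {
  snps <- paste0("S", 1:3)
  a1 <- mk_assoc(snps, beta = c(0.5, 0, 1), se = c(0.25, 1, 0.5),
                 flag = c("", "monomorphic", ""))
  a2 <- mk_assoc(snps[1:2], beta = c(-0.2, 0.3), se = c(0.1, 0.1),
                 pos = c(1e6, 2e6))
  tm <- build_t_matrix(list("Zn:E1" = a1, "Fe:E1" = a2))
  expect_equal(tm$t["S1", "Zn:E1"], 2.0)
  expect_equal(tm$t["S2", "Zn:E1"], 0)     # monomorphic entered as 0
  expect_true(tm$monomorphic["S2", "Zn:E1"])
  expect_true(is.na(tm$t["S3", "Fe:E1"]))  # absent analysis -> missing
  expect_equal(tm$analyses$element, c("Zn", "Fe"))

  ## 13 elements x 6 environments -> 78 columns
  full <- lapply(1:78, function(i) mk_assoc("S1", 1, 1))
  names(full) <- paste(rep(paste0("el", 1:13), each = 6),
                       rep(paste0("E", 1:6), 13), sep = ":")
  expect_equal(ncol(build_t_matrix(full)$t), 78L)

  ## inconsistent allele orientation is a hard error
  a3 <- mk_assoc(snps, beta = 1, se = 1)
  a3$allele_ref <- "B"; a3$allele_alt <- "A"
  expect_error(build_t_matrix(list("a:1" = a1, "b:1" = a3)), "inconsistent")
})

test_that("the t-correlation matrix behaves under independence, duplication, and permutation", {
  set.seed(51)
  tmock <- matrix(rnorm(10000 * 4), 10000, 4,
                  dimnames = list(paste0("S", 1:10000),
                                  c("a:1", "b:1", "c:1", "d:1")))
  tm <- list(t = tmock,
             map = data.frame(snp_id = rownames(tmock), chrom = "1A",
                              pos_bp = seq_len(10000), pos_cm = 0,
                              allele_ref = "A", allele_alt = "B"),
             analyses = data.frame(label = colnames(tmock),
                                   element = c("a", "b", "c", "d"),
                                   env = "1"))
  class(tm) <- "t_matrix"
  V <- estimate_v(tm)
  expect_lte(max(abs(V - diag(4))), 0.05)

  ## duplicated column -> unit off-diagonal
  tm2 <- tm
  tm2$t[, 2] <- tm2$t[, 1]
  V2 <- estimate_v(tm2)
  expect_equal(V2[1, 2], 1)

  ## invariant to SNP order
  perm <- sample(10000)
  tm3 <- tm
  tm3$t <- tm3$t[perm, ]
  tm3$map <- tm3$map[perm, ]
  expect_equal(estimate_v(tm3), V, tolerance = 1e-12)

  ## zero-variance column is a hard error naming the analysis
  tm4 <- tm
  tm4$t[, 3] <- 0
  expect_error(estimate_v(tm4), "c:1")
})

test_that("meta chi-square reproduces its closed-form identities", {
  snps <- paste0("S", 1:2)
  mk_tm <- function(tvals) {
    k <- ncol(tvals)
    lab <- paste0("a", 1:k, ":1")
    a <- lapply(1:k, function(j)
      mk_assoc(snps, beta = tvals[, j], se = 1))
    names(a) <- lab
    build_t_matrix(a)
  }
  ## t = (2,0,0), V = I: chi2 = 4, df = 3, p = upper chi2(3) tail at 4
  tm <- mk_tm(rbind(c(2, 0, 0), c(0, 0, 0)))
  V <- diag(3); dimnames(V) <- list(colnames(tm$t), colnames(tm$t))
  mc <- meta_chi2(tm, V)
  expect_equal(mc$chi2[1], 4)
  expect_equal(mc$df[1], 3)
  expect_equal(mc$p[1], pchisq(4, 3, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(mc$p[1], 0.2615, tolerance = 5e-4)
  ## all-zero t: chi2 = 0, p = 1
  expect_equal(mc$chi2[2], 0)
  expect_equal(mc$p[2], 1)

  ## V = I: chi2 equals the sum of squared t-values exactly
  set.seed(53)
  tv <- matrix(rnorm(10), 2, 5)
  tm5 <- mk_tm(tv)
  V5 <- diag(5); dimnames(V5) <- list(colnames(tm5$t), colnames(tm5$t))
  mc5 <- meta_chi2(tm5, V5)
  expect_equal(mc5$chi2, rowSums(tv^2), ignore_attr = TRUE, tolerance = 1e-12)

  ## one analysis: chi2 = t^2 and p matches the chi2(1)/normal identity
  tm1 <- mk_tm(matrix(c(1.7, -0.4), 2, 1))
  V1 <- diag(1); dimnames(V1) <- list(colnames(tm1$t), colnames(tm1$t))
  mc1 <- meta_chi2(tm1, V1)
  expect_equal(mc1$chi2, c(1.7, -0.4)^2, tolerance = 1e-12)
  expect_equal(mc1$p, 2 * pnorm(-abs(c(1.7, -0.4))), tolerance = 1e-12)
})

test_that("missing analyses reduce the per-SNP degrees of freedom", {
  a1 <- mk_assoc(paste0("S", 1:2), beta = c(2, 1), se = 1)
  a2 <- mk_assoc("S1", beta = 1, se = 1, pos = 1e6)
  tm <- build_t_matrix(list("a:1" = a1, "b:1" = a2))
  V <- diag(2); dimnames(V) <- list(colnames(tm$t), colnames(tm$t))
  mc <- meta_chi2(tm, V)
  expect_equal(mc$df[mc$snp_id == "S1"], 2)
  expect_equal(mc$df[mc$snp_id == "S2"], 1)
  expect_equal(mc$chi2[mc$snp_id == "S2"], 1)
})

test_that("chi-square is invariant to coherent sign flips of an analysis", {
  set.seed(57)
  k <- 4
  tv <- matrix(rnorm(20 * k), 20, k)
  a <- lapply(1:k, function(j) mk_assoc(paste0("S", 1:20), beta = tv[, j],
                                        se = 1, pos = (1:20) * 1e6))
  names(a) <- paste0("an", 1:k, ":1")
  tm <- build_t_matrix(a)
  V <- cor(tv); dimnames(V) <- list(colnames(tm$t), colnames(tm$t))
  mc <- meta_chi2(tm, V)
  ## flip analysis 2: t column and the corresponding rows/cols of V
  tm2 <- tm
  tm2$t[, 2] <- -tm2$t[, 2]
  V2 <- V
  V2[2, ] <- -V2[2, ]; V2[, 2] <- -V2[, 2]
  mc2 <- meta_chi2(tm2, V2)
  expect_equal(mc2$chi2, mc$chi2, tolerance = 1e-10)
})

test_that("Bonferroni threshold follows the quoted arithmetic", {
  expect_equal(bonferroni_threshold(0.05, 41666), 0.05 / 41666)
  expect_equal(bonferroni_threshold(0.05, 41666), 1.20002e-06,
               tolerance = 1e-5)
  expect_equal(-log10(bonferroni_threshold(0.05, 41666)), 5.92,
               tolerance = 1e-2)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_lt(bonferroni_threshold(0.05, 100), bonferroni_threshold(0.05, 10))
  expect_error(bonferroni_threshold(0.05, 0), "m")
})

test_that("QTL clustering follows the lead-based LD rule", {
  ## constructed dosages: S1-S2 in high LD, S3 independent
  set.seed(59)
  x1 <- rep(c(0, 2), each = 10)
  x2 <- x1; x2[c(1, 11)] <- 2 - x2[c(1, 11)]
  x3 <- sample(rep(c(0, 2), 10))
  stopifnot(pair_r2(x1, x2) > 0.5, pair_r2(x1, x3) < 0.5)
  g <- toy_geno(cbind(x1, x2, x3))
  meta <- data.frame(snp_id = paste0("S", 1:3), chrom = "1A",
                     pos_bp = (1:3) * 1e6, pos_cm = (1:3) * 0.2,
                     chi2 = c(40, 30, 25), df = 3,
                     p = c(1e-9, 1e-7, 1e-6), stringsAsFactors = FALSE)
  q <- cluster_qtl(meta, g, threshold = 1e-5, r2_threshold = 0.5)
  expect_equal(nrow(q), 2L)
  expect_equal(q$lead_snp, c("S1", "S3"))
  expect_equal(q$members[1], "S1,S2")

  ## SNPs on different chromosomes never merge even in perfect LD
  g2 <- toy_geno(cbind(x1, x1), chrom = c("1A", "2B"), pos = c(1e6, 1e6))
  meta2 <- meta[1:2, ]; meta2$chrom <- c("1A", "2B")
  q2 <- cluster_qtl(meta2, g2, threshold = 1e-5)
  expect_equal(nrow(q2), 2L)

  ## empty input -> empty output
  q0 <- cluster_qtl(meta[0, ], g, threshold = 1e-5)
  expect_equal(nrow(q0), 0L)
})

test_that("chained LD assigns clusters by the lead, not by adjacency", {
  ## construct r2(1,2) > 0.5, r2(2,3) > 0.5, r2(1,3) < 0.5
  x2 <- rep(c(0, 2), each = 12)
  x1 <- x2; x1[c(1, 13)] <- 2 - x1[c(1, 13)]
  x3 <- x2; x3[c(5, 17)] <- 2 - x3[c(5, 17)]
  stopifnot(pair_r2(x1, x2) > 0.5, pair_r2(x2, x3) > 0.5,
            pair_r2(x1, x3) < 0.5)
  g <- toy_geno(cbind(x1, x2, x3))
  base <- data.frame(snp_id = paste0("S", 1:3), chrom = "1A",
                     pos_bp = (1:3) * 1e6, pos_cm = (1:3) * 0.2,
                     chi2 = 1, df = 1, stringsAsFactors = FALSE)
  ## S2 most significant: one cluster {S1, S2, S3}
  m1 <- base; m1$p <- c(1e-7, 1e-9, 1e-7)
  q1 <- cluster_qtl(m1, g, threshold = 1e-5)
  expect_equal(nrow(q1), 1L)
  expect_equal(q1$lead_snp, "S2")
  ## S1 most significant: clusters {S1, S2} and {S3}
  m2 <- base; m2$p <- c(1e-9, 1e-7, 1e-6)
  q2 <- cluster_qtl(m2, g, threshold = 1e-5)
  expect_equal(nrow(q2), 2L)
  expect_equal(q2$lead_snp, c("S1", "S3"))

  ## every significant SNP lands in exactly one cluster
  all_members <- unlist(strsplit(q2$members, ","))
  expect_setequal(all_members, paste0("S", 1:3))
  expect_equal(anyDuplicated(all_members), 0L)
})

test_that("a grouping with one group equal to all elements makes Meta1 identical to Meta", {
  set.seed(61)
  k <- 4
  tv <- matrix(rnorm(300 * k), 300, k)
  a <- lapply(1:k, function(j) mk_assoc(paste0("S", 1:300), beta = tv[, j],
                                        se = 1, pos = (1:300) * 1e5))
  names(a) <- paste(c("a", "b", "c", "d"), "E1", sep = ":")
  tm <- build_t_matrix(a)
  grouping <- structure(list(
    groups = setNames(rep(1L, 4), c("a", "b", "c", "d")),
    members = list("1" = c("a", "b", "c", "d"))),
    class = "element_grouping")
  res <- run_meta_design(tm, grouping, alpha = 0.05, m = 300)
  expect_identical(res$meta1, res$meta)
  expect_null(res$meta2)
})

test_that("allelic effects are reported in phenotypic standard deviations", {
  blues <- data.frame(env = "E1", element = "Zn",
                      line_id = paste0("L", 1:20),
                      blue = c(rep(0, 10), rep(1, 10)),
                      stringsAsFactors = FALSE)
  dos <- setNames(c(rep(0, 10), rep(2, 10)), paste0("L", 1:20))
  eff <- allelic_effect_sd(blues, dos)
  expect_equal(eff$effect_sd, 1 / sd(blues$blue))

  ## identical class means -> 0; allele swap flips the sign
  blues2 <- blues; blues2$blue <- rep(c(0, 1), 10)
  dos2 <- setNames(c(rep(0, 10), rep(2, 10)), paste0("L", 1:20))
  expect_equal(allelic_effect_sd(blues2, dos2)$effect_sd, 0)
  expect_equal(allelic_effect_sd(blues, 2 - dos)$effect_sd,
               -eff$effect_sd)

  ## an empty homozygote class is flagged
  dos3 <- setNames(rep(2, 20), paste0("L", 1:20))
  eff3 <- allelic_effect_sd(blues, dos3)
  expect_true(is.na(eff3$effect_sd))
  expect_equal(eff3$flag, "insufficient_class")
})
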