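test_that("simulated inbred genotypes respect the parameter contracts", {
  g <- simulate_genotypes(50, data.frame(chrom = c("1A", "2B"), n_snps = 80,
                                         length_bp = 4e7),
                          missing_rate = 0, seed = 3)
  expect_false(anyNA(g$dosage))
  expect_true(all(g$dosage %in% c(0, 2)))          # doubled haplotypes
  expect_true(all(apply(g$dosage, 2, snp_maf) >= 0.05))
  for (ch in unique(g$map$chrom))
    expect_false(is.unsorted(g$map$pos_bp[g$map$chrom == ch], strictly = TRUE))

  g2 <- simulate_genotypes(50, data.frame(chrom = c("1A", "2B"), n_snps = 80,
                                          length_bp = 4e7),
                           missing_rate = 0.1, seed = 3)
  expect_equal(sum(is.na(g2$dosage)), round(0.1 * length(g2$dosage)))

  ## bit-identical under a fixed seed
  g3 <- simulate_genotypes(50, data.frame(chrom = c("1A", "2B"), n_snps = 80,
                                          length_bp = 4e7),
                           missing_rate = 0.1, seed = 3)
  expect_identical(g2$dosage, g3$dosage)
  expect_identical(g2$map, g3$map)

  expect_error(simulate_genotypes(1), "n_lines")
  expect_error(simulate_genotypes(10, maf_min = 0.6), "maf_min")
})

test_that("ld_scale -> 0 collapses adjacent-SNP r2 to the inter-chromosomal background", {
  adj <- bgm <- numeric(5)
  for (s in 1:5) {
    g <- simulate_genotypes(150, data.frame(chrom = c("1A", "2B"),
                                            n_snps = 150, length_bp = 6e7),
                            ld_scale = 1, seed = s)
    map <- g$map
    r2a <- c()
    for (ch in unique(map$chrom)) {
      idx <- which(map$chrom == ch)
      r2a <- c(r2a, vapply(seq_len(length(idx) - 1), function(i)
        pair_r2(g$dosage[, idx[i]], g$dosage[, idx[i + 1]]), 0.0))
    }
    adj[s] <- mean(r2a, na.rm = TRUE)
    bg <- background_ld(g, n_pairs = 3000, seed = s)
    bgm[s] <- mean(attr(bg, "r2"))
  }
  dif <- adj - bgm
  se <- sd(dif) / sqrt(length(dif))
  expect_lt(abs(mean(dif)), 2 * se + 1e-3)
})

test_that("trait architecture meets its construction contracts", {
  g <- simulate_genotypes(200, data.frame(chrom = c("1A", "2B"), n_snps = 200,
                                          length_bp = 6e7), seed = 7)
  arch <- simulate_architecture(g, elements = c("Ca", "K", "Fe", "Zn", "Mg"),
                                group1 = c("Ca", "K"), n_shared = 10,
                                n_private = 1, n_antagonistic = 1,
                                h2_target = 0.4, seed = 7)
  ant <- arch$qtl[arch$qtl$type == "antagonistic", ]
  expect_equal(nrow(ant), 1L)
  eff <- as.numeric(ant[1, arch$elements])
  g1 <- arch$elements %in% arch$groups$group1
  expect_true(all(sign(eff[g1]) == sign(eff[g1][1])))
  expect_true(all(sign(eff[!g1]) == -sign(eff[g1][1])))

  ## per-element genetic variance matches the h2 target scale by construction
  vg <- apply(arch$genetic_values, 2, var)
  expect_equal(unname(vg), rep(0.4 / 0.6, 5), tolerance = 1e-10)

  ## QTL SNPs polymorphic at the floor
  maf <- apply(g$dosage[, arch$qtl$snp_id], 2, snp_maf)
  expect_true(all(maf >= 0.05))

  expect_error(simulate_architecture(g, elements = c("A", "B"), group1 = "A",
                                     n_shared = 10000, seed = 1),
               "QTL")
})

test_that("rg_within = 1 with only shared QTL gives perfectly correlated groups", {
  g <- simulate_genotypes(150, data.frame(chrom = "1A", n_snps = 150,
                                          length_bp = 6e7), seed = 5)
  arch <- simulate_architecture(g, elements = c("a", "b", "c", "d"),
                                group1 = c("a", "b"), n_shared = 12,
                                n_private = 0, n_antagonistic = 0,
                                rg_within = 1, rg_between = 1,
                                h2_target = 0.4, seed = 5)
  cg <- cor(arch$genetic_values)
  expect_equal(max(abs(cg - 1)), 0, tolerance = 1e-8)
})

test_that("between-group genetic correlation tracks its target over seeds", {
  rgs <- numeric(20)
  for (s in 1:20) {
    g <- simulate_genotypes(200, data.frame(chrom = "1A", n_snps = 120,
                                            length_bp = 6e7), seed = s)
    arch <- simulate_architecture(g, elements = c("a", "b", "c", "d"),
                                  group1 = c("a", "b"), n_shared = 20,
                                  n_private = 0, n_antagonistic = 0,
                                  rg_within = 0.45, rg_between = -0.2,
                                  seed = s)
    cg <- cor(arch$genetic_values)
    rgs[s] <- mean(cg[c("a", "b"), c("c", "d")])
  }
  expect_lt(abs(mean(rgs) - (-0.2)), 0.15)
})

test_that("field trials follow the design and the noise-free limit", {
  g <- simulate_genotypes(40, data.frame(chrom = "1A", n_snps = 80,
                                         length_bp = 4e7), seed = 2)
  arch <- simulate_architecture(g, elements = c("Zn", "Fe"), group1 = "Zn",
                                n_shared = 6, n_private = 0,
                                n_antagonistic = 0, seed = 2)
  envs <- list(list(label = "E1", lines = rownames(g$dosage), n_reps = 2,
                    n_row = 10, n_col = 8))
  ## noise-free: plot value = intercept + genetic value exactly
  pl0 <- simulate_trials(g, arch, envs, spatial_sd = 0, rep_sd = 0,
                         resid_sd = 0, intercept = 5, seed = 4)
  expect_equal(pl0$value,
               5 + arch$genetic_values[cbind(pl0$line_id, pl0$element)],
               tolerance = 1e-12)

  ## two plots per (env, line, element)
  pl <- simulate_trials(g, arch, envs, seed = 4)
  cnt <- table(pl$line_id, pl$element)
  expect_true(all(cnt == 2))
  ## one plot per (env, row, col) per element
  expect_false(anyDuplicated(pl[pl$element == "Zn", c("row", "col")]) > 0)

  ## deterministic under the seed
  pl2 <- simulate_trials(g, arch, envs, seed = 4)
  expect_identical(pl, pl2)

  expect_error(simulate_trials(g, arch,
                               list(list(label = "X", lines = "nope",
                                         n_reps = 2, n_row = 5, n_col = 5))),
               "absent")
})

test_that("simulate_study wires the subset design together", {
  st <- simulate_study(n_lines = 60,
                       chrom_plan = data.frame(chrom = c("1A", "2B"),
                                               n_snps = 60, length_bp = 4e7),
                       missing_rate = 0, n_subset = 25, seed = 6,
                       elements = c("Ca", "Zn"), group1 = "Ca",
                       n_shared = 5, n_private = 1, n_antagonistic = 0)
  expect_length(st$envs, 6L)
  n_lines_per_env <- tapply(st$plots$line_id, st$plots$env,
                            function(x) length(unique(x)))
  expect_setequal(unname(n_lines_per_env), c(60, 60, 25, 25, 25, 25))
})
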