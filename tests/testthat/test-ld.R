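test_that("pairwise r2 matches direct correlation and its symmetries", {
  x <- c(0, 2, 2, 0, 2)
  y <- c(0, 2, 0, 0, 2)
  expect_equal(pair_r2(x, x), 1)
  expect_equal(pair_r2(x, 2 - x), 1)          # allele-label free
  expect_equal(pair_r2(x, y), cor(x, y)^2)    # brute-force oracle
  expect_equal(pair_r2(x, y), pair_r2(y, x))
  expect_true(is.na(pair_r2(x, rep(2, 5))))   # monomorphic flagged as NA
  ## missing entries drop pairwise
  x2 <- c(0, 2, NA, 0, 2); y2 <- c(0, 2, 0, NA, 2)
  ok <- !is.na(x2) & !is.na(y2)
  expect_equal(pair_r2(x2, y2), cor(x2[ok], y2[ok])^2)
})

test_that("intra-chromosomal pair sampling is exhaustive under the cap and reproducible", {
  g <- hwe_geno(30, 12, seed = 63)
  p <- sample_intra_pairs(g, max_pairs_per_chrom = 1000, seed = 1)
  expect_equal(nrow(p), choose(12, 2))
  expect_true(all(p$dist_bp >= 0))
  expect_true(all(p$dist_bp <= max(g$map$pos_bp)))

  g2 <- simulate_genotypes(40, data.frame(chrom = "1A", n_snps = 80,
                                          length_bp = 4e7), seed = 64)
  pa <- sample_intra_pairs(g2, max_pairs_per_chrom = 500, seed = 5)
  pb <- sample_intra_pairs(g2, max_pairs_per_chrom = 500, seed = 5)
  expect_equal(nrow(pa), 500L)
  expect_identical(pa, pb)
  ## sampled fast path agrees with the direct pair computation
  idx <- sample(nrow(pa), 20)
  direct <- mapply(function(a, b)
    pair_r2(g2$dosage[, a], g2$dosage[, b]), pa$snp_a[idx], pa$snp_b[idx])
  expect_equal(pa$r2[idx], unname(direct), tolerance = 1e-12)
})

test_that("background LD reproduces the quantile oracle", {
  ## constant inter-chromosomal r2 -> background equals it
  x <- rep(c(0, 2), 8)
  d <- cbind(x, x, x, x)
  g <- toy_geno(d, chrom = c("1A", "1A", "2B", "2B"),
                pos = c(1e6, 2e6, 1e6, 2e6))
  bg <- background_ld(g, n_pairs = 200, seed = 1)
  expect_equal(as.numeric(bg), 1)

  ## sort-and-interpolate oracle on the sampled values
  g2 <- simulate_genotypes(60, data.frame(chrom = c("1A", "2B"), n_snps = 50,
                                          length_bp = 4e7), seed = 65)
  bg2 <- background_ld(g2, n_pairs = 2000, quantile = 0.99, seed = 7)
  r2 <- attr(bg2, "r2")
  s <- sort(r2)
  h <- (length(s) - 1) * 0.99 + 1
  lo <- floor(h)
  oracle <- s[lo] + (h - lo) * (s[lo + 1] - s[lo])
  expect_equal(as.numeric(bg2), oracle, tolerance = 1e-12)

  expect_error(background_ld(toy_geno(matrix(c(0, 2), 4, 3)), 10),
               "two chromosomes")
})

test_that("background LD scales like the chi-square tail of independent panels", {
  g <- simulate_genotypes(200, data.frame(chrom = c("1A", "2B", "3D"),
                                          n_snps = 150, length_bp = 6e7),
                          ld_scale = 1, n_founders = 150, seed = 67)
  bg <- as.numeric(background_ld(g, n_pairs = 20000, seed = 67))
  expected <- qchisq(0.99, 1) / 200
  expect_lt(abs(bg - expected), 0.5 * expected + 0.005)
})

test_that("loess decay reproduces constants and exact quadratics", {
  set.seed(69)
  pairs_const <- data.frame(dist_bp = runif(200, 0, 1e7), r2 = 0.3)
  cv <- loess_decay(pairs_const, span = 0.75)
  expect_equal(cv$smoothed_r2, rep(0.3, length(cv$grid_bp)), tolerance = 1e-9)

  d <- seq(0, 1e7, length.out = 300)
  quad <- 0.8 - 6e-8 * d + 2e-15 * d^2
  cv2 <- loess_decay(data.frame(dist_bp = d, r2 = quad), span = 1,
                     grid_points = 50)
  truth <- 0.8 - 6e-8 * cv2$grid_bp + 2e-15 * cv2$grid_bp^2
  expect_equal(cv2$smoothed_r2, pmax(truth, 0), tolerance = 1e-6)
})

test_that("block size interpolates the background crossing exactly", {
  ## a curve constructed to cross 0.176 at exactly 7 Mb
  grid <- seq(0, 2e7, length.out = 201)
  sm <- 0.176 + (7e6 - grid) * 1e-8
  curve <- structure(list(grid_bp = grid, smoothed_r2 = sm, span = 0.5,
                          degree = 2L, background = 0.176),
                     class = "ld_decay")
  expect_equal(block_size(curve), 7e6, tolerance = 1)

  ## never reaching the background -> undefined
  curve2 <- curve
  curve2$smoothed_r2 <- sm + 10
  expect_true(is.na(block_size(curve2)))

  ## starting below the background -> 0
  curve3 <- curve
  curve3$smoothed_r2 <- rep(0.01, 201)
  expect_equal(block_size(curve3), 0)
})

test_that("synthetic germplasm decay is monotone-ish and the analysis is seed-stable", {
  g <- simulate_genotypes(150, data.frame(chrom = c("1A", "2B"), n_snps = 200,
                                          length_bp = 8e7), seed = 71)
  res <- ld_analysis(g, max_pairs_per_chrom = 8000, n_inter_pairs = 8000,
                     seed = 3)
  res2 <- ld_analysis(g, max_pairs_per_chrom = 8000, n_inter_pairs = 8000,
                      seed = 3)
  expect_identical(res$block_size_bp, res2$block_size_bp)
  sm <- res$curve$smoothed_r2
  n <- length(sm)
  skip_first <- ceiling(0.05 * n)
  drops <- diff(sm[skip_first:n])
  expect_gte(mean(drops <= 1e-4), 0.9)   # largely non-increasing
  expect_gt(sm[skip_first], res$background)
})
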