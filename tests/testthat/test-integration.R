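rand_dist <- function(n, seed) {
  set.seed(seed)
  as.matrix(dist(matrix(rnorm(2 * n), ncol = 2)))
}

test_that("two-block PLS detects and quantifies shared structure", {
  set.seed(101)
  x <- matrix(rnorm(200), ncol = 4)
  res <- two_block_pls(x, x, n_perm = 49)
  expect_gt(res$score_correlations[1], 0.999)
  expect_true(all(diff(res$singular_values) <= 1e-12))
  expect_true(all(abs(res$score_correlations) <= 1))
  expect_error(two_block_pls(x, x[1:10, ]), "share specimens")
  # planted rank-1 cross-covariance along known directions
  n <- 200
  u <- c(1, -1, 0.5, 0); u <- u / sqrt(sum(u^2))
  v <- c(0.3, 1, -0.2); v <- v / sqrt(sum(v^2))
  s <- rnorm(n, sd = 3)
  X <- outer(s, u) + matrix(rnorm(n * 4, sd = 0.3), n)
  Y <- outer(s, v) + matrix(rnorm(n * 3, sd = 0.3), n)
  res2 <- two_block_pls(X, Y, n_perm = 99)
  expect_gt(abs(sum(res2$x_loadings[, 1] * u)), 0.99)
  expect_gt(abs(sum(res2$y_loadings[, 1] * v)), 0.99)
  expect_equal(res2$permutation_p[1], 1 / 100)
})

test_that("Mantel r equals the Pearson correlation of triangle vectors", {
  a4 <- matrix(c(0, 1, 2, 3,
                 1, 0, 1.5, 2.5,
                 2, 1.5, 0, 1,
                 3, 2.5, 1, 0), 4)
  b4 <- matrix(c(0, 1.2, 1.8, 2.9,
                 1.2, 0, 1.1, 2.2,
                 1.8, 1.1, 0, 1.4,
                 2.9, 2.2, 1.4, 0), 4)
  res <- mantel_test(a4, b4, n_perm = 99)
  va <- a4[lower.tri(a4)]; vb <- b4[lower.tri(b4)]
  expect_equal(res$r, cor(va, vb), tolerance = 1e-12)
  self <- mantel_test(a4, a4, n_perm = 19)
  expect_equal(self$r, 1)
  expect_error(mantel_test(a4, matrix(0, 4, 4), n_perm = 9), "constant")
})

test_that("Mantel agrees with an independent implementation", {
  skip_if_not_installed("vegan")
  a <- rand_dist(12, 102); b <- rand_dist(12, 103)
  ours <- mantel_test(a, b, n_perm = 99)
  ref <- vegan::mantel(as.dist(a), as.dist(b), permutations = 99)
  expect_equal(ours$r, unname(ref$statistic), tolerance = 1e-12)
})

test_that("partial Mantel removes a planted confound", {
  set.seed(104)
  n <- 20
  w <- rnorm(n)                      # confounding gradient
  z <- rnorm(n)                      # signal gradient
  C <- as.matrix(dist(w))
  B <- as.matrix(dist(z))
  A <- 0.8 * B + 1.2 * C             # A carries both, plus the confound
  simple <- mantel_test(dist_matrix(A), dist_matrix(B), n_perm = 99)
  partial <- partial_mantel(dist_matrix(A), dist_matrix(B),
                            dist_matrix(C), n_perm = 999)
  # oracle: direct correlation of OLS residual vectors
  va <- A[lower.tri(A)]; vb <- B[lower.tri(B)]; vc <- C[lower.tri(C)]
  r_expect <- cor(resid(lm(va ~ vc)), resid(lm(vb ~ vc)))
  expect_equal(partial$r, r_expect, tolerance = 1e-12)
  expect_lt(partial$p_value, 0.01)
  # uncorrelated control: partial approximately equals simple
  C2 <- rand_dist(n, 105)
  p2 <- partial_mantel(dist_matrix(A), dist_matrix(B), dist_matrix(C2),
                       n_perm = 99)
  expect_equal(p2$r, simple$r, tolerance = 0.1)
  # A equal to the control up to exchangeable noise: association gone
  set.seed(106)
  E <- matrix(0, n, n)
  E[lower.tri(E)] <- rnorm(n * (n - 1) / 2, sd = 0.05)
  A3 <- pmax(C + E + t(E), 0); diag(A3) <- 0
  p3 <- partial_mantel(dist_matrix(A3), dist_matrix(B), dist_matrix(C),
                       n_perm = 199)
  expect_lt(abs(p3$r), 0.2)
  expect_gt(p3$p_value, 0.05)
  expect_error(partial_mantel(dist_matrix(C), dist_matrix(B),
                              dist_matrix(C), n_perm = 9), "collinear")
})

test_that("distance scaling to unit maximum is exact and idempotent", {
  m <- matrix(c(0, 2, 4, 2, 0, 3, 4, 3, 0), 3)
  s <- scale_to_unit(m)
  expect_equal(max(s), 1)
  expect_equal(s[1, 2], 0.5)
  expect_equal(unclass(scale_to_unit(s)), unclass(s), ignore_attr = TRUE)
  expect_error(scale_to_unit(matrix(0, 3, 3)), "zero")
})

test_that("SNP thinning walks chromosomes greedily", {
  g <- genotype_data(matrix(0:2, 3, 4),
                     loci = data.frame(chrom = "chr1",
                                       pos = c(1L, 400000L, 600000L,
                                               1200000L)),
                     samples = c("a", "b", "c"))
  out <- suppressMessages(filter_snps(g, min_spacing = 500000))
  expect_equal(out$loci$pos, c(1L, 600000L, 1200000L))
  # a single missing genotype drops the locus
  g$genotypes[2, 3] <- NA
  out2 <- suppressMessages(filter_snps(g, min_spacing = 500000))
  expect_equal(out2$loci$pos, c(1L, 1200000L))
  out3 <- suppressMessages(filter_snps(g, min_spacing = 500000,
                                       require_complete = FALSE))
  expect_equal(out3$loci$pos, c(1L, 600000L, 1200000L))
  # empty input passes through
  g0 <- genotype_data(matrix(integer(0), 3, 0),
                      loci = data.frame(chrom = character(0),
                                        pos = integer(0)),
                      samples = c("a", "b", "c"))
  expect_equal(nrow(suppressMessages(filter_snps(g0))$loci), 0L)
  # property: no two kept loci closer than the spacing
  set.seed(107)
  pos <- sort(sample.int(5e6, 300))
  pos <- pos[!duplicated(pos)]
  gr <- genotype_data(matrix(1L, 2, length(pos)),
                      loci = data.frame(chrom = "c1", pos = pos),
                      samples = c("a", "b"))
  kept <- suppressMessages(filter_snps(gr, min_spacing = 250000))
  expect_true(all(diff(kept$loci$pos) >= 250000))
})

test_that("genotype PCA separates structured populations", {
  haplo <- rbind(matrix(0L, 5, 40), matrix(2L, 5, 40))
  g <- genotype_data(haplo,
                     loci = data.frame(chrom = "c1", pos = seq_len(40)),
                     samples = paste0("s", 1:10))
  p <- genotype_pca(g)
  expect_lt(var(p$scores[1:5, 1]), 1e-18)
  expect_gt(abs(mean(p$scores[1:5, 1]) - mean(p$scores[6:10, 1])), 1)
  m <- g$genotypes
  expect_equal(sum(p$eigenvalues), sum(apply(m, 2, var)))
  g0 <- genotype_data(matrix(1L, 4, 3),
                      loci = data.frame(chrom = "c1", pos = 1:3),
                      samples = paste0("s", 1:4))
  expect_error(genotype_pca(g0), "monomorphic")
})

test_that("Hudson F_ST matches hand arithmetic and its invariances", {
  # pop1: 20 diploids, 8 alt alleles (p = 0.2); pop2: p = 0.8
  g1 <- c(rep(2L, 4), rep(0L, 16))
  g2 <- c(rep(2L, 16), rep(0L, 4))
  g <- genotype_data(matrix(c(g1, g2), ncol = 1),
                     loci = data.frame(chrom = "c1", pos = 1L),
                     samples = paste0("s", 1:40))
  pops <- rep(c("p1", "p2"), each = 20)
  fst <- pairwise_fst(g, pops)
  # hand: num = 0.36 - 2 * (0.2 * 0.8 / 39); den = 0.04 + 0.64
  hand <- (0.36 - 2 * (0.16 / 39)) / 0.68
  expect_equal(fst["p1", "p2"], hand, tolerance = 1e-9)
  # allele-label swap leaves the estimator unchanged
  gs <- g; gs$genotypes <- 2L - gs$genotypes
  expect_equal(pairwise_fst(gs, pops)["p1", "p2"], hand, tolerance = 1e-12)
  # alternate fixed alleles give F_ST 1
  gf <- genotype_data(cbind(rep(c(0L, 2L), each = 4), rep(c(2L, 0L), each = 4)),
                      loci = data.frame(chrom = "c1", pos = c(1L, 2L)),
                      samples = paste0("s", 1:8))
  expect_equal(pairwise_fst(gf, rep(c("a", "b"), each = 4))["a", "b"], 1)
})

test_that("F_ST is centred at zero for a randomly split pool", {
  set.seed(108)
  vals <- numeric(50)
  for (i in 1:50) {
    p <- runif(60, 0.1, 0.9)
    geno <- vapply(p, function(pp) rbinom(30L, 2L, pp), integer(30L))
    g <- genotype_data(geno, loci = data.frame(chrom = "c1", pos = 1:60),
                       samples = paste0("s", 1:30))
    vals[i] <- attr(pairwise_fst(g, rep(c("a", "b"), 15)), "raw")[1, 2]
  }
  expect_lt(abs(mean(vals)), 0.01)
})
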