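test_that("PCA recovers a diagonal covariance structure", {
  set.seed(61)
  x <- cbind(rnorm(20000, sd = sqrt(2)), rnorm(20000, sd = 1))
  p <- pca(x)
  expect_equal(p$eigenvalues, c(2, 1), tolerance = 0.05)
  expect_gt(abs(p$axes[1, 1]), 0.999)
  expect_lt(max(abs(colMeans(p$scores))), 1e-9)
  cr <- crossprod(p$scores) / (nrow(x) - 1)
  expect_lt(max(abs(cr[lower.tri(cr)])), 1e-9)
  expect_equal(sum(p$eigenvalues), sum(apply(x, 2, var)))
  expect_lt(max(abs(crossprod(p$axes) - diag(2))), 1e-9)
  x[1, 1] <- NA
  expect_error(pca(x), "missing")
})

test_that("equal-frequency ellipse has the chi-square geometry", {
  set.seed(62)
  x <- matrix(rnorm(400), 200, 2)
  # whiten so the sample covariance is exactly the identity
  x <- sweep(x, 2, colMeans(x))
  e <- eigen(cov(x), symmetric = TRUE)
  x <- x %*% e$vectors %*% diag(1 / sqrt(e$values)) %*% t(e$vectors)
  spec <- equal_frequency_ellipse(x, probability = 0.9)
  # chi-square(2) has closed-form CDF 1 - exp(-q/2): q = -2 log(0.1)
  expect_equal(spec$q, -2 * log(0.1), tolerance = 1e-12)
  expect_equal(spec$area, pi * -2 * log(0.1), tolerance = 1e-9)
  expect_equal(spec$center, colMeans(x))
  expect_true(all(in_ellipse(spec, matrix(0, 1, 2))))
  expect_error(equal_frequency_ellipse(cbind(1:5, 2 * (1:5))), "singular")
  expect_error(equal_frequency_ellipse(x, probability = 1.2), "probability")
})

test_that("SEA matches hand eigen-arithmetic and its analytic limit", {
  pts <- matrix(c(1, 2, 2.5, 1.1, 0.3, 3, 4, 2.2, 1.7, 0.5),
                ncol = 2, byrow = TRUE)
  # independent route: covariance by sums, eigenvalues via the
  # quadratic formula
  n <- nrow(pts)
  mx <- mean(pts[, 1]); my <- mean(pts[, 2])
  sxx <- sum((pts[, 1] - mx)^2) / (n - 1)
  syy <- sum((pts[, 2] - my)^2) / (n - 1)
  sxy <- sum((pts[, 1] - mx) * (pts[, 2] - my)) / (n - 1)
  tr <- sxx + syy; det2 <- sxx * syy - sxy^2
  l1 <- (tr + sqrt(tr^2 - 4 * det2)) / 2
  l2 <- (tr - sqrt(tr^2 - 4 * det2)) / 2
  res <- sea_seac(pts)
  expect_equal(res$sea, pi * sqrt(l1 * l2), tolerance = 1e-9)
  expect_equal(res$seac / res$sea, (n - 1) / (n - 2))
  set.seed(63)
  big <- matrix(rnorm(2e5), ncol = 2)
  expect_equal(sea_seac(big)$sea, pi, tolerance = 0.02)
  expect_error(sea_seac(big[1:2, ]), "at least 3")
})

test_that("ellipse overlap matches closed-form lens area", {
  mk <- function(cx) {
    s <- equal_frequency_ellipse(matrix(rnorm(20), 10, 2))
    s$center <- c(cx, 0); s$covariance <- diag(2); s$q <- 1
    s$area <- pi
    s
  }
  a <- mk(0); b <- mk(1)
  expect_equal(ellipse_overlap(a, a), pi, tolerance = 1e-3)
  # two unit circles at distance 1: lens = 2 acos(1/2) - sqrt(3)/2 * 1
  lens <- 2 * acos(0.5) - 0.5 * sqrt(3)
  expect_equal(ellipse_overlap(a, b), lens, tolerance = 0.01 * lens)
  far <- mk(10)
  expect_equal(ellipse_overlap(a, far), 0)
})

test_that("CVA equals the Fisher discriminant for two groups", {
  set.seed(64)
  n <- 120
  x <- rbind(MASS::mvrnorm(n, c(0, 0, 0), diag(c(2, 1, 0.5))),
             MASS::mvrnorm(n, c(1, 0.5, -0.4), diag(c(2, 1, 0.5))))
  g <- rep(c("a", "b"), each = n)
  res <- cva(x, g, n_perm = 99)
  # closed-form direction: W^-1 (mean difference); undo the PCA
  # rotation applied inside cva
  p <- pca(x)
  z <- p$scores
  W <- (crossprod(sweep(z[1:n, ], 2, colMeans(z[1:n, ]))) +
          crossprod(sweep(z[-(1:n), ], 2, colMeans(z[-(1:n), ])))) /
    (2 * n - 2)
  fisher <- solve(W, colMeans(z[-(1:n), ]) - colMeans(z[1:n, ]))
  ax <- res$ordination$axes[, 1]
  cosine <- abs(sum(ax * fisher)) / sqrt(sum(ax^2) * sum(fisher^2))
  expect_gt(cosine, 0.999)
  expect_equal(res$pairwise$p_mahalanobis[1], 0.01)
})

test_that("CVA Mahalanobis distance is calibrated and affine invariant", {
  n <- 250; sigma <- 0.7; delta <- c(1, -0.5, 0.25)
  gen <- function(seed) {
    set.seed(seed)
    rbind(matrix(rnorm(3 * n, sd = sigma), ncol = 3),
          sweep(matrix(rnorm(3 * n, sd = sigma), ncol = 3), 2,
                delta, `+`))
  }
  g <- rep(c("a", "b"), each = n)
  ds <- vapply(65:68, function(s)
    cva(gen(s), g, n_perm = 9)$mahalanobis["a", "b"], numeric(1))
  expect_equal(mean(ds), sqrt(sum(delta^2)) / sigma, tolerance = 0.05)
  set.seed(65)
  x <- gen(65)
  res <- cva(x, g, n_perm = 19)
  A <- matrix(c(2, 0.5, 0, -0.3, 1.5, 0.2, 0.1, 0, 0.8), 3)
  res2 <- cva(x %*% A, g, n_perm = 19)
  expect_equal(res2$mahalanobis, res$mahalanobis, tolerance = 1e-6)
  # null data: shuffled labels on one cloud
  set.seed(66)
  x0 <- matrix(rnorm(160), ncol = 2)
  res0 <- cva(x0, sample(rep(c("a", "b"), each = 40)), n_perm = 199)
  expect_lt(res0$mahalanobis["a", "b"], 0.6)
  expect_gt(res0$pairwise$p_mahalanobis[1], 0.01)
})

test_that("NPMANOVA on univariate Euclidean distances equals ANOVA F", {
  set.seed(67)
  vals <- rnorm(24)
  g <- rep(c("a", "b", "c"), each = 8)
  d <- as.matrix(dist(vals))
  res <- suppressMessages(npmanova(d, g, n_perm = 49, pairwise = FALSE))
  expect_equal(res$statistic, anova_oneway(vals, g)$statistic,
               tolerance = 1e-9)
})

test_that("NPMANOVA agrees with an independent PERMANOVA implementation", {
  skip_if_not_installed("vegan")
  set.seed(68)
  x <- matrix(rnorm(60), ncol = 3)
  g <- rep(c("a", "b"), each = 10)
  d <- dist(x)
  ours <- npmanova(as.matrix(d), g, n_perm = 49, pairwise = FALSE)
  ref <- vegan::adonis2(d ~ g, permutations = 49)
  expect_equal(ours$statistic, ref$F[1], tolerance = 1e-9)
})

test_that("NPMANOVA handles perfect separation and validates input", {
  d <- matrix(1, 4, 4) - diag(4)
  d[1, 2] <- d[2, 1] <- 0; d[3, 4] <- d[4, 3] <- 0
  res <- npmanova(d, c("a", "a", "b", "b"), n_perm = 99, pairwise = FALSE)
  expect_identical(res$statistic, Inf)
  expect_equal(res$p_value, 1 / 100, tolerance = 0.05)
  expect_gte(res$p_value, 1 / 100)
  expect_error(npmanova(d, c("a", "a", "a", "b"), n_perm = 9),
               "at least 2")
  expect_error(npmanova(d[1:3, 1:3], c("a", "a", "b", "b"), n_perm = 9),
               "does not match")
})

test_that("one-way ANOVA and Holm adjustment match hand computation", {
  # groups (1,2,3) and (2,4,6): SSB = 6, SSW = 10, F = 6 / 2.5 = 2.4
  res <- anova_oneway(c(1, 2, 3, 2, 4, 6), rep(c("a", "b"), each = 3))
  expect_equal(res$statistic, 2.4, tolerance = 1e-12)
  expect_equal(res$p_value, pf(2.4, 1, 4, lower.tail = FALSE))
  expect_error(anova_oneway(c(1, 1, 1, 1), c("a", "a", "b", "b")),
               "zero within-group variance")
  # Holm by hand: sorted (0.01,0.03,0.04) * (3,2,1) -> (0.03,0.06,0.04),
  # cumulative max restores monotonicity -> (0.03,0.06,0.06)
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  p <- runif(10)
  expect_true(all(holm_adjust(p) >= p))
})

test_that("Pearson correlation matches direct arithmetic", {
  x <- c(1, 2, 3, 5); y <- c(2, 1, 4, 6)
  num <- sum((x - mean(x)) * (y - mean(y)))
  den <- sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson(x, y)$r, num / den, tolerance = 1e-12)
  expect_equal(pearson(x, x)$r, 1)
  expect_equal(pearson(x, -x)$r, -1)
  expect_error(pearson(x, rep(1, 4)), "zero variance")
})

test_that("permutation p-values use the +1 correction", {
  set.seed(69)
  x <- matrix(rnorm(40), ncol = 2)
  g <- rep(c("a", "b"), each = 10)
  res <- npmanova(as.matrix(dist(x)), g, n_perm = 19, pairwise = FALSE)
  expect_gte(res$p_value, 1 / 20)
  expect_lte(res$p_value, 1)
})
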