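test_that("centroid size has the defining metric properties", {
  square <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1), ncol = 2, byrow = TRUE)
  # sqrt(sum of squared distances from the centroid) = sqrt(4 * 0.5)
  expect_equal(centroid_size(square), sqrt(2))
  tri <- triangle_a
  expect_equal(centroid_size(tri * 3), 3 * centroid_size(tri))
  expect_equal(centroid_size(sweep(tri, 2, c(10, -7), `+`)),
               centroid_size(tri))
  expect_error(centroid_size(matrix(1, 4, 2)), "degenerate")
})

test_that("GPA aligns similarity-transformed copies exactly", {
  set.seed(11)
  tri <- triangle_a
  configs <- lapply(1:6, function(i) random_similarity(tri))
  al <- gpa(landmark_set(configs))
  for (i in 2:6) {
    expect_lt(max(abs(al$coords[i, , ] - al$coords[1, , ])), 1e-8)
    expect_lt(procrustes_distance(al$coords[i, , ], al$coords[1, , ]), 1e-7)
  }
})

test_that("GPA output is invariant to similarity transforms of inputs", {
  set.seed(12)
  lm <- make_fish_set(n = 6L)
  base <- gpa(lm)
  for (i in c(1L, 3L, 6L)) {
    co <- lm$coords
    co[i, , ] <- random_similarity(co[i, , ])
    alt <- gpa(landmark_set(co, lm$records))
    expect_lt(max(abs(alt$coords - base$coords)), 1e-8)
  }
})

test_that("GPA residual sum of squares is non-increasing over iterations", {
  set.seed(13)
  lm <- make_fish_set(n = 10L, noise = 0.05)
  al <- gpa(lm)
  expect_true(all(diff(al$rss) <= 1e-10))
})

test_that("consensus is unchanged by relabeling specimens", {
  set.seed(14)
  lm <- make_fish_set(n = 5L)
  al1 <- gpa(lm)
  co <- lm$coords[c(2, 1, 3, 4, 5), , ]
  al2 <- gpa(landmark_set(co))
  expect_equal(al2$consensus, al1$consensus, tolerance = 1e-10)
})

test_that("aligned configurations satisfy the preshape invariants", {
  set.seed(15)
  lm <- make_fish_set(n = 6L, noise = 0.03)
  al <- gpa(lm)
  # consensus is the mean of the aligned (projected) configurations
  expect_equal(apply(al$coords, c(2, 3), mean), al$consensus,
               tolerance = 1e-12, ignore_attr = TRUE)
  for (i in 1:6) {
    x <- al$coords[i, , ]
    expect_lt(max(abs(colMeans(x))), 1e-9)
  }
})

test_that("Procrustes distance matches the rotation-grid oracle", {
  expect_lt(procrustes_distance(triangle_a,
                                random_similarity(triangle_a)), 1e-9)
  d_ab <- procrustes_distance(triangle_a, triangle_b)
  expect_equal(d_ab, procrustes_distance(triangle_b, triangle_a),
               tolerance = 1e-9)
  expect_equal(d_ab, grid_procrustes_distance(triangle_a, triangle_b),
               tolerance = 1e-6)
  expect_error(procrustes_distance(triangle_a, matrix(0, 4, 2)),
               "dimension")
})

test_that("allometry regression recovers a planted size vector", {
  cfg <- sim_config(21)
  cfg$landmark_noise_sd <- 0
  cfg$groups <- cfg$groups[1]
  cfg$groups[[1]]$shape_offset <- cfg$groups[[1]]$shape_offset * 0
  cfg$groups[[1]]$n_landmarks <- 40L
  planted <- 0.05 * ecomorph:::allometry_direction()
  cfg$allometry_vector <- planted
  al <- gpa(simulate_landmarks(cfg))
  reg <- regress_shape_on_size(al)
  expect_gt(reg$percent_predicted, 99)
  # rotate the estimated gradient into the template frame before
  # comparing directions (GPA orientation is canonical, not template)
  tpl <- fish_template()
  tpl <- sweep(tpl, 2, colMeans(tpl)); tpl <- tpl / sqrt(sum(tpl^2))
  R <- ecomorph:::optimal_rotation(al$consensus, tpl)
  best <- matrix(reg$coefficients, ncol = 2) %*% R
  cosine <- sum(best * planted) / sqrt(sum(best^2) * sum(planted^2))
  expect_gt(abs(cosine), 0.999)
  # residuals are orthogonal to log size
  x <- reg$log_size - mean(reg$log_size)
  expect_lt(max(abs(crossprod(x, reg$residuals))) / sum(x^2), 1e-9)
})

test_that("size-independent shapes yield near-zero allometry", {
  cfg <- sim_config(22)
  cfg$groups <- cfg$groups[1]
  cfg$groups[[1]]$shape_offset <- cfg$groups[[1]]$shape_offset * 0
  cfg$allometry_vector <- cfg$allometry_vector * 0
  al <- gpa(simulate_landmarks(cfg))
  reg <- regress_shape_on_size(al)
  expect_lt(reg$percent_predicted, 5)
  expect_error(regress_shape_on_size(
    structure(list(coords = al$coords,
                   centroid_sizes = rep(2, length(al$centroid_sizes)),
                   records = al$records),
              class = "aligned_shapes")),
    "constant centroid size")
})

test_that("symmetric component of a symmetric shape is itself", {
  # bilaterally symmetric 6-landmark configuration (pairs across x=0)
  sym <- matrix(c(-1, 0,  1, 0, -0.5, 1, 0.5, 1, 0, 2, 0, -1),
                ncol = 2, byrow = TRUE)
  map <- symmetry_map(paired = rbind(c(1, 2), c(3, 4)),
                      midline = c(5, 6), k = 6)
  lm <- landmark_set(list(sym, sym * 1.3))
  sc <- symmetric_component(lm, map)
  expect_lt(max(sc$asymmetry), 1e-9)
  al <- gpa(lm)
  expect_lt(max(abs(sc$coords - al$coords)), 1e-9)
})

test_that("symmetric component symmetrizes asymmetric pairs", {
  asym <- matrix(c(-1, 0,  1.4, 0.1, -0.5, 1, 0.5, 1, 0, 2, 0, -1),
                 ncol = 2, byrow = TRUE)
  map <- symmetry_map(paired = rbind(c(1, 2), c(3, 4)),
                      midline = c(5, 6), k = 6)
  lm <- landmark_set(list(asym, asym + 0.01))
  sc <- symmetric_component(lm, map)
  for (i in 1:2) {
    y <- sc$coords[i, , ]
    # mirroring + relabeling reproduces the symmetric component
    relab <- c(2, 1, 4, 3, 5, 6)
    mir <- y[relab, ]; mir[, 1] <- -mir[, 1]
    expect_lt(procrustes_distance(y, mir), 1e-9)
  }
  expect_gt(min(sc$asymmetry), 0.01)  # the planted asymmetry is seen
})

test_that("mirror-augmented data give identical symmetric components", {
  set.seed(31)
  base <- matrix(c(-1, 0, 1.2, 0.2, -0.4, 1.1, 0.6, 0.9, 0.05, 2, 0, -1),
                 ncol = 2, byrow = TRUE)
  map <- symmetry_map(paired = rbind(c(1, 2), c(3, 4)),
                      midline = c(5, 6), k = 6)
  lm1 <- landmark_set(list(base, base + matrix(rnorm(12, sd = 0.02), 6)))
  sc1 <- symmetric_component(lm1, map)
  relab <- c(2, 1, 4, 3, 5, 6)
  mirrored <- lapply(1:2, function(i) {
    m <- lm1$coords[i, relab, ]; m[, 1] <- -m[, 1]; m
  })
  lm2 <- landmark_set(c(lapply(1:2, function(i) lm1$coords[i, , ]),
                        mirrored))
  sc2 <- symmetric_component(lm2, map)
  for (i in 1:2)
    expect_lt(procrustes_distance(sc1$coords[i, , ], sc2$coords[i, , ]),
              1e-7)
})

test_that("landmark pruning does the LPJ-style bookkeeping", {
  set.seed(41)
  k <- 28L
  roles <- rep(c("true", "semi"), c(6L, 22L))
  configs <- lapply(1:3, function(i)
    matrix(rnorm(2 * k), k, 2))
  lm <- landmark_set(configs, roles = roles)
  kept <- prune_landmarks(lm, c(1:6, 7, 9, 11, 13, 15, 17))
  expect_equal(dim(kept$coords)[2], 12L)
  expect_equal(sum(kept$roles == "true"), 6L)
  expect_equal(prune_landmarks(lm, 1:28)$coords, lm$coords)
  expect_error(prune_landmarks(lm, c(1, 99)), "out of range")
  expect_error(prune_landmarks(lm, c(1, 1)), "duplicate")
})
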