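## Ordination: PCA on covariance, canonical variate analysis.

#' Principal component analysis (covariance based)
#'
#' Eigendecomposition of the covariance of the column-centred input.
#' Axes are orthonormal with a deterministic sign convention (the
#' largest-magnitude loading of each axis is positive); eigenvalues are
#' non-negative, descending, and sum to the total column variance.
#'
#' @param x numeric matrix, observations in rows.  Missing values are
#'   an error.
#' @return object of class `ordination`: `scores` (n x m), `axes`
#'   (p x m orthonormal loadings), `eigenvalues`, `center`.
#' @export
pca <- function(x) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("missing values are not allowed in PCA input")
  if (nrow(x) < 2L) stop("need at least 2 observations")
  ctr <- colMeans(x)
  xc <- sweep(x, 2L, ctr)
  S <- crossprod(xc) / (nrow(x) - 1L)
  e <- eigen(S, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  axes <- e$vectors
  for (j in seq_len(ncol(axes))) {
    i <- which.max(abs(axes[, j]))
    if (axes[i, j] < 0) axes[, j] <- -axes[, j]
  }
  scores <- xc %*% axes
  colnames(scores) <- colnames(axes) <- paste0("PC", seq_len(ncol(axes)))
  rownames(scores) <- rownames(x)
  rownames(axes) <- colnames(x)
  structure(list(scores = scores, axes = axes, eigenvalues = ev,
                 center = ctr),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  pct <- 100 * x$eigenvalues / sum(x$eigenvalues)
  cat("Ordination:", nrow(x$scores), "observations,",
      ncol(x$scores), "axes; first axes explain",
      paste(sprintf("%.1f%%", utils::head(pct, 3L)), collapse = ", "), "\n")
  invisible(x)
}

#' Canonical variate analysis with permutation tests
#'
#' The input is first reduced to its informative PCA subspace
#' (eigenvalues above `rank_tol` times the largest — Procrustes shape
#' data are rank deficient), then canonical axes are extracted from the
#' two-matrix eigenproblem of between-group vs pooled within-group
#' covariance.  Pairwise group separation is reported both as
#' Mahalanobis distance (within-covariance metric) and as Euclidean
#' distance between group means in the input space, each with a
#' permutation p-value obtained by reshuffling group labels, and
#' Bonferroni-adjusted across pairs.
#'
#' @param x numeric matrix, observations in rows.
#' @param groups group labels, length `nrow(x)`; every group needs at
#'   least 2 members.
#' @param n_perm number of label permutations.
#' @param rank_tol relative eigenvalue threshold for the PCA reduction.
#' @return list with `ordination` (canonical scores/axes in the reduced
#'   space, eigenvalues), `mahalanobis` and `euclidean` pairwise
#'   distance matrices, and `pairwise` — a data frame of pairwise
#'   statistics with raw and Bonferroni-adjusted permutation p-values.
#' @export
cva <- function(x, groups, n_perm = 999L, rank_tol = 1e-12) {
  x <- as.matrix(x)
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(table(groups) < 2L)) stop("every group needs at least 2 members")
  p <- pca(x)
  keep <- p$eigenvalues > rank_tol * p$eigenvalues[1L]
  z <- p$scores[, keep, drop = FALSE]
  n <- nrow(z); g <- nlevels(groups)
  means <- rowsum(z, groups) / as.vector(table(groups))
  grand <- colMeans(z)
  W <- matrix(0, ncol(z), ncol(z))
  for (lv in levels(groups)) {
    zi <- z[groups == lv, , drop = FALSE]
    W <- W + crossprod(sweep(zi, 2L, colMeans(zi)))
  }
  W <- W / (n - g)
  B <- crossprod(sweep(means, 2L, grand) * sqrt(as.vector(table(groups)))) /
    (g - 1L)
  eW <- eigen(W, symmetric = TRUE)
  if (any(eW$values <= 1e-12 * eW$values[1L]))
    stop("pooled within-group covariance is singular")
  Wmh <- eW$vectors %*% diag(1 / sqrt(eW$values), ncol(z)) %*% t(eW$vectors)
  eB <- eigen(Wmh %*% B %*% Wmh, symmetric = TRUE)
  n_axes <- min(g - 1L, ncol(z))
  axes <- Wmh %*% eB$vectors[, seq_len(n_axes), drop = FALSE]
  scores <- sweep(z, 2L, grand) %*% axes
  colnames(scores) <- paste0("CV", seq_len(n_axes))
  Winv <- Wmh %*% Wmh
  pair_dists <- function(zz, grp) {
    mm <- rowsum(zz, grp) / as.vector(table(grp))
    lv <- rownames(mm)
    np <- length(lv)
    mah <- euc <- matrix(0, np, np, dimnames = list(lv, lv))
    for (i in seq_len(np - 1L)) for (j in (i + 1L):np) {
      d <- mm[i, ] - mm[j, ]
      mah[i, j] <- mah[j, i] <- sqrt(drop(t(d) %*% Winv %*% d))
      euc[i, j] <- euc[j, i] <- sqrt(sum(d^2))
    }
    list(mah = mah, euc = euc)
  }
  obs <- pair_dists(z, groups)
  lv <- levels(groups)
  pairs <- utils::combn(lv, 2L)
  n_pairs <- ncol(pairs)
  exceed_mah <- exceed_euc <- numeric(n_pairs)
  for (b in seq_len(n_perm)) {
    pd <- pair_dists(z, sample(groups))
    for (q in seq_len(n_pairs)) {
      i <- pairs[1L, q]; j <- pairs[2L, q]
      exceed_mah[q] <- exceed_mah[q] + (pd$mah[i, j] >= obs$mah[i, j])
      exceed_euc[q] <- exceed_euc[q] + (pd$euc[i, j] >= obs$euc[i, j])
    }
  }
  p_mah <- (exceed_mah + 1) / (n_perm + 1)
  p_euc <- (exceed_euc + 1) / (n_perm + 1)
  pairwise <- data.frame(
    group1 = pairs[1L, ], group2 = pairs[2L, ],
    mahalanobis = obs$mah[t(pairs)],
    euclidean = obs$euc[t(pairs)],
    p_mahalanobis = p_mah,
    p_euclidean = p_euc,
    p_mahalanobis_adj = pmin(1, p_mah * n_pairs),
    p_euclidean_adj = pmin(1, p_euc * n_pairs),
    stringsAsFactors = FALSE)
  list(ordination = structure(list(scores = scores, axes = axes,
                                   eigenvalues = pmax(eB$values[seq_len(n_axes)], 0),
                                   center = grand),
                              class = "ordination"),
       mahalanobis = obs$mah,
       euclidean = obs$euc,
       pairwise = pairwise,
       n_permutations = n_perm)
}
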