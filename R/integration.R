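## Cross-dataset statistics: two-block PLS, Mantel tests, distance
## scaling, SNP thinning, genotype PCA, Hudson's F_ST.

#' Two-block partial least squares
#'
#' Singular value decomposition of the cross-covariance between two
#' column-centred blocks measured on the same specimens.  Axis scores
#' are the block projections on the paired singular vectors; the
#' strength of covariation per axis is the correlation of the paired
#' scores, tested by permuting the specimen rows of the second block.
#'
#' @param x,y numeric matrices with the same rows (specimens); if both
#'   have rownames they must match.
#' @param n_perm number of row permutations.
#' @return object of class `pls_result`: `singular_values`,
#'   `x_scores`, `y_scores`, `x_loadings`, `y_loadings`,
#'   `score_correlations`, `permutation_p` (per axis, testing the
#'   score correlation), `n_permutations`.
#' @export
two_block_pls <- function(x, y, n_perm = 999L) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (nrow(x) != nrow(y)) stop("blocks must share specimens (rows)")
  if (!is.null(rownames(x)) && !is.null(rownames(y)) &&
      !identical(rownames(x), rownames(y)))
    stop("row names of the two blocks do not match")
  n <- nrow(x)
  if (n < 4L) stop("need at least 4 specimens")
  xc <- sweep(x, 2L, colMeans(x))
  yc <- sweep(y, 2L, colMeans(y))
  sv <- svd(crossprod(xc, yc) / (n - 1L))
  n_axes <- sum(sv$d > 1e-12 * max(sv$d, 1e-300))
  n_axes <- max(1L, n_axes)
  u <- sv$u[, seq_len(n_axes), drop = FALSE]
  v <- sv$v[, seq_len(n_axes), drop = FALSE]
  xs <- xc %*% u; ys <- yc %*% v
  rho <- vapply(seq_len(n_axes), function(j)
    stats::cor(xs[, j], ys[, j]), numeric(1L))
  exceed <- numeric(n_axes)
  for (b in seq_len(n_perm)) {
    yp <- yc[sample(n), , drop = FALSE]
    svp <- svd(crossprod(xc, yp) / (n - 1L))
    for (j in seq_len(n_axes)) {
      rp <- abs(stats::cor(xc %*% svp$u[, j], yp %*% svp$v[, j]))
      exceed[j] <- exceed[j] + (rp >= abs(rho[j]))
    }
  }
  structure(list(singular_values = sv$d[seq_len(n_axes)],
                 x_scores = xs, y_scores = ys,
                 x_loadings = u, y_loadings = v,
                 score_correlations = rho,
                 permutation_p = (exceed + 1) / (n_perm + 1),
                 n_permutations = n_perm),
            class = "pls_result")
}

#' @export
print.pls_result <- function(x, ...) {
  cat("Two-block PLS:", length(x$singular_values), "axes; first-axis",
      sprintf("score correlation %.4f (p = %.4g)\n",
              x$score_correlations[1L], x$permutation_p[1L]))
  invisible(x)
}

#' Simple Mantel test
#'
#' Pearson correlation of the lower-triangle vectors of two labeled
#' distance matrices, with significance from simultaneous row/column
#' permutation of the first matrix.  One-tailed for positive
#' association by default.
#'
#' @param a,b [dist_matrix()] objects (or symmetric matrices) over the
#'   same labels.
#' @param n_perm number of permutations (study default 10000).
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return list with `r`, `p_value`, `n_permutations`.
#' @export
mantel_test <- function(a, b, n_perm = 10000L,
                        alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  a <- dist_matrix(as.matrix(a)); b <- dist_matrix(as.matrix(b))
  if (nrow(a) != nrow(b)) stop("matrices differ in size")
  if (!is.null(rownames(a)) && !is.null(rownames(b)) &&
      !setequal(rownames(a), rownames(b)))
    stop("matrix labels do not match")
  if (!is.null(rownames(b))) b <- b[rownames(a), rownames(a)]
  n <- nrow(a)
  if (n < 4L) stop("need at least 4 objects")
  va <- lower_vec(a); vb <- lower_vec(b)
  if (stats::sd(va) == 0 || stats::sd(vb) == 0)
    stop("constant distance matrix: Mantel r undefined")
  r_obs <- stats::cor(va, vb)
  stat <- function(r) if (alternative == "greater") r else abs(r)
  exceed <- 0L
  for (k in seq_len(n_perm)) {
    idx <- sample(n)
    rp <- stats::cor(lower_vec(a[idx, idx]), vb)
    exceed <- exceed + (stat(rp) >= stat(r_obs))
  }
  list(r = r_obs, p_value = (exceed + 1) / (n_perm + 1),
       n_permutations = n_perm, alternative = alternative)
}

#' Partial Mantel test
#'
#' Association between two distance matrices controlling for a third
#' (residual method): the lower-triangle vectors of `a` and `b` are
#' each residualized on that of `c` by OLS, the partial r is the
#' Pearson correlation of the residual vectors, and significance comes
#' from row/column permutation of `a`'s residualized matrix.
#'
#' @param a,b,c [dist_matrix()] objects over the same labels; `c` is
#'   the matrix controlled for.
#' @param n_perm number of permutations.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return list with `r`, `p_value`, `n_permutations`.
#' @export
partial_mantel <- function(a, b, c, n_perm = 10000L,
                           alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  a <- dist_matrix(as.matrix(a)); b <- dist_matrix(as.matrix(b))
  c <- dist_matrix(as.matrix(c))
  n <- nrow(a)
  if (nrow(b) != n || nrow(c) != n) stop("matrices differ in size")
  if (!setequal(rownames(a), rownames(b)) ||
      !setequal(rownames(a), rownames(c)))
    stop("matrix labels do not match")
  b <- b[rownames(a), rownames(a)]
  c <- c[rownames(a), rownames(a)]
  vc <- lower_vec(c)
  if (stats::sd(vc) == 0) stop("constant control matrix")
  residualize <- function(v) stats::resid(stats::lm(v ~ vc))
  ra_full <- matrix(0, n, n)
  ra_full[lower.tri(ra_full)] <- residualize(lower_vec(a))
  ra_full <- ra_full + t(ra_full)
  rb <- residualize(lower_vec(b))
  if (stats::sd(lower_vec(ra_full)) < 1e-12 || stats::sd(rb) < 1e-12)
    stop("control matrix is collinear with a tested matrix")
  r_obs <- stats::cor(lower_vec(ra_full), rb)
  stat <- function(r) if (alternative == "greater") r else abs(r)
  exceed <- 0L
  for (k in seq_len(n_perm)) {
    idx <- sample(n)
    rp <- stats::cor(lower_vec(ra_full[idx, idx]), rb)
    exceed <- exceed + (stat(rp) >= stat(r_obs))
  }
  list(r = r_obs, p_value = (exceed + 1) / (n_perm + 1),
       n_permutations = n_perm, alternative = alternative)
}

#' Scale a distance matrix to unit maximum
#'
#' Divides every entry by the largest off-diagonal value, so the
#' maximum pairwise distance becomes exactly 1 (the convention for
#' comparing morphological against genomic distances on one plot).
#' Idempotent.
#'
#' @param m a [dist_matrix()] (or symmetric matrix).
#' @return the rescaled `dist_matrix`.
#' @export
scale_to_unit <- function(m) {
  m <- dist_matrix(as.matrix(m))
  mx <- max(m[lower.tri(m)])
  if (mx <= 0) stop("zero distance matrix cannot be scaled")
  dist_matrix(m / mx, rownames(m))
}

#' Thin SNPs by physical spacing (and completeness)
#'
#' Optionally drops every locus with any missing genotype, then walks
#' each chromosome left to right keeping a locus only when it lies at
#' least `min_spacing` bp from the last kept locus (deterministic
#' greedy thinning); kept/dropped counts are reported.
#'
#' @param g a [genotype_data()] object (positions sorted within
#'   chromosome by construction).
#' @param min_spacing minimum distance between kept loci in bp
#'   (default 500 kb).
#' @param require_complete drop loci with missing data first?
#' @return the thinned `genotype_data` (possibly with zero loci).
#' @export
filter_snps <- function(g, min_spacing = 500000L, require_complete = TRUE) {
  stopifnot(inherits(g, "genotype_data"))
  keep <- rep(TRUE, nrow(g$loci))
  if (require_complete) keep <- colSums(is.na(g$genotypes)) == 0L
  n_missing_drop <- sum(!keep)
  kept_idx <- integer(0)
  for (ch in unique(g$loci$chrom)) {
    idx <- which(keep & g$loci$chrom == ch)
    last <- -Inf
    for (i in idx) {
      if (g$loci$pos[i] - last >= min_spacing) {
        kept_idx <- c(kept_idx, i)
        last <- g$loci$pos[i]
      }
    }
  }
  kept_idx <- sort(kept_idx)
  message("SNP thinning: ", nrow(g$loci), " loci in, ",
          n_missing_drop, " dropped for missing data, ",
          length(kept_idx), " kept at >= ", min_spacing, " bp spacing")
  out <- g
  out$loci <- g$loci[kept_idx, , drop = FALSE]
  rownames(out$loci) <- NULL
  out$genotypes <- g$genotypes[, kept_idx, drop = FALSE]
  out
}

#' PCA of a genotype dosage matrix
#'
#' Column-centres the alternate-allele dosage matrix (no column
#' scaling by default, matching the common visualization convention)
#' and runs the covariance PCA of [pca()].
#'
#' @param g a complete (post-filter) [genotype_data()] object.
#' @param scale divide columns by their standard deviation?
#' @return an `ordination`.
#' @export
genotype_pca <- function(g, scale = FALSE) {
  stopifnot(inherits(g, "genotype_data"))
  m <- g$genotypes
  if (anyNA(m)) stop("missing genotypes: filter first")
  storage.mode(m) <- "double"
  sds <- apply(m, 2L, stats::sd)
  if (all(sds == 0)) stop("all loci are monomorphic")
  if (scale) {
    m <- m[, sds > 0, drop = FALSE]
    m <- sweep(m, 2L, apply(m, 2L, stats::sd), `/`)
  }
  pca(m)
}

#' Pairwise F_ST between populations (Hudson estimator)
#'
#' Hudson-type per-locus estimator combined across loci as a ratio of
#' averages (robust to rare alleles and unequal sample sizes), for
#' every pair of populations.  The estimator is invariant to swapping
#' allele labels.  Raw values can be slightly negative under no
#' differentiation; for use as a distance they are floored at zero
#' (the raw matrix is attached as an attribute).
#'
#' @param g a [genotype_data()] object (diploid dosages).
#' @param populations population labels, one per sample.
#' @return a [dist_matrix()] of floored F_ST values with attribute
#'   `raw` (unfloored matrix).
#' @export
pairwise_fst <- function(g, populations) {
  stopifnot(inherits(g, "genotype_data"))
  populations <- factor(populations)
  if (length(populations) != length(g$samples))
    stop("one population label per sample required")
  if (nlevels(populations) < 2L) stop("need >= 2 populations")
  if (any(table(populations) < 2L))
    stop("every population needs >= 2 samples")
  lv <- levels(populations)
  np <- length(lv)
  raw <- matrix(0, np, np, dimnames = list(lv, lv))
  for (i in seq_len(np - 1L)) for (j in (i + 1L):np) {
    gi <- g$genotypes[populations == lv[i], , drop = FALSE]
    gj <- g$genotypes[populations == lv[j], , drop = FALSE]
    ni <- 2 * colSums(!is.na(gi)); nj <- 2 * colSums(!is.na(gj))
    if (any(ni == 0) || any(nj == 0))
      stop("population ", lv[i], " or ", lv[j],
           " has a locus with all genotypes missing")
    p1 <- colSums(gi, na.rm = TRUE) / ni
    p2 <- colSums(gj, na.rm = TRUE) / nj
    usable <- ni > 2 & nj > 2
    num <- (p1 - p2)^2 - p1 * (1 - p1) / (ni - 1) - p2 * (1 - p2) / (nj - 1)
    den <- p1 * (1 - p2) + p2 * (1 - p1)
    keep <- usable & den > 0
    if (!any(keep)) stop("no usable polymorphic loci between ",
                         lv[i], " and ", lv[j])
    raw[i, j] <- raw[j, i] <- sum(num[keep]) / sum(den[keep])
  }
  out <- dist_matrix(pmax(raw, 0), lv)
  attr(out, "raw") <- raw
  out
}

#' Great-circle distance matrix from coordinates
#'
#' Helper for building the geographic control matrix of the partial
#' Mantel stage, using the spherical law of cosines (via the geosphere
#' package).
#'
#' @param lon,lat coordinates in decimal degrees.
#' @param labels site labels.
#' @return a [dist_matrix()] in kilometres.
#' @export
geographic_distance_matrix <- function(lon, lat, labels = NULL) {
  if (!requireNamespace("geosphere", quietly = TRUE))
    stop("geographic distances require the geosphere package")
  pts <- cbind(lon, lat)
  n <- nrow(pts)
  m <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    m[i, j] <- m[j, i] <- geosphere::distCosine(pts[i, ], pts[j, ]) / 1000
  dist_matrix(m, labels %||% paste0("site", seq_len(n)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
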