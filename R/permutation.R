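## Distance-based and classical univariate inference.

#' Labeled distance matrix constructor
#'
#' Validates symmetry (to 1e-12), a zero diagonal, and nonnegativity,
#' and forces exact symmetry and zero diagonal.
#'
#' @param values square numeric matrix.
#' @param labels optional row/column labels (defaults to dimnames).
#' @return matrix of class `dist_matrix`.
#' @export
dist_matrix <- function(values, labels = rownames(values)) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("distance matrix must be square")
  if (max(abs(values - t(values))) > 1e-12)
    stop("distance matrix is not symmetric")
  if (max(abs(diag(values))) > 1e-12)
    stop("distance matrix diagonal must be zero")
  if (any(values < 0)) stop("distances must be nonnegative")
  values <- (values + t(values)) / 2
  diag(values) <- 0
  if (is.null(labels)) labels <- paste0("obj", seq_len(nrow(values)))
  dimnames(values) <- list(labels, labels)
  class(values) <- c("dist_matrix", "matrix")
  values
}

lower_vec <- function(m) m[lower.tri(m)]

## pseudo-F from a squared-distance matrix and integer group codes
pseudo_f <- function(d2, codes, g, n) {
  ss_tot <- sum(d2[lower.tri(d2)]) / n
  ss_within <- 0
  for (lv in seq_len(g)) {
    sel <- codes == lv
    ng <- sum(sel)
    if (ng > 1L)
      ss_within <- ss_within + sum(d2[sel, sel][lower.tri(d2[sel, sel])]) / ng
  }
  ss_between <- ss_tot - ss_within
  if (ss_within <= 0) return(Inf)
  (ss_between / (g - 1L)) / (ss_within / (n - g))
}

#' Nonparametric (permutational) MANOVA on a distance matrix
#'
#' Anderson's pseudo-F computed from sums of squared pairwise
#' distances (total minus within-group), with a p-value from group
#' label permutation using the +1 correction, so p is never zero.
#' Degenerate perfect separation (zero within-group distances) reports
#' `statistic = Inf`.  Pairwise comparisons rerun the test on each pair
#' of groups with plain Bonferroni adjustment (multiplication by the
#' number of pairs).
#'
#' @param d a [dist_matrix()] (or symmetric matrix / `dist`).
#' @param groups labels matching the rows of `d`; every group >= 2.
#' @param n_perm number of permutations (study default 10000).
#' @param pairwise also compute the pairwise table?
#' @return list: `statistic`, `p_value`, `n_permutations`, df, SS
#'   decomposition, and optionally `pairwise` (data frame with F, raw
#'   and Bonferroni-adjusted p per group pair).
#' @export
npmanova <- function(d, groups, n_perm = 10000L, pairwise = TRUE) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  d <- dist_matrix(unclass(d), rownames(d))
  groups <- factor(groups)
  n <- nrow(d)
  if (length(groups) != n) stop("groups length does not match distance matrix")
  if (any(table(groups) < 2L)) stop("every group needs at least 2 members")
  g <- nlevels(groups)
  d2 <- d^2
  codes <- as.integer(groups)
  f_obs <- pseudo_f(d2, codes, g, n)
  exceed <- 0L
  # perfect separation (F infinite) is maximally significant: no
  # permutation is counted as reaching it, so p = 1 / (n_perm + 1)
  for (b in seq_len(n_perm)) {
    fp <- pseudo_f(d2, sample(codes), g, n)
    exceed <- exceed +
      (if (is.infinite(f_obs)) fp > f_obs else fp >= f_obs)
  }
  out <- list(statistic = f_obs,
              p_value = (exceed + 1) / (n_perm + 1),
              n_permutations = n_perm,
              df = c(between = g - 1L, within = n - g))
  if (pairwise && g > 2L) {
    pairs <- utils::combn(levels(groups), 2L)
    rows <- lapply(seq_len(ncol(pairs)), function(q) {
      sel <- groups %in% pairs[, q]
      sub <- npmanova(d[sel, sel], droplevels(groups[sel]),
                      n_perm = n_perm, pairwise = FALSE)
      data.frame(group1 = pairs[1L, q], group2 = pairs[2L, q],
                 F = sub$statistic, p = sub$p_value,
                 stringsAsFactors = FALSE)
    })
    pw <- do.call(rbind, rows)
    pw$p_adj <- pmin(1, pw$p * nrow(pw))
    out$pairwise <- pw
  }
  out
}

#' One-way ANOVA
#'
#' Classical fixed-effects one-way analysis of variance (F statistic
#' with its F-distribution p-value) via [stats::lm()].
#'
#' @param values numeric response.
#' @param groups group labels; at least two groups with >= 2 values.
#' @return list: `statistic`, `p_value`, `df`, group means.
#' @export
anova_oneway <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(table(groups) < 2L)) stop("every group needs >= 2 values")
  means <- tapply(values, groups, mean)
  within_var <- tapply(values, groups, stats::var)
  if (all(within_var == 0) && length(unique(means)) == 1L)
    stop("zero within-group variance with equal means: F undefined")
  tab <- stats::anova(stats::lm(values ~ groups))
  list(statistic = tab$`F value`[1L],
       p_value = tab$`Pr(>F)`[1L],
       df = c(between = tab$Df[1L], within = tab$Df[2L]),
       means = means)
}

#' Holm step-down (sequential Bonferroni) adjustment
#'
#' Delegates to [stats::p.adjust()] with `method = "holm"`; adjusted
#' p-values are monotone and each is at least the raw value.
#'
#' @param p numeric vector of raw p-values.
#' @return adjusted p-values in the input order.
#' @export
holm_adjust <- function(p) stats::p.adjust(p, method = "holm")

#' Pearson product-moment correlation with t-based p-value
#'
#' @param x,y numeric vectors, length >= 3, non-constant.
#' @return list with `r` and `p_value`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value)
}
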