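## Diet composition and discrete trophic trait statistics.

#' Canonical stomach-content categories
#'
#' Six percent-by-volume categories used for stomach composition
#' tables.
#' @export
diet_categories <- c("algae_cyanobacteria", "cellulose_plant",
                     "small_arthropods", "fry_eggs",
                     "fish_remains_scales", "grit_sand")

#' Validate and normalize a diet composition table
#'
#' Each row holds the six category percentages for one specimen.
#' Values must lie in [0, 100]; row sums within [95, 105] are accepted
#' and renormalized to exactly 100, anything further off is an error.
#'
#' @param table data frame with `specimen_id`, `species`, `site` and
#'   the six [diet_categories] columns.
#' @return the table with category columns renormalized to sum to 100.
#' @export
diet_records <- function(table) {
  stopifnot(is.data.frame(table),
            all(diet_categories %in% names(table)))
  m <- as.matrix(table[, diet_categories])
  if (any(m < 0 | m > 100)) stop("category percentages must be in [0, 100]")
  s <- rowSums(m)
  bad <- which(s < 95 | s > 105)
  if (length(bad))
    stop("composition rows sum outside [95, 105]: rows ",
         paste(bad, collapse = ", "))
  table[, diet_categories] <- m * (100 / s)
  table
}

#' Schoener's index of dietary overlap
#'
#' `D = 1 - 0.5 * sum(|p_i - q_i|) / 100` on two percentage
#' compositions over the same categories; `D` is symmetric, lies in
#' [0, 1], equals 1 for identical compositions, and values above 0.6
#' are conventionally considered substantial biological overlap.
#'
#' @param p,q named percentage compositions summing to 100 (after
#'   normalization).
#' @param threshold substantiality threshold (default 0.6).
#' @return list with `D` and logical `substantial`.
#' @export
schoener_overlap <- function(p, q, threshold = 0.6) {
  if (!is.null(names(p)) && !is.null(names(q))) {
    if (!setequal(names(p), names(q)))
      stop("category sets differ between the two compositions")
    q <- q[names(p)]
  } else if (length(p) != length(q)) {
    stop("compositions differ in length")
  }
  for (v in list(p, q))
    if (abs(sum(v) - 100) > 1e-6)
      stop("compositions must sum to 100 (normalize first)")
  D <- 1 - 0.5 * sum(abs(p - q)) / 100
  list(D = D, substantial = D > threshold)
}

#' Mean stomach composition per group
#'
#' Arithmetic mean of the category percentages per group; each group
#' mean again sums to 100 (mass conservation).
#'
#' @param table a normalized [diet_records()] table.
#' @param by grouping column name (default `"species"`).
#' @return data frame of group, n, and mean category percentages.
#' @export
composition_summary <- function(table, by = "species") {
  stopifnot(by %in% names(table))
  g <- factor(table[[by]])
  m <- rowsum(as.matrix(table[, diet_categories]), g) /
    as.vector(table(g))
  data.frame(group = rownames(m), n = as.vector(table(g)), m,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Pairwise Schoener overlap between group mean compositions
#'
#' @param table a normalized [diet_records()] table.
#' @param by grouping column name.
#' @return symmetric matrix of Schoener's D between group means
#'   (diagonal 1).
#' @export
schoener_matrix <- function(table, by = "species") {
  cs <- composition_summary(table, by)
  m <- as.matrix(cs[, diet_categories])
  rownames(m) <- cs$group
  ng <- nrow(m)
  out <- diag(1, ng)
  dimnames(out) <- list(cs$group, cs$group)
  for (i in seq_len(ng)) for (j in seq_len(ng))
    if (i != j) out[i, j] <- schoener_overlap(m[i, ], m[j, ])$D
  out
}

#' Relative gut length
#'
#' `log10(gut length) / log10(standard length)`, the dimensionless gut
#' length measure that removes the allometric length-length relation.
#'
#' @param gut_length,standard_length positive lengths (mm).
#' @return numeric vector of relative gut lengths.
#' @export
relative_gut_length <- function(gut_length, standard_length) {
  if (any(gut_length <= 0) || any(standard_length <= 0))
    stop("lengths must be positive")
  log10(gut_length) / log10(standard_length)
}

#' Group tests of relative gut length
#'
#' Overall one-way ANOVA of relative gut length across groups plus all
#' pairwise ANOVAs with Holm (sequential Bonferroni) adjustment.
#' Juveniles are expected to be excluded upstream by the caller's
#' adult filter.
#'
#' @param table data frame with `gut_length`, `standard_length`, and
#'   the grouping column; missing lengths are an error.
#' @param by grouping column name (default `"species"`).
#' @return list: `overall` ([anova_oneway()] result), `pairwise` data
#'   frame with F, raw and Holm-adjusted p.
#' @export
relative_gut_length_tests <- function(table, by = "species") {
  stopifnot(all(c("gut_length", "standard_length", by) %in% names(table)))
  if (anyNA(table$gut_length) || anyNA(table$standard_length))
    stop("missing gut or standard lengths")
  rgl <- relative_gut_length(table$gut_length, table$standard_length)
  g <- factor(table[[by]])
  if (any(table(g) < 3L)) stop("every group needs >= 3 individuals")
  overall <- anova_oneway(rgl, g)
  pairs <- utils::combn(levels(g), 2L)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(q) {
    sel <- g %in% pairs[, q]
    a <- anova_oneway(rgl[sel], droplevels(g[sel]))
    data.frame(group1 = pairs[1L, q], group2 = pairs[2L, q],
               F = a$statistic, p = a$p_value, stringsAsFactors = FALSE)
  }))
  pw$p_adj <- holm_adjust(pw$p)
  list(overall = overall, pairwise = pw, rgl = rgl)
}

#' Compare mean-function models for gut length vs body length
#'
#' Least-squares fits of gut length on standard length per species
#' under four mean functions — linear, exponential, logarithmic, and
#' quadratic (the lowest-order polynomial beyond linear) — all with
#' Gaussian error on the raw gut-length scale so their small-sample
#' AIC (AICc) values are comparable; models are ranked by AICc per
#' species.  Model ranking is invariant to rescaling the length units.
#'
#' @param table data frame with `gut_length`, `standard_length`, and
#'   `species`; at least 6 records per species.
#' @return data frame: species, model, AICc, residual SS, rank; the
#'   rank-1 row per species is the winning model.
#' @export
gut_model_comparison <- function(table) {
  stopifnot(all(c("gut_length", "standard_length", "species") %in%
                  names(table)))
  if (any(table$gut_length <= 0) || any(table$standard_length <= 0))
    stop("lengths must be positive")
  aicc <- function(rss, n, k) {
    # gaussian log-likelihood profile; k = mean-function params + sigma
    n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
  }
  fit_one <- function(sub) {
    y <- sub$gut_length; x <- sub$standard_length
    n <- length(y)
    fits <- list(
      linear = stats::lm(y ~ x),
      logarithmic = stats::lm(y ~ log(x)),
      quadratic = stats::lm(y ~ x + I(x^2)))
    rss <- vapply(fits, function(f) sum(stats::resid(f)^2), numeric(1L))
    npar <- c(linear = 3, logarithmic = 3, quadratic = 4)
    # exponential y = b0 * exp(b1 * x), Gaussian error on y
    lf <- stats::lm(log(y) ~ x)
    exp_fit <- tryCatch(
      stats::nls(y ~ b0 * exp(b1 * x),
                 start = list(b0 = exp(stats::coef(lf)[1L]),
                              b1 = stats::coef(lf)[2L]),
                 control = stats::nls.control(warnOnly = TRUE)),
      error = function(e) NULL)
    if (!is.null(exp_fit)) {
      rss <- c(rss, exponential = sum(stats::resid(exp_fit)^2))
      npar <- c(npar, exponential = 3)
    }
    data.frame(model = names(rss), rss = unname(rss),
               AICc = aicc(unname(rss), n, npar[names(rss)]),
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(split(table, table$species), function(sub) {
    if (nrow(sub) < 6L)
      stop("species ", sub$species[1L], ": need >= 6 records")
    res <- fit_one(sub)
    res$species <- sub$species[1L]
    res$rank <- rank(res$AICc, ties.method = "first")
    res[order(res$rank), c("species", "model", "AICc", "rss", "rank")]
  }))
  rownames(out) <- NULL
  out
}

#' Gill-raker count tests
#'
#' Pearson correlation of raker count against standard length (does
#' count covary with body size?) and a one-way ANOVA of counts across
#' species.
#'
#' @param counts positive integer raker counts.
#' @param standard_lengths specimen standard lengths (mm).
#' @param groups species labels.
#' @return list: `size_correlation` ([pearson()] result), `anova`
#'   ([anova_oneway()] result).
#' @export
raker_tests <- function(counts, standard_lengths, groups) {
  if (any(counts <= 0) || any(counts != round(counts)))
    stop("counts must be positive integers")
  if (length(counts) < 3L) stop("need at least 3 observations")
  list(size_correlation = pearson(counts, standard_lengths),
       anova = anova_oneway(counts, groups))
}
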