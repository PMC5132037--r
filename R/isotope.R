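## Stable-isotope processing: delta notation, C:N-based lipid
## normalization, preservation checks, niche metrics.

#' Delta notation for an isotope ratio
#'
#' `delta = (R_sample / R_standard - 1) * 1000`, in per mille, with
#' `R` the heavy/light isotope ratio (13C/12C or 15N/14N).
#'
#' @param r_sample,r_standard positive isotope ratios.
#' @return delta value in per mille.
#' @export
delta_value <- function(r_sample, r_standard) {
  if (any(r_sample <= 0) || any(r_standard <= 0))
    stop("isotope ratios must be positive")
  (r_sample / r_standard - 1) * 1000
}

#' Lipid-normalization model parameters
#'
#' Parameters of the two-equation arithmetic lipid correction that
#' maps a tissue C:N ratio (by weight) to a corrected delta-13C.
#' Equation A estimates lipid percentage,
#' `L = a / (1 + 1 / (b * CN - c))`; equation B shifts the measured
#' value, `d13C' = d13C + D * (I + k1 / (1 + k2 / L))`, where `D` is
#' the protein-lipid discrimination in per mille.  Defaults are the
#' published estimates of the fish-muscle normalization model this
#' correction follows; they are configuration, not constants.
#'
#' @param D protein-lipid discrimination (per mille), >= 0; `D = 0`
#'   makes the correction the identity.
#' @param I dimensionless intercept of the correction kernel.
#' @param a,b,c coefficients of the C:N -> lipid%% curve.
#' @param k1,k2 reference constants of the correction kernel.
#' @return list of class `lipid_params`.
#' @export
lipid_params <- function(D = 7.018, I = 0.048, a = 93, b = 0.246,
                         c = 0.775, k1 = 3.90, k2 = 287) {
  if (D < 0) stop("D must be >= 0")
  structure(list(D = D, I = I, a = a, b = b, c = c, k1 = k1, k2 = k2),
            class = "lipid_params")
}

#' C:N-based lipid correction of delta-13C
#'
#' Applies the arithmetic lipid normalization of [lipid_params()] to
#' an isotope table, adding a `d13C_corrected` column (the raw value
#' is retained).  The estimated lipid percentage is clamped to
#' [0, 100] with a warning when the C:N ratio falls outside the
#' calibrated range; a C:N ratio at the pole of the lipid curve
#' (`b * CN == c`) is an error.
#'
#' @param table data frame with columns `d13C` and `cn_ratio`
#'   (`cn_ratio > 0`).
#' @param params a [lipid_params()] object.
#' @return `table` with `d13C_corrected` (and `lipid_percent`) added.
#' @export
lipid_correct <- function(table, params = lipid_params()) {
  stopifnot(is.data.frame(table),
            all(c("d13C", "cn_ratio") %in% names(table)))
  if (any(table$cn_ratio <= 0)) stop("cn_ratio must be positive")
  denom <- params$b * table$cn_ratio - params$c
  if (any(abs(denom) < 1e-12))
    stop("C:N ratio at the pole of the lipid curve (b*CN == c)")
  L <- params$a / (1 + 1 / denom)
  if (any(L < 0 | L > 100)) {
    warning("estimated lipid percentage outside [0, 100]; clamped")
    L <- pmin(pmax(L, 0), 100)
  }
  shift <- ifelse(L > 0,
                  params$D * (params$I + params$k1 / (1 + params$k2 / L)),
                  params$D * params$I)
  table$lipid_percent <- L
  table$d13C_corrected <- table$d13C + shift
  table
}

#' Inverse of the lipid correction shift
#'
#' Raw delta-13C that [lipid_correct()] would map to `target` at the
#' given C:N ratio.  Used by the synthetic-data generator.
#'
#' @param target target corrected delta-13C values.
#' @param cn_ratio C:N ratios (by weight).
#' @param params a [lipid_params()] object.
#' @return raw delta-13C values.
#' @export
lipid_uncorrect <- function(target, cn_ratio, params = lipid_params()) {
  tab <- lipid_correct(data.frame(d13C = 0, cn_ratio = cn_ratio), params)
  target - tab$d13C_corrected
}

#' Paired preservation-effect tests
#'
#' Within-sample comparison of air-dried vs chemically preserved
#' tissue values: mean difference, paired t test, and Wilcoxon signed
#' rank test (exact for n <= 25, normal approximation above).  When
#' all differences are zero the Wilcoxon test is undefined and is
#' reported with p = 1.
#'
#' @param dried,preserved paired per-specimen values (equal length).
#' @return list: `mean_difference`, `t_stat`, `t_p`, `wilcoxon_stat`,
#'   `wilcoxon_p`, `n`.
#' @export
preservation_paired_test <- function(dried, preserved) {
  if (length(dried) != length(preserved))
    stop("dried and preserved must be paired (equal length)")
  diffs <- preserved - dried
  n <- length(diffs)
  if (all(diffs == 0)) {
    return(list(mean_difference = 0, t_stat = 0, t_p = 1,
                wilcoxon_stat = NA_real_, wilcoxon_p = 1, n = n))
  }
  tt <- stats::t.test(preserved, dried, paired = TRUE)
  wt <- suppressWarnings(stats::wilcox.test(preserved, dried, paired = TRUE,
                                            exact = n <= 25L))
  list(mean_difference = mean(diffs),
       t_stat = unname(tt$statistic), t_p = tt$p.value,
       wilcoxon_stat = unname(wt$statistic), wilcoxon_p = wt$p.value,
       n = n)
}

#' Within-site species comparisons of isotope values
#'
#' One-way ANOVA between species, separately per site and per element
#' (corrected delta-13C and raw delta-15N).  Sites with fewer than two
#' species, or with any species below two individuals, are skipped
#' with a message; groups with n < 3 are flagged `low_n` (their tests
#' still run, but small samples deserve caution).
#'
#' @param table isotope data frame with columns `species`, `site`,
#'   `d13C_corrected`, `d15N`.
#' @return data frame: site, element, F, p, df, low_n flag.
#' @export
within_site_tests <- function(table) {
  stopifnot(all(c("species", "site", "d13C_corrected", "d15N") %in%
                  names(table)))
  out <- list()
  for (s in unique(table$site)) {
    sub <- table[table$site == s, ]
    counts <- table(sub$species)
    if (length(counts) < 2L) {
      message("site ", s, ": single species, skipped")
      next
    }
    if (any(counts < 2L)) {
      message("site ", s, ": species with n < 2, skipped")
      next
    }
    low_n <- any(counts < 3L)
    for (el in c("d13C_corrected", "d15N")) {
      a <- anova_oneway(sub[[el]], sub$species)
      out[[length(out) + 1L]] <- data.frame(
        site = s, element = el, F = a$statistic, p = a$p_value,
        df_between = a$df[["between"]], df_within = a$df[["within"]],
        low_n = low_n, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(data.frame())
  do.call(rbind, out)
}

#' Isotopic distance matrix between individuals
#'
#' Euclidean distances treating (corrected delta-13C, delta-15N) as
#' Cartesian coordinates.
#'
#' @param table isotope data frame with `specimen_id`,
#'   `d13C_corrected`, `d15N`.
#' @return a [dist_matrix()] labeled by specimen id.
#' @export
isotopic_distance_matrix <- function(table) {
  need <- c("specimen_id", "d13C_corrected", "d15N")
  stopifnot(all(need %in% names(table)))
  bad <- table$specimen_id[!stats::complete.cases(
    table[, c("d13C_corrected", "d15N")])]
  if (length(bad))
    stop("missing isotope values for: ", paste(bad, collapse = ", "))
  m <- as.matrix(stats::dist(table[, c("d13C_corrected", "d15N")]))
  dist_matrix(m, table$specimen_id)
}

#' Isotopic niche ellipses per group
#'
#' Standard ellipse area (SEA) and its small-sample correction (SEAc)
#' per group, the corresponding standard ellipse, and the pairwise
#' ellipse overlap areas by numerical polygon intersection.  Groups
#' with fewer than 3 individuals are skipped with a message.
#'
#' @param table isotope data frame with `d13C_corrected`, `d15N`, and
#'   the grouping column.
#' @param by grouping column name (`"species"` or `"site"`).
#' @return list: `areas` (data frame group/n/sea/seac), `ellipses`
#'   (named list of `ellipse_spec`), `overlap` (matrix of pairwise
#'   overlap areas).
#' @export
niche_ellipses <- function(table, by = "species") {
  stopifnot(by %in% names(table),
            all(c("d13C_corrected", "d15N") %in% names(table)))
  groups <- split(table, table[[by]])
  ok <- vapply(groups, nrow, 1L) >= 3L
  for (g in names(groups)[!ok])
    message("group ", g, ": n < 3, skipped")
  groups <- groups[ok]
  if (!length(groups)) stop("no group has n >= 3")
  specs <- lapply(groups, function(g) {
    pts <- as.matrix(g[, c("d13C_corrected", "d15N")])
    # standard ellipse: Mahalanobis radius 1 (q = 1)
    spec <- equal_frequency_ellipse(pts, probability = stats::pchisq(1, 2))
    spec$q <- 1
    spec$area <- pi * sqrt(det(spec$covariance))
    spec
  })
  areas <- data.frame(
    group = names(groups),
    n = vapply(groups, nrow, 1L),
    t(vapply(groups, function(g)
      unlist(sea_seac(as.matrix(g[, c("d13C_corrected", "d15N")]))[1:2]),
      numeric(2L))),
    row.names = NULL, stringsAsFactors = FALSE)
  ng <- length(specs)
  ov <- matrix(0, ng, ng, dimnames = list(names(specs), names(specs)))
  for (i in seq_len(ng)) for (j in seq_len(ng))
    ov[i, j] <- if (i == j) specs[[i]]$area else
      ellipse_overlap(specs[[i]], specs[[j]])
  list(areas = areas, ellipses = specs, overlap = ov)
}
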