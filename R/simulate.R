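## Seeded generators producing inputs with the statistical structure
## the pipeline assumes: multi-species landmark data with planted mean
## shape differences and allometry, bivariate-normal isotopic niches
## separated chiefly in delta-13C, Dirichlet diet compositions,
## Brownian-motion traits on a tree, and two-level population
## structured genotypes.

#' 16-landmark fish body template
#'
#' Fixed coordinate constant describing a generalized fish outline in
#' left lateral view (snout at the origin, caudal base at x = 1):
#' snout tip, head/eye, nape, dorsal-fin origin and end, dorsal and
#' ventral caudal peduncle, caudal base points, anal- and pelvic-fin
#' origins, pectoral origin, opercular edge, lower jaw.  Used as the
#' mean shape of [simulate_landmarks()].
#'
#' @return `16 x 2` coordinate matrix.
#' @export
fish_template <- function() {
  m <- matrix(c(
    0.00,  0.000,   # 1 snout tip
    0.08,  0.060,   # 2 eye / anterior head
    0.25,  0.120,   # 3 nape
    0.45,  0.160,   # 4 dorsal-fin origin
    0.70,  0.120,   # 5 dorsal-fin end
    0.85,  0.060,   # 6 dorsal caudal peduncle
    0.95,  0.030,   # 7 upper caudal base
    1.00,  0.000,   # 8 mid caudal base
    0.95, -0.030,   # 9 lower caudal base
    0.85, -0.060,   # 10 ventral caudal peduncle
    0.68, -0.110,   # 11 anal-fin end
    0.50, -0.140,   # 12 anal-fin origin
    0.35, -0.130,   # 13 pelvic-fin origin
    0.20, -0.100,   # 14 pectoral-fin origin
    0.10, -0.070,   # 15 opercular edge
    0.03, -0.030),  # 16 lower jaw
    ncol = 2L, byrow = TRUE)
  colnames(m) <- c("x", "y")
  m
}

## project a displacement field into pure shape space: remove the
## translation component (column means) and the component along the
## template preshape (pure scaling), then renormalize
as_shape_direction <- function(d) {
  tpl <- fish_template()
  tpl <- center_config(tpl) / centroid_size(tpl)
  d <- sweep(d, 2L, colMeans(d))
  d <- d - sum(d * tpl) * tpl
  d / sqrt(sum(d^2))
}

## unit-norm mean-shape offset directions (k x 2 each), themed on the
## mouth/snout contrasts the landmark stages must detect
shape_offset_direction <- function(which = c("upturned_mouth",
                                             "subterminal_mouth",
                                             "deep_body")) {
  which <- match.arg(which)
  d <- matrix(0, 16L, 2L)
  if (which == "upturned_mouth") {
    d[1L, 2L] <- 1; d[2L, 2L] <- 0.5; d[16L, 2L] <- 1
  } else if (which == "subterminal_mouth") {
    d[1L, 2L] <- -1; d[16L, 2L] <- -0.8; d[2L, 1L] <- 0.4
  } else {
    d[4L, 2L] <- 1; d[12L, 2L] <- -1; d[3L, 2L] <- 0.5; d[13L, 2L] <- -0.5
  }
  as_shape_direction(d)
}

## default unit allometry direction: relative head shrinkage and body
## deepening with size
allometry_direction <- function() {
  d <- matrix(0, 16L, 2L)
  d[2L, 1L] <- 1; d[15L, 1L] <- 1; d[1L, 1L] <- 0.5
  d[4L, 2L] <- 0.8; d[12L, 2L] <- -0.8
  as_shape_direction(d)
}

#' Default three-species simulation configuration
#'
#' Study-like conditions for the whole synthetic pipeline: three
#' sympatric species at one site; mean-shape offsets of 0.05
#' Procrustes units in distinct directions with landmark noise sd
#' 0.01 and an allometry vector of norm 0.15 per log10 size unit over
#' sizes 10^1.6 to 10^2.2 mm; bivariate-normal isotopic niches in
#' which only the first species is shifted in delta-13C (by about
#' +6 per mille) while delta-15N is shared; Dirichlet diet
#' compositions with the first species cellulose-dominated and the
#' others algae-dominated; isotope sample size 15 per species.
#'
#' @param seed integer seed for all generators reading this config.
#' @return nested list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L) {
  groups <- list(
    list(label = "sp_alcalica", n_landmarks = 30L, n_isotopes = 15L,
         shape_offset = 0.05 * shape_offset_direction("upturned_mouth"),
         isotope_mean = c(d13C = -14, d15N = 8.0),
         isotope_cov = matrix(c(2.25, 0.3, 0.3, 0.64), 2L),
         diet_concentration = c(algae_cyanobacteria = 30,
                                cellulose_plant = 43,
                                small_arthropods = 10, fry_eggs = 2,
                                fish_remains_scales = 5,
                                grit_sand = 10) * 0.25,
         cn_mean = 3.6),
    list(label = "sp_latilabris", n_landmarks = 30L, n_isotopes = 15L,
         shape_offset = 0.05 * shape_offset_direction("subterminal_mouth"),
         isotope_mean = c(d13C = -20, d15N = 8.0),
         isotope_cov = matrix(c(2.25, 0.3, 0.3, 0.64), 2L),
         diet_concentration = c(algae_cyanobacteria = 70,
                                cellulose_plant = 5,
                                small_arthropods = 5, fry_eggs = 1,
                                fish_remains_scales = 4,
                                grit_sand = 15) * 0.25,
         cn_mean = 3.4),
    list(label = "sp_ndalalani", n_landmarks = 30L, n_isotopes = 15L,
         shape_offset = 0.05 * shape_offset_direction("deep_body"),
         isotope_mean = c(d13C = -21, d15N = 8.0),
         isotope_cov = matrix(c(2.25, 0.3, 0.3, 0.64), 2L),
         diet_concentration = c(algae_cyanobacteria = 77,
                                cellulose_plant = 4,
                                small_arthropods = 6, fry_eggs = 1,
                                fish_remains_scales = 4,
                                grit_sand = 8) * 0.25,
         cn_mean = 3.4))
  structure(list(seed = as.integer(seed),
                 groups = groups,
                 site = "site05",
                 landmark_noise_sd = 0.01,
                 allometry_vector = 0.15 * allometry_direction(),
                 size_range = c(1.6, 2.2),
                 bm_sigma2 = 1,
                 fst_drift = c(0.1, 0.1)),
            class = "sim_config")
}

## deterministic sub-seed per generator so adding one generator never
## perturbs the draws of another (kept below 2^31)
fork_seed <- function(seed, label) {
  offsets <- c(landmarks = 101L, isotopes = 211L, diet = 307L,
               bm = 401L, genotypes = 503L)
  (as.integer(seed) * 7919L + offsets[[label]]) %% 2147483629L
}

#' Simulate multi-species landmark configurations
#'
#' Per specimen: shape = [fish_template()] (as a unit-size preshape)
#' + its group's mean-shape offset + allometry_vector * (log10 size -
#' mid-range) + isotropic Gaussian landmark noise; the configuration
#' is then scaled to its centroid size, randomly rotated and
#' translated, so superimposition has real work to do.  Bit
#' reproducible given (seed, config).
#'
#' @param cfg a [sim_config()].
#' @return a [landmark_set()] with species/site/size metadata and
#'   attribute `true_log_sizes`.
#' @export
simulate_landmarks <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(fork_seed(cfg$seed, "landmarks"))
  template <- fish_template()
  template <- center_config(template) / centroid_size(template)
  k <- nrow(template)
  configs <- list(); species <- character(0); sizes <- numeric(0)
  mid <- mean(cfg$size_range)
  for (g in cfg$groups) {
    if (nrow(g$shape_offset) != k) stop("shape offset dimension mismatch")
    for (i in seq_len(g$n_landmarks)) {
      s <- stats::runif(1L, cfg$size_range[1L], cfg$size_range[2L])
      shp <- template + g$shape_offset +
        cfg$allometry_vector * (s - mid) +
        matrix(stats::rnorm(2L * k, sd = cfg$landmark_noise_sd), k, 2L)
      if (min(stats::dist(shp)) < 1e-6)
        stop("planted offsets collapse landmarks (spacing < 1e-6)")
      theta <- stats::runif(1L, 0, 2 * pi)
      R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L)
      xy <- (shp %*% R) * 10^s
      xy <- sweep(xy, 2L, stats::runif(2L, -100, 100), `+`)
      configs[[length(configs) + 1L]] <- xy
      species <- c(species, g$label)
      sizes <- c(sizes, s)
    }
  }
  out <- landmark_set(configs,
                      records = data.frame(
                        specimen_id = sprintf("lm%03d", seq_along(configs)),
                        species = species, site = cfg$site,
                        stringsAsFactors = FALSE),
                      scale_units = "mm")
  attr(out, "true_log_sizes") <- sizes
  out
}

#' Simulate an isotope table
#'
#' Per group, bivariate normal (delta-13C, delta-15N) draws around the
#' configured niche centre; C:N ratios from a gamma distribution
#' around the group mean (cv 8%); the raw delta-13C is back-computed
#' with [lipid_uncorrect()] so that [lipid_correct()] under default
#' parameters returns exactly the drawn target values.
#'
#' @param cfg a [sim_config()].
#' @param params [lipid_params()] assumed by the back-computation.
#' @return data frame: specimen_id, species, site, d13C (raw), d15N,
#'   cn_ratio, plus the target corrected values in
#'   `d13C_target`.
#' @export
simulate_isotopes <- function(cfg = sim_config(), params = lipid_params()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(fork_seed(cfg$seed, "isotopes"))
  rows <- lapply(cfg$groups, function(g) {
    ev <- eigen(g$isotope_cov, symmetric = TRUE, only.values = TRUE)$values
    if (any(ev <= 0)) stop("isotope covariance must be positive definite")
    xy <- MASS::mvrnorm(g$n_isotopes, g$isotope_mean, g$isotope_cov)
    # C:N as a structural floor of 3.2 (lipid-free muscle) plus a
    # gamma-distributed lipid excess, keeping draws inside the
    # calibrated range of the correction curve
    excess <- g$cn_mean - 3.2
    if (excess <= 0) stop("cn_mean must exceed 3.2")
    cn <- 3.2 + stats::rgamma(g$n_isotopes, shape = 4,
                              rate = 4 / excess)
    data.frame(species = g$label, site = cfg$site,
               d13C_target = xy[, 1L], d15N = xy[, 2L], cn_ratio = cn,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$specimen_id <- sprintf("iso%03d", seq_len(nrow(tab)))
  tab$d13C <- lipid_uncorrect(tab$d13C_target, tab$cn_ratio, params)
  tab[, c("specimen_id", "species", "site", "d13C", "d15N",
          "cn_ratio", "d13C_target")]
}

#' Simulate diet composition records
#'
#' Dirichlet draws (gamma normalization) around each group's
#' concentration vector, scaled to percentages.
#'
#' @param cfg a [sim_config()].
#' @param n_per_group records per group (default 30).
#' @return a normalized [diet_records()] table.
#' @export
simulate_diet <- function(cfg = sim_config(), n_per_group = 30L) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(fork_seed(cfg$seed, "diet"))
  rows <- lapply(cfg$groups, function(g) {
    conc <- g$diet_concentration[diet_categories]
    if (any(conc <= 0)) stop("diet concentrations must be positive")
    draws <- t(vapply(seq_len(n_per_group), function(i) {
      x <- stats::rgamma(length(conc), shape = conc)
      100 * x / sum(x)
    }, numeric(length(conc))))
    colnames(draws) <- diet_categories
    data.frame(species = g$label, site = cfg$site, draws,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$specimen_id <- sprintf("diet%03d", seq_len(nrow(tab)))
  diet_records(tab[, c("specimen_id", "species", "site", diet_categories)])
}

#' Simulate Brownian-motion tip values on a tree
#'
#' Recursive normal increments from the root: along each branch the
#' state changes by N(0, sigma2 * branch length).
#'
#' @param tree rooted [ape::phylo] with branch lengths.
#' @param sigma2 BM rate (>= 0).
#' @param root root state.
#' @param seed optional integer seed.
#' @return named numeric vector of tip values.
#' @export
simulate_bm <- function(tree, sigma2 = 1, root = 0, seed = NULL) {
  validate_phylogeny(tree)
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- length(tree$tip.label)
  states <- numeric(n + tree$Nnode)
  states[n + 1L] <- root
  # cladewise edge order guarantees every parent precedes its children
  tree <- stats::reorder(tree, "cladewise")
  for (e in seq_len(nrow(tree$edge))) {
    u <- tree$edge[e, 1L]; v <- tree$edge[e, 2L]
    states[v] <- states[u] +
      stats::rnorm(1L, sd = sqrt(sigma2 * tree$edge.length[e]))
  }
  stats::setNames(states[seq_len(n)], tree$tip.label)
}

#' Simulate population-structured genotypes
#'
#' Balding-Nichols model: ancestral allele frequencies Uniform(0.05,
#' 0.95); each population's frequency is Beta-distributed around the
#' ancestral one with variance governed by its drift parameter F
#' (shape parameters `p(1-F)/F` and `(1-p)(1-F)/F`); genotypes are
#' Binomial(2, freq) dosages.  Positions are laid out on two
#' chromosomes with ~100 kb spacing jitter so physical thinning has
#' work to do.
#'
#' @param cfg a [sim_config()] (drift parameters from `fst_drift`).
#' @param n_per_pop samples per population.
#' @param n_loci number of loci.
#' @return a [genotype_data()] object; population labels in attribute
#'   `populations`.
#' @export
simulate_genotypes <- function(cfg = sim_config(), n_per_pop = 20L,
                               n_loci = 400L) {
  stopifnot(inherits(cfg, "sim_config"))
  drift <- cfg$fst_drift
  if (any(drift <= 0 | drift >= 1)) stop("drift parameters must be in (0,1)")
  set.seed(fork_seed(cfg$seed, "genotypes"))
  n_pop <- length(drift)
  p_anc <- stats::runif(n_loci, 0.05, 0.95)
  geno <- matrix(NA_integer_, n_pop * n_per_pop, n_loci)
  pops <- rep(paste0("pop", seq_len(n_pop)), each = n_per_pop)
  for (pp in seq_len(n_pop)) {
    f <- drift[pp]
    pf <- stats::rbeta(n_loci, p_anc * (1 - f) / f,
                       (1 - p_anc) * (1 - f) / f)
    rows <- (pp - 1L) * n_per_pop + seq_len(n_per_pop)
    geno[rows, ] <- vapply(seq_len(n_loci), function(l)
      stats::rbinom(n_per_pop, 2L, pf[l]), integer(n_per_pop))
  }
  per_chrom <- ceiling(n_loci / 2L)
  chrom <- rep(c("chr1", "chr2"), c(per_chrom, n_loci - per_chrom))
  pos <- unlist(lapply(split(seq_len(n_loci), chrom), function(idx)
    cumsum(sample(20000:180000, length(idx), replace = TRUE))),
    use.names = FALSE)
  out <- genotype_data(geno,
                       loci = data.frame(chrom = chrom, pos = pos),
                       samples = sprintf("s%03d", seq_len(nrow(geno))))
  attr(out, "populations") <- pops
  out
}
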