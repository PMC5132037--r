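## Generalized Procrustes analysis and related shape machinery.
## Conventions: configurations are k x 2 matrices; the flattened shape
## vector is c(x_1..x_k, y_1..y_k) (length 2k).

center_config <- function(x) sweep(x, 2L, colMeans(x))

preshape <- function(x) {
  x <- center_config(x)
  x / sqrt(sum(x^2))
}

## Optimal rotation R (det +1) minimizing ||target - x %*% R||^2
optimal_rotation <- function(x, target) {
  s <- svd(crossprod(x, target))
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, d)) %*% t(s$v)
}

#' Generalized Procrustes analysis
#'
#' Iterative full-Procrustes superimposition: every configuration is
#' centred, scaled to unit centroid size, and rotated (reflections
#' disallowed) onto the running consensus; the consensus is the mean of
#' the aligned configurations, renormalized to unit size, and iteration
#' continues until it moves by less than `tol`.  Aligned coordinates
#' are finally projected orthogonally onto the tangent space at the
#' consensus.
#'
#' @param data a [landmark_set()] with at least two specimens.
#' @param tol convergence tolerance on the consensus (root summed
#'   squared change per iteration).
#' @param max_iter iteration cap; non-convergence is an error.
#' @return object of class `aligned_shapes`: `coords` (n x k x 2
#'   tangent-projected Procrustes coordinates), `centroid_sizes`
#'   (original units), `consensus` (k x 2, arithmetic mean of the
#'   aligned configurations), `iterations_used`, plus the originating
#'   `records` and `roles`.
#' @export
gpa <- function(data, tol = 1e-10, max_iter = 100L) {
  stopifnot(inherits(data, "landmark_set"))
  n <- n_specimens(data); k <- n_landmarks(data)
  if (n < 2L) stop("GPA needs at least 2 specimens")
  cs <- numeric(n)
  configs <- vector("list", n)
  for (i in seq_len(n)) {
    x <- center_config(data$coords[i, , ])
    cs[i] <- sqrt(sum(x^2))
    if (cs[i] <= 0) stop("degenerate configuration for specimen ", i)
    configs[[i]] <- x / cs[i]
  }
  consensus <- configs[[1L]]
  consensus <- consensus / sqrt(sum(consensus^2))
  iter <- 0L
  rss <- numeric(0)
  repeat {
    iter <- iter + 1L
    aligned <- lapply(configs, function(x) x %*% optimal_rotation(x, consensus))
    new_cons <- Reduce(`+`, aligned) / n
    new_cons <- new_cons / sqrt(sum(new_cons^2))
    rss[iter] <- sum(vapply(aligned, function(x)
      sum((x - new_cons)^2), numeric(1L)))
    change <- sqrt(sum((new_cons - consensus)^2))
    consensus <- new_cons
    if (change < tol) break
    if (iter >= max_iter)
      stop("GPA did not converge in ", max_iter,
           " iterations (last consensus change ", format(change), ")")
  }
  # canonical orientation: principal axes of the consensus, major axis
  # first, sign fixed by the largest-magnitude projection; makes the
  # output invariant to similarity transforms of the inputs
  e <- eigen(crossprod(consensus), symmetric = TRUE)
  v1 <- e$vectors[, 1L]
  pr <- drop(consensus %*% v1)
  if (pr[which.max(abs(pr))] < 0) v1 <- -v1
  Rc <- cbind(v1, c(-v1[2L], v1[1L]))  # det +1, no reflection
  consensus <- consensus %*% Rc
  aligned <- lapply(configs, function(x) x %*% optimal_rotation(x, consensus))
  # orthogonal projection onto the tangent hyperplane <y, c> = 1 at the
  # unit-norm consensus
  cvec <- as.vector(consensus)
  proj <- lapply(aligned, function(x) {
    v <- as.vector(x)
    matrix(v + (1 - sum(v * cvec)) * cvec, ncol = 2L)
  })
  coords <- aperm(simplify2array(proj), c(3L, 1L, 2L))
  dimnames(coords) <- dimnames(data$coords)
  structure(list(coords = coords,
                 centroid_sizes = cs,
                 consensus = Reduce(`+`, proj) / n,
                 iterations_used = iter,
                 rss = rss,
                 records = data$records,
                 roles = data$roles),
            class = "aligned_shapes")
}

#' @export
print.aligned_shapes <- function(x, ...) {
  cat("Aligned shapes:", dim(x$coords)[1], "specimens,",
      dim(x$coords)[2], "landmarks; GPA converged in",
      x$iterations_used, "iteration(s)\n")
  invisible(x)
}

#' Flatten aligned shapes to an n x 2k matrix
#'
#' Columns are ordered `x1..xk, y1..yk`, the layout used by the
#' regression, ordination and PLS stages.
#'
#' @param shapes an `aligned_shapes` object (or a `landmark_set`).
#' @return numeric matrix `n x 2k` with specimen ids as rownames.
#' @export
shape_matrix <- function(shapes) {
  co <- shapes$coords
  m <- cbind(co[, , 1L], co[, , 2L])
  rownames(m) <- dimnames(co)[[1L]]
  colnames(m) <- c(paste0("x", seq_len(dim(co)[2])),
                   paste0("y", seq_len(dim(co)[2])))
  m
}

#' Full Procrustes distance between two configurations
#'
#' Both configurations are reduced to preshapes (centred, unit centroid
#' size); the distance is the square root of the minimized residual sum
#' of squares after the optimal rotation-and-scale fit of one onto the
#' other, `sqrt(1 - s^2)` with `s` the reflection-corrected sum of
#' singular values of the preshape cross-product.  Symmetric, and zero
#' iff the shapes are identical up to a similarity transform.
#'
#' @param a,b `k x 2` coordinate matrices with the same `k`.
#' @return nonnegative scalar.
#' @export
procrustes_distance <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!identical(dim(a), dim(b)))
    stop("configurations differ in dimension: ",
         paste(dim(a), collapse = "x"), " vs ", paste(dim(b), collapse = "x"))
  pa <- preshape(a); pb <- preshape(b)
  sv <- svd(crossprod(pb, pa))
  s <- sum(sv$d[-length(sv$d)]) + sign(det(sv$u %*% t(sv$v))) *
    sv$d[length(sv$d)]
  sqrt(max(0, 1 - s^2))
}

#' Regress shape on log centroid size (allometry correction)
#'
#' Ordinary least squares of each Procrustes shape variable on
#' log10 centroid size, pooled across all specimens.  The residuals
#' (column means zero) are the size-corrected shape variables used by
#' downstream ordination and tests; `percent_predicted` is the share of
#' total shape variance explained by size.
#'
#' @param shapes an `aligned_shapes` object from [gpa()].
#' @param log_base base for the size logarithm (10 by default).
#' @return object of class `shape_regression`: `coefficients` (length
#'   2k slope vector), `intercepts`, `residuals` (n x 2k),
#'   `fitted`, `percent_predicted`, `log_size`.
#' @export
regress_shape_on_size <- function(shapes, log_base = 10) {
  stopifnot(inherits(shapes, "aligned_shapes"))
  y <- shape_matrix(shapes)
  if (nrow(y) < 3L) stop("need at least 3 specimens")
  if (any(shapes$centroid_sizes <= 0)) stop("centroid sizes must be positive")
  x <- log(shapes$centroid_sizes, base = log_base)
  if (stats::sd(x) == 0)
    stop("constant centroid size: allometry is not estimable")
  xc <- x - mean(x)
  yc <- sweep(y, 2L, colMeans(y))
  beta <- as.vector(crossprod(xc, yc) / sum(xc^2))
  fitted_c <- outer(xc, beta)
  res <- yc - fitted_c
  ss_tot <- sum(yc^2)
  ss_mod <- sum(fitted_c^2)
  structure(list(coefficients = stats::setNames(beta, colnames(y)),
                 intercepts = colMeans(y) - mean(x) * beta,
                 residuals = res,
                 fitted = sweep(fitted_c, 2L, colMeans(y), `+`),
                 percent_predicted = 100 * ss_mod / ss_tot,
                 log_size = x),
            class = "shape_regression")
}

#' @export
print.shape_regression <- function(x, ...) {
  cat("Shape ~ log centroid size:", nrow(x$residuals), "specimens;",
      sprintf("%.2f%%", x$percent_predicted),
      "of shape variance predicted by size\n")
  invisible(x)
}

#' Symmetry map for object-symmetric structures
#'
#' @param paired two-column integer matrix of (left, right) landmark
#'   index pairs.
#' @param midline integer vector of unpaired midline landmark indices.
#' @param k total number of landmarks; every landmark must appear
#'   exactly once across `paired` and `midline`.
#' @return object of class `symmetry_map`.
#' @export
symmetry_map <- function(paired, midline, k) {
  paired <- matrix(as.integer(paired), ncol = 2L)
  midline <- as.integer(midline)
  all_idx <- c(as.vector(paired), midline)
  if (any(all_idx < 1L | all_idx > k))
    stop("paired/midline indices out of range 1..", k)
  if (length(all_idx) != k || anyDuplicated(all_idx))
    stop("every landmark must appear exactly once across paired and midline")
  structure(list(paired = paired, midline = midline, k = k),
            class = "symmetry_map")
}

#' Symmetric shape component under object symmetry
#'
#' For a bilaterally symmetric structure digitized as a single
#' configuration, each specimen is mirrored (x negated) with paired
#' landmark labels swapped, GPA is run on the doubled sample, and the
#' symmetric component of each specimen is the mean of its aligned
#' original and mirrored copies.  The per-specimen aligned distance
#' between the two copies measures asymmetry.
#'
#' @param data a [landmark_set()].
#' @param map a [symmetry_map()] covering all landmarks of `data`.
#' @param ... passed to [gpa()].
#' @return an `aligned_shapes` object of symmetric components, with an
#'   `asymmetry` element (per-specimen Euclidean distance between
#'   aligned original and mirror).
#' @export
symmetric_component <- function(data, map, ...) {
  stopifnot(inherits(data, "landmark_set"), inherits(map, "symmetry_map"))
  k <- n_landmarks(data)
  if (map$k != k) stop("symmetry map is for ", map$k, " landmarks, data has ", k)
  n <- n_specimens(data)
  relabel <- seq_len(k)
  relabel[map$paired[, 1L]] <- map$paired[, 2L]
  relabel[map$paired[, 2L]] <- map$paired[, 1L]
  doubled <- array(NA_real_, c(2L * n, k, 2L))
  doubled[seq_len(n), , ] <- data$coords
  for (i in seq_len(n)) {
    m <- data$coords[i, , ]
    m[, 1L] <- -m[, 1L]
    doubled[n + i, , ] <- m[relabel, ]
  }
  ids <- data$records$specimen_id
  dbl <- landmark_set(doubled,
                      records = data.frame(
                        specimen_id = c(ids, paste0(ids, ".mirror")),
                        stringsAsFactors = FALSE),
                      roles = data$roles, scale_units = data$scale_units)
  al <- gpa(dbl, ...)
  sym <- (al$coords[seq_len(n), , , drop = FALSE] +
            al$coords[n + seq_len(n), , , drop = FALSE]) / 2
  dimnames(sym) <- dimnames(data$coords)
  asym <- vapply(seq_len(n), function(i)
    sqrt(sum((al$coords[i, , ] - al$coords[n + i, , ])^2)), numeric(1L))
  structure(list(coords = sym,
                 centroid_sizes = vapply(seq_len(n), function(i)
                   centroid_size(data$coords[i, , ]), numeric(1L)),
                 consensus = apply(sym, c(2L, 3L), mean),
                 iterations_used = al$iterations_used,
                 records = data$records,
                 roles = data$roles,
                 asymmetry = stats::setNames(asym, ids)),
            class = "aligned_shapes")
}
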