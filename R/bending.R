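## Thin-plate spline bending energy and sliding semilandmarks.

#' Thin-plate-spline bending energy matrix
#'
#' For a reference configuration, the bending energy of a target is
#' `t(yx) %*% Be %*% yx + t(yy) %*% Be %*% yy` where `Be` is the
#' upper-left `k x k` block of the inverse of the bordered TPS system
#' built from the kernel `U(r) = r^2 log(r^2)`.  `Be` is symmetric
#' positive semidefinite and annihilates affine terms: its rows sum to
#' zero and are orthogonal to the reference coordinates, so affine
#' deformations of the reference have exactly zero bending energy.
#'
#' @param reference `k x 2` matrix without duplicate points.
#' @return `k x k` bending energy matrix.
#' @export
bending_energy_matrix <- function(reference) {
  reference <- as.matrix(reference)
  k <- nrow(reference)
  if (k < 4L) stop("need at least 4 landmarks for a TPS")
  d <- as.matrix(stats::dist(reference))
  if (any(d[upper.tri(d)] < 1e-12))
    stop("duplicate landmarks in reference: TPS system is singular")
  K <- ifelse(d > 0, d^2 * log(d^2), 0)
  Q <- cbind(1, reference)
  L <- rbind(cbind(K, Q), cbind(t(Q), matrix(0, 3L, 3L)))
  Linv <- tryCatch(solve(L), error = function(e)
    stop("singular TPS system: ", conditionMessage(e)))
  Be <- Linv[seq_len(k), seq_len(k), drop = FALSE]
  (Be + t(Be)) / 2
}

#' Bending energy of a target relative to a reference
#'
#' @param target `k x 2` target configuration.
#' @param reference `k x 2` reference configuration, or a precomputed
#'   matrix from [bending_energy_matrix()].
#' @return nonnegative scalar (numerically, clipped at 0).
#' @export
bending_energy <- function(target, reference) {
  target <- as.matrix(target)
  Be <- if (is.matrix(reference) && nrow(reference) == ncol(reference) &&
            nrow(reference) == nrow(target) && ncol(reference) != 2L)
    reference else bending_energy_matrix(reference)
  e <- sum(diag(t(target) %*% Be %*% target))
  max(0, e)
}

#' Sliding scheme for semilandmarks
#'
#' Defines, for each semilandmark, the pair of neighbouring landmarks
#' whose chord gives its tangent direction.  Endpoints of open curves
#' use `NA` for the missing neighbour and anchor to the chord from the
#' semilandmark to its single neighbour.
#'
#' @param semilandmarks integer vector of semilandmark indices.
#' @param neighbors two-column integer matrix (prev, next), one row per
#'   semilandmark; `NA` allowed in one column for curve endpoints.
#' @param iterations number of slide/GPA cycles (default 10).
#' @return object of class `sliding_scheme`.
#' @export
sliding_scheme <- function(semilandmarks, neighbors, iterations = 10L) {
  semilandmarks <- as.integer(semilandmarks)
  neighbors <- matrix(as.integer(neighbors), ncol = 2L)
  if (nrow(neighbors) != length(semilandmarks))
    stop("one neighbor pair per semilandmark required")
  if (any(rowSums(is.na(neighbors)) > 1L))
    stop("each semilandmark needs at least one neighbor")
  structure(list(semilandmarks = semilandmarks, neighbors = neighbors,
                 iterations = as.integer(iterations)),
            class = "sliding_scheme")
}

## tangent unit vectors for the semilandmarks of one configuration
slide_tangents <- function(config, scheme) {
  m <- length(scheme$semilandmarks)
  u <- matrix(NA_real_, m, 2L)
  for (j in seq_len(m)) {
    s <- scheme$semilandmarks[j]
    p <- scheme$neighbors[j, 1L]; q <- scheme$neighbors[j, 2L]
    v <- if (is.na(p)) config[q, ] - config[s, ]
    else if (is.na(q)) config[s, ] - config[p, ]
    else config[q, ] - config[p, ]
    len <- sqrt(sum(v^2))
    if (len < 1e-12)
      stop("zero-length tangent chord at semilandmark index ", s)
    u[j, ] <- v / len
  }
  u
}

#' Slide one configuration's semilandmarks against a reference
#'
#' Closed-form joint solve for the slide amounts `t` of all
#' semilandmarks of a single configuration: each semilandmark `j`
#' moves along its unit chord tangent by `t_j`, with `t` minimizing
#' the TPS bending energy of the slid configuration relative to the
#' reference (a linear solve, since the energy is quadratic in `t`).
#'
#' @param config `k x 2` configuration to slide.
#' @param reference `k x 2` TPS reference (e.g. a sample consensus).
#' @param scheme a [sliding_scheme()].
#' @return list: `coords` (slid configuration), `t` (slide amounts),
#'   `energy_before`, `energy_after`.
#' @export
slide_config <- function(config, reference, scheme) {
  config <- as.matrix(config)
  k <- nrow(config)
  idx <- scheme$semilandmarks
  m <- length(idx)
  Be <- bending_energy_matrix(reference)
  u <- slide_tangents(config, scheme)
  U <- matrix(0, 2L * k, m)
  U[cbind(idx, seq_len(m))] <- u[, 1L]
  U[cbind(k + idx, seq_len(m))] <- u[, 2L]
  Ux <- U[seq_len(k), , drop = FALSE]
  Uy <- U[k + seq_len(k), , drop = FALSE]
  B2y <- c(Be %*% config[, 1L], Be %*% config[, 2L])
  UtBU <- t(Ux) %*% Be %*% Ux + t(Uy) %*% Be %*% Uy
  tvec <- tryCatch(-solve(UtBU, crossprod(U, B2y)),
                   error = function(e)
                     -MASS::ginv(UtBU) %*% crossprod(U, B2y))
  ynew <- c(config[, 1L], config[, 2L]) + as.vector(U %*% tvec)
  slid <- cbind(ynew[seq_len(k)], ynew[k + seq_len(k)])
  list(coords = slid, t = as.vector(tvec),
       energy_before = bending_energy(config, Be),
       energy_after = bending_energy(slid, Be))
}

#' Slide semilandmarks by minimum bending energy
#'
#' Iterative relaxation of semilandmark positions along their curve
#' tangents.  Each cycle: (i) GPA of the current data; (ii) the sample
#' consensus becomes the TPS reference; (iii) for every specimen the
#' slide amounts `t` of all semilandmarks (along unit chord tangents
#' between their neighbours, recomputed per cycle) are found jointly by
#' the closed-form linear solve minimizing the specimen's bending
#' energy relative to the reference; (iv) coordinates are updated.
#' Within every cycle the minimization cannot increase bending energy;
#' the per-cycle energy trace is returned as an attribute.
#'
#' @param data a [landmark_set()].
#' @param scheme a [sliding_scheme()] valid for `data`.
#' @param ... passed to [gpa()].
#' @return a `landmark_set` of slid (Procrustes-aligned) coordinates
#'   with attribute `energy` — a data frame of total bending energy
#'   before and after sliding per iteration.  With
#'   `scheme$iterations == 0` the input is returned unchanged.
#' @export
slide_semilandmarks <- function(data, scheme, ...) {
  stopifnot(inherits(data, "landmark_set"), inherits(scheme, "sliding_scheme"))
  k <- n_landmarks(data)
  idx <- scheme$semilandmarks
  if (any(idx < 1L | idx > k)) stop("semilandmark index out of range")
  nb <- scheme$neighbors[!is.na(scheme$neighbors)]
  if (any(nb < 1L | nb > k)) stop("neighbor index out of range")
  if (scheme$iterations == 0L) return(data)
  cur <- data
  n <- n_specimens(data)
  m <- length(idx)
  energy <- matrix(NA_real_, scheme$iterations, 2L)
  for (it in seq_len(scheme$iterations)) {
    al <- gpa(cur, ...)
    ref <- al$consensus
    new_coords <- al$coords
    e_before <- 0; e_after <- 0
    for (i in seq_len(n)) {
      s <- slide_config(al$coords[i, , ], ref, scheme)
      e_before <- e_before + s$energy_before
      e_after <- e_after + s$energy_after
      new_coords[i, , ] <- s$coords
    }
    energy[it, ] <- c(e_before, e_after)
    cur <- landmark_set(new_coords, cur$records, cur$roles, cur$scale_units)
  }
  attr(cur, "energy") <- data.frame(iteration = seq_len(scheme$iterations),
                                    before = energy[, 1L],
                                    after = energy[, 2L])
  cur
}
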