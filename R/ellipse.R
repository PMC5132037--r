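## Bivariate equal-frequency ellipses and standard ellipse areas.

#' Equal-frequency ellipse of a bivariate sample
#'
#' Centre at the sample mean; boundary at the Mahalanobis contour of
#' the sample covariance scaled by the chi-square (2 df) quantile at
#' `probability`, so that under bivariate normality the ellipse
#' contains that fraction of the population.  Its area is
#' `pi * q * sqrt(det(cov))` with `q = qchisq(probability, 2)`.
#'
#' @param points `n x 2` matrix, `n >= 3`.
#' @param probability coverage probability in (0, 1); 0.9 draws the
#'   conventional equal-frequency ellipse of ordination scatter plots.
#' @return object of class `ellipse_spec`: `center`, `covariance`,
#'   `probability`, `q` (radius-squared scaling), `area`.
#' @export
equal_frequency_ellipse <- function(points, probability = 0.9) {
  points <- as.matrix(points)
  if (ncol(points) != 2L) stop("points must be n x 2")
  if (nrow(points) < 3L) stop("need at least 3 points")
  if (probability <= 0 || probability >= 1)
    stop("probability must be in (0, 1)")
  S <- stats::cov(points)
  if (det(S) <= 1e-300) stop("singular covariance: ellipse undefined")
  q <- stats::qchisq(probability, df = 2L)
  structure(list(center = colMeans(points), covariance = S,
                 probability = probability, q = q,
                 area = pi * q * sqrt(det(S))),
            class = "ellipse_spec")
}

#' @export
print.ellipse_spec <- function(x, ...) {
  cat(sprintf("Ellipse: center (%.3f, %.3f), probability %.3g, area %.4g\n",
              x$center[1L], x$center[2L], x$probability, x$area))
  invisible(x)
}

#' Test points for ellipse membership
#'
#' @param spec an `ellipse_spec`.
#' @param points `n x 2` matrix.
#' @return logical vector: is each point inside (or on) the boundary?
#' @export
in_ellipse <- function(spec, points) {
  points <- as.matrix(points)
  stats::mahalanobis(points, spec$center, spec$covariance) <= spec$q
}

#' Polygonal approximation of an ellipse boundary
#'
#' @param spec an `ellipse_spec`.
#' @param n_vertices number of boundary vertices.
#' @return `n_vertices x 2` matrix tracing the boundary.
#' @export
ellipse_polygon <- function(spec, n_vertices = 360L) {
  e <- eigen(spec$covariance, symmetric = TRUE)
  theta <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  circ <- cbind(cos(theta), sin(theta))
  pts <- circ %*% diag(sqrt(spec$q * e$values)) %*% t(e$vectors)
  sweep(pts, 2L, spec$center, `+`)
}

#' Standard ellipse area with small-sample correction
#'
#' The standard ellipse area of a bivariate scatter is
#' `SEA = pi * sqrt(lambda1 * lambda2)` from the sample covariance
#' eigenvalues (the ~40% density contour used as an isotopic niche
#' width metric); `SEAc = SEA * (n - 1) / (n - 2)` corrects the
#' small-sample bias.
#'
#' @param points `n x 2` matrix with `n >= 3`.
#' @return list with `sea`, `seac`, and `n`.
#' @export
sea_seac <- function(points) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 3L) stop("need at least 3 points for SEA")
  ev <- eigen(stats::cov(points), symmetric = TRUE, only.values = TRUE)$values
  sea <- pi * sqrt(prod(pmax(ev, 0)))
  list(sea = sea, seac = sea * (n - 1) / (n - 2), n = n)
}

signed_area <- function(p) {
  i2 <- c(seq_len(nrow(p))[-1L], 1L)
  sum(p[, 1L] * p[i2, 2L] - p[i2, 1L] * p[, 2L]) / 2
}

ensure_ccw <- function(p) if (signed_area(p) < 0) p[rev(seq_len(nrow(p))), ] else p

## Sutherland-Hodgman clipping of a convex subject polygon by a convex
## clip polygon; returns the clipped polygon.
clip_convex <- function(subject, clip) {
  subject <- ensure_ccw(subject)
  clip <- ensure_ccw(clip)
  out <- subject
  nc <- nrow(clip)
  for (i in seq_len(nc)) {
    if (nrow(out) == 0L) return(out)
    a <- clip[i, ]; b <- clip[if (i == nc) 1L else i + 1L, ]
    # inside = left of directed edge a->b
    side <- function(p) (b[1L] - a[1L]) * (p[2L] - a[2L]) -
      (b[2L] - a[2L]) * (p[1L] - a[1L])
    inp <- out
    out <- matrix(numeric(0), 0L, 2L)
    np <- nrow(inp)
    s_prev <- side(inp[np, ])
    prev <- inp[np, ]
    for (j in seq_len(np)) {
      curr <- inp[j, ]; s_curr <- side(curr)
      if (s_curr >= 0) {
        if (s_prev < 0) {
          t <- s_prev / (s_prev - s_curr)
          out <- rbind(out, prev + t * (curr - prev))
        }
        out <- rbind(out, curr)
      } else if (s_prev >= 0) {
        t <- s_prev / (s_prev - s_curr)
        out <- rbind(out, prev + t * (curr - prev))
      }
      prev <- curr; s_prev <- s_curr
    }
  }
  out
}

polygon_area <- function(p) {
  if (nrow(p) < 3L) return(0)
  i2 <- c(seq_len(nrow(p))[-1L], 1L)
  abs(sum(p[, 1L] * p[i2, 2L] - p[i2, 1L] * p[, 2L])) / 2
}

#' Overlap area of two ellipses
#'
#' Numerical polygon intersection: each boundary is discretized into a
#' convex polygon and clipped (Sutherland-Hodgman); the overlap is the
#' shoelace area of the intersection.
#'
#' @param spec1,spec2 `ellipse_spec` objects.
#' @param n_vertices boundary discretization (default 720 gives
#'   relative error well below 1e-3).
#' @return nonnegative overlap area.
#' @export
ellipse_overlap <- function(spec1, spec2, n_vertices = 720L) {
  p1 <- ellipse_polygon(spec1, n_vertices)
  p2 <- ellipse_polygon(spec2, n_vertices)
  polygon_area(clip_convex(p1, p2))
}
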