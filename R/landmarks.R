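#' Landmark dataset constructor
#'
#' Bundles a specimen-by-landmark-by-2 coordinate array with specimen
#' metadata and per-landmark roles.  All specimens must share the same
#' landmarks in the same order; a landmark is either a true (homologous)
#' landmark or a semilandmark placed along an outline curve.
#'
#' @param coords numeric array `n x k x 2` (specimens, landmarks, x/y),
#'   or a list of `k x 2` matrices of equal dimension.
#' @param records data frame with at least a `specimen_id` column
#'   (unique); `species`, `site`, `sex`, `standard_length` are honoured
#'   when present.  Defaults to generated ids.
#' @param roles character vector of length `k`, values `"true"` or
#'   `"semi"`.  Defaults to all `"true"`.
#' @param scale_units free-text unit tag carried opaquely (e.g. `"mm"`).
#' @return object of class `landmark_set`.
#' @export
landmark_set <- function(coords, records = NULL, roles = NULL,
                         scale_units = "unknown") {
  if (is.list(coords) && !is.array(coords)) {
    k <- unique(vapply(coords, nrow, 1L))
    if (length(k) != 1L)
      stop("inconsistent landmark count across specimens: ",
           paste(sort(unique(vapply(coords, nrow, 1L))), collapse = ", "))
    coords <- aperm(simplify2array(coords), c(3L, 1L, 2L))
  }
  if (length(dim(coords)) != 3L || dim(coords)[3] != 2L)
    stop("coords must be an n x k x 2 array")
  n <- dim(coords)[1]; k <- dim(coords)[2]
  if (k < 3L) stop("at least 3 landmarks are required (k = ", k, ")")
  if (anyNA(coords)) stop("missing coordinates are not allowed")
  if (is.null(records))
    records <- data.frame(specimen_id = paste0("spec", seq_len(n)),
                          stringsAsFactors = FALSE)
  if (nrow(records) != n)
    stop("records has ", nrow(records), " rows for ", n, " specimens")
  if (anyDuplicated(records$specimen_id))
    stop("specimen_id values must be unique")
  if (!is.null(records$standard_length) &&
      any(records$standard_length <= 0, na.rm = TRUE))
    stop("standard_length must be positive")
  if (is.null(roles)) roles <- rep("true", k)
  roles <- match.arg(roles, c("true", "semi"), several.ok = TRUE)
  if (length(roles) != k) stop("roles must have length k = ", k)
  dimnames(coords) <- list(records$specimen_id, NULL, c("x", "y"))
  structure(list(coords = coords, records = records, roles = roles,
                 scale_units = scale_units),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("Landmark set:", dim(x$coords)[1], "specimens,",
      dim(x$coords)[2], "landmarks (",
      sum(x$roles == "true"), "true,", sum(x$roles == "semi"),
      "semilandmarks ), units:", x$scale_units, "\n")
  invisible(x)
}

n_specimens <- function(x) dim(x$coords)[1]
n_landmarks <- function(x) dim(x$coords)[2]

#' Subset a landmark set to a fixed set of landmarks
#'
#' Used e.g. to reduce a slid outline scheme to a small set of retained
#' semilandmarks, or to drop one member of each symmetric pair before a
#' distance-based test.  Coordinates and roles are subset in the order
#' given; specimen metadata is untouched.
#'
#' @param data a [landmark_set()].
#' @param keep integer vector of landmark indices to retain.
#' @return a `landmark_set` with `length(keep)` landmarks.
#' @export
prune_landmarks <- function(data, keep) {
  stopifnot(inherits(data, "landmark_set"))
  k <- n_landmarks(data)
  keep <- as.integer(keep)
  if (length(keep) == 0L) stop("keep must be non-empty")
  if (anyDuplicated(keep)) stop("keep contains duplicate indices")
  if (any(keep < 1L | keep > k))
    stop("landmark index out of range 1..", k, ": ",
         paste(keep[keep < 1L | keep > k], collapse = ", "))
  landmark_set(data$coords[, keep, , drop = FALSE], data$records,
               data$roles[keep], data$scale_units)
}

#' Centroid size of a landmark configuration
#'
#' The square root of the summed squared distances of the landmarks
#' from their centroid: the standard geometric-morphometric size
#' measure, invariant to translation and rotation and homogeneous of
#' degree one under isotropic scaling.
#'
#' @param config numeric `k x 2` matrix.
#' @return positive scalar.
#' @export
centroid_size <- function(config) {
  config <- as.matrix(config)
  if (nrow(config) < 3L) stop("need at least 3 landmarks")
  cen <- sweep(config, 2L, colMeans(config))
  cs <- sqrt(sum(cen^2))
  if (cs <= 0) stop("degenerate configuration: all landmarks coincide")
  cs
}
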