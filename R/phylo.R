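## Comparative methods on rooted branch-length trees (ape "phylo").

#' Prune a phylogeny to a set of taxa
#'
#' Induced subtree on `keep`: unifurcations are collapsed with branch
#' lengths merged additively, so root-to-tip path lengths of retained
#' taxa are preserved.
#'
#' @param tree an [ape::phylo] object with branch lengths.
#' @param keep tip labels to retain (must all exist).
#' @return the pruned `phylo` object.
#' @export
prune_to_taxa <- function(tree, keep) {
  validate_phylogeny(tree)
  missing <- setdiff(keep, tree$tip.label)
  if (length(missing))
    stop("unknown taxa: ", paste(missing, collapse = ", "))
  if (length(keep) < 2L) stop("keep at least 2 taxa")
  ape::keep.tip(tree, keep)
}

## Edge weights 1/length with zero lengths replaced by a small epsilon
## relative to tree height (kept finite; replacement is reported).
edge_weights <- function(tree) {
  len <- tree$edge.length
  height <- max(ape::node.depth.edgelength(tree))
  eps <- 1e-8 * if (height > 0) height else 1
  zero <- len <= 0
  if (any(zero)) {
    message(sum(zero), " zero-length branch(es) replaced by ",
            format(eps), " for weighting")
    len[zero] <- eps
  }
  1 / len
}

#' Weighted squared-change parsimony ancestral states
#'
#' Internal-node states minimizing the sum over edges of
#' `(state change)^2 / branch length` — squared change weighted by the
#' molecular change on each branch — solved independently per trait as
#' a linear system (the graph-Laplacian normal equations).  The
#' solution equals the Brownian-motion generalized-least-squares point
#' estimates of the ancestral states, is invariant to uniform
#' rescaling of all branch lengths, and every node state lies within
#' the range of the tip values of its trait.
#'
#' @param tree rooted [ape::phylo] with branch lengths; zero-length
#'   branches are handled by a small epsilon.
#' @param tip_values numeric vector or matrix (tips x traits) with
#'   names/rownames matching `tree$tip.label`.
#' @return object of class `ancestral_reconstruction`: `node_states`
#'   (internal nodes x traits, rownames are ape node numbers),
#'   `tip_values`, `objective` (the minimized weighted sum of squared
#'   changes per trait), `tree`.
#' @export
squared_change_parsimony <- function(tree, tip_values) {
  validate_phylogeny(tree)
  n <- length(tree$tip.label)
  if (is.null(dim(tip_values)))
    tip_values <- matrix(tip_values, ncol = 1L,
                         dimnames = list(names(tip_values), "trait"))
  if (is.null(rownames(tip_values)))
    stop("tip_values must be named by taxon")
  missing <- setdiff(tree$tip.label, rownames(tip_values))
  if (length(missing))
    stop("no trait values for tips: ", paste(missing, collapse = ", "))
  x_tip <- tip_values[tree$tip.label, , drop = FALSE]
  m <- tree$Nnode
  w <- edge_weights(tree)
  # Laplacian blocks: internal nodes are n+1 .. n+m
  A <- matrix(0, m, m)
  b <- matrix(0, m, ncol(x_tip))
  for (e in seq_len(nrow(tree$edge))) {
    u <- tree$edge[e, 1L]; v <- tree$edge[e, 2L]; we <- w[e]
    iu <- u - n  # parent is always internal
    A[iu, iu] <- A[iu, iu] + we
    if (v <= n) {
      b[iu, ] <- b[iu, ] + we * x_tip[v, ]
    } else {
      iv <- v - n
      A[iv, iv] <- A[iv, iv] + we
      A[iu, iv] <- A[iu, iv] - we
      A[iv, iu] <- A[iv, iu] - we
    }
  }
  states <- solve(A, b)
  rownames(states) <- as.character(n + seq_len(m))
  colnames(states) <- colnames(x_tip)
  all_states <- rbind(x_tip, states)
  obj <- vapply(seq_len(ncol(x_tip)), function(j) {
    dx <- all_states[tree$edge[, 1L], j] - all_states[tree$edge[, 2L], j]
    sum(w * dx^2)
  }, numeric(1L))
  structure(list(node_states = states, tip_values = x_tip,
                 objective = stats::setNames(obj, colnames(x_tip)),
                 tree = tree),
            class = "ancestral_reconstruction")
}

#' @export
print.ancestral_reconstruction <- function(x, ...) {
  cat("Ancestral reconstruction:", nrow(x$node_states), "internal nodes,",
      ncol(x$node_states), "trait(s)\n")
  invisible(x)
}

## Brownian-motion machinery shared by phenogram95: tip covariance,
## node-tip shared paths, GLS root and rate estimates.
bm_gls <- function(tree, x) {
  n <- length(tree$tip.label)
  C <- ape::vcv(tree)[tree$tip.label, tree$tip.label]
  x <- x[tree$tip.label]
  Cinv <- solve(C)
  one <- rep(1, n)
  mu <- drop(one %*% Cinv %*% x) / drop(one %*% Cinv %*% one)
  r <- x - mu
  q <- drop(r %*% Cinv %*% r)
  list(C = C, Cinv = Cinv, mu = mu,
       sigma2_ml = q / n, sigma2_reml = q / (n - 1))
}

#' Ancestral states with 95% intervals (phenogram data)
#'
#' For a single trait under Brownian motion: the BM rate `sigma2` is
#' estimated by restricted maximum likelihood (REML; `method = "ML"`
#' selectable), ancestral point estimates come from
#' [squared_change_parsimony()] (identical to the GLS estimates), and
#' per-node conditional variances come from the GLS formulation —
#' `sigma2 * (C_jj - c_j' C^-1 c_j + (1 - c_j' C^-1 1)^2 / (1' C^-1 1))`,
#' which accounts for the estimated root state.  The 95% interval is
#' the state +/- 1.96 standard deviations; plotted against node height
#' this is the 95 percent phenogram.
#'
#' @param tree rooted [ape::phylo] with branch lengths, > 2 tips.
#' @param tip_values named numeric vector (one trait).
#' @param method `"REML"` (default) or `"ML"` for the rate estimate.
#' @return data frame: node (ape number), height (distance from
#'   root), state, var, lo95, hi95; tips included with zero variance.
#'   The estimated `sigma2` is attached as an attribute.
#' @export
phenogram95 <- function(tree, tip_values, method = c("REML", "ML")) {
  method <- match.arg(method)
  validate_phylogeny(tree)
  if (!is.null(dim(tip_values))) stop("phenogram95 is univariate")
  n <- length(tree$tip.label)
  if (n <= 2L) stop("sigma2 is not estimable with <= 2 tips")
  scp <- squared_change_parsimony(tree, tip_values)
  g <- bm_gls(tree, tip_values)
  sigma2 <- if (method == "REML") g$sigma2_reml else g$sigma2_ml
  depths <- ape::node.depth.edgelength(tree)
  D <- ape::dist.nodes(tree)
  m <- tree$Nnode
  node_ids <- n + seq_len(m)
  one <- rep(1, n)
  s11 <- drop(one %*% g$Cinv %*% one)
  vars <- vapply(node_ids, function(j) {
    cj <- (depths[j] + depths[seq_len(n)] - D[j, seq_len(n)]) / 2
    cj <- cj[match(tree$tip.label, tree$tip.label)]
    h <- drop(g$Cinv %*% cj)
    max(0, depths[j] - sum(cj * h) + (1 - sum(h))^2 / s11)
  }, numeric(1L))
  out <- data.frame(
    node = c(seq_len(n), node_ids),
    label = c(tree$tip.label, rep(NA_character_, m)),
    height = depths[c(seq_len(n), node_ids)],
    state = c(unname(scp$tip_values[tree$tip.label, 1L]),
              unname(scp$node_states[, 1L])),
    var = c(rep(0, n), sigma2 * vars),
    stringsAsFactors = FALSE)
  out$lo95 <- out$state - 1.96 * sqrt(out$var)
  out$hi95 <- out$state + 1.96 * sqrt(out$var)
  attr(out, "sigma2") <- sigma2
  attr(out, "method") <- method
  out
}

#' Phylomorphospace projection
#'
#' Places internal nodes in a two-dimensional morphospace (e.g. the
#' first two PC scores of shape) by weighted squared-change parsimony
#' and reports tree edges as coordinate pairs for plotting the
#' phylogeny inside the ordination.
#'
#' @param tree rooted [ape::phylo] with branch lengths.
#' @param tip_scores `n x 2` matrix of tip coordinates, rownames
#'   matching tip labels.
#' @return list: `nodes` (data frame node/type/xy), `edges` (data
#'   frame with the two endpoint coordinates per tree edge).
#' @export
phylomorphospace <- function(tree, tip_scores) {
  tip_scores <- as.matrix(tip_scores)
  if (ncol(tip_scores) != 2L)
    stop("tip_scores must have exactly 2 columns")
  scp <- squared_change_parsimony(tree, tip_scores)
  n <- length(tree$tip.label)
  coords <- rbind(scp$tip_values[tree$tip.label, , drop = FALSE],
                  scp$node_states)
  nodes <- data.frame(
    node = seq_len(n + tree$Nnode),
    label = c(tree$tip.label, rep(NA_character_, tree$Nnode)),
    type = rep(c("tip", "internal"), c(n, tree$Nnode)),
    x = coords[, 1L], y = coords[, 2L],
    row.names = NULL, stringsAsFactors = FALSE)
  edges <- data.frame(
    parent = tree$edge[, 1L], child = tree$edge[, 2L],
    x0 = coords[tree$edge[, 1L], 1L], y0 = coords[tree$edge[, 1L], 2L],
    x1 = coords[tree$edge[, 2L], 1L], y1 = coords[tree$edge[, 2L], 2L])
  list(nodes = nodes, edges = edges)
}
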