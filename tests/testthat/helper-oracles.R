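## Independent oracles and small fixtures shared across tests.  Each
## oracle reimplements a quantity from first principles by a different
## route than the package code.

## Full Procrustes distance by brute force: both configurations reduced
## to preshapes, then the residual minimized over a fine rotation grid
## with the closed-form optimal scale per angle.
grid_procrustes_distance <- function(a, b, step = 1e-4) {
  pre <- function(x) {
    x <- sweep(x, 2L, colMeans(x))
    x / sqrt(sum(x^2))
  }
  a <- pre(as.matrix(a)); b <- pre(as.matrix(b))
  thetas <- seq(0, 2 * pi, by = step)
  best <- Inf
  for (th in thetas) {
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
    ip <- sum(a * (b %*% R))
    # optimal nonneg scale beta = max(ip, 0); residual = 1 - beta^2
    best <- min(best, 1 - max(ip, 0)^2)
  }
  sqrt(max(0, best))
}

## Bending energy matrix by a second route: pseudo-inverse of the
## kernel matrix projected orthogonally to the affine subspace
## (instead of the bordered-system inverse used by the package).
be_matrix_oracle <- function(reference) {
  reference <- as.matrix(reference)
  k <- nrow(reference)
  d <- as.matrix(dist(reference))
  K <- ifelse(d > 0, d^2 * log(d^2), 0)
  Q <- cbind(1, reference)
  P <- diag(k) - Q %*% solve(crossprod(Q), t(Q))
  MASS::ginv(P %*% K %*% P)
}

## Weighted squared-change objective evaluated from scratch
scp_objective <- function(tree, tip_vals, internal_states) {
  n <- length(tree$tip.label)
  all_states <- c(tip_vals[tree$tip.label], internal_states)
  len <- tree$edge.length
  len[len <= 0] <- 1e-8 * max(ape::node.depth.edgelength(tree))
  sum((all_states[tree$edge[, 1L]] - all_states[tree$edge[, 2L]])^2 / len)
}

## Numerically minimize the weighted squared-change objective
scp_numeric <- function(tree, tip_vals) {
  m <- tree$Nnode
  start <- rep(mean(tip_vals), m)
  fit <- optim(start, function(s) scp_objective(tree, tip_vals, s),
               method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  fit$par
}

## Random similarity transform of one k x 2 configuration
random_similarity <- function(config) {
  th <- runif(1L, 0, 2 * pi)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
  s <- runif(1L, 0.2, 5)
  tr <- runif(2L, -50, 50)
  sweep(config %*% R * s, 2L, tr, `+`)
}

## Fixed non-degenerate triangle pair used by several distance tests
triangle_a <- matrix(c(0, 0, 1, 0, 0.4, 0.9), ncol = 2L, byrow = TRUE)
triangle_b <- matrix(c(0, 0, 1, 0.1, 0.2, 1.1), ncol = 2L, byrow = TRUE)

## Small landmark set of perturbed fish shapes, built in code
make_fish_set <- function(n = 8L, noise = 0.01, seed = 42L) {
  set.seed(seed)
  tpl <- fish_template()
  configs <- lapply(seq_len(n), function(i)
    random_similarity(tpl + matrix(rnorm(32L, sd = noise), 16L, 2L)))
  landmark_set(configs)
}
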