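# Shared fixtures and independent oracles used across the test files.

# small, fast scenario used by most generator tests
small_scenario <- function(..., seed = 101) {
  leaf_scenario(nx = 15, ny = 15, n_species = 120, seed = seed, ...)
}

# independent oracle for hierarchical partitioning: average the marginal
# R^2 contribution of each predictor over all k! orderings (Shapley/LMG
# form), with every subset R^2 taken from plain lm() fits.
oracle_shapley_r2 <- function(y, X) {
  X <- as.matrix(X)
  k <- ncol(X)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  r2 <- function(cols) {
    if (!length(cols)) return(0)
    summary(lm(y ~ X[, cols, drop = FALSE]))$r.squared
  }
  I <- numeric(k)
  pp <- perms(seq_len(k))
  for (p in pp) {
    sofar <- integer(0)
    for (i in p) {
      I[i] <- I[i] + r2(c(sofar, i)) - r2(sofar)
      sofar <- c(sofar, i)
    }
  }
  I / length(pp)
}

# centred, exactly orthogonal predictor columns (for partition limit cases)
orthogonal_design <- function(n, k, seed = 1) {
  set.seed(seed)
  M <- matrix(rnorm(n * k), n, k)
  M <- scale(M, center = TRUE, scale = FALSE)
  Q <- qr.Q(qr(M))
  scale(Q, center = TRUE, scale = FALSE)
}

# cheap GRF pair simulator for null-calibration loops: one Cholesky factor
# shared across draws
grf_pair_factory <- function(n_side, range_cells) {
  xy <- as.matrix(expand.grid(x = seq_len(n_side), y = seq_len(n_side)))
  D <- as.matrix(dist(xy))
  L <- chol(exp(-D / range_cells) + diag(1e-8, nrow(D)))
  list(coords = xy,
       draw = function() drop(crossprod(L, rnorm(nrow(xy)))))
}

# star phylogeny with unit branch lengths (V = I)
star_tree <- function(n) {
  tr <- ape::stree(n)
  tr$edge.length <- rep(1, nrow(tr$edge))
  tr$tip.label <- paste0("t", seq_len(n))
  tr
}

expect_rel_equal <- function(actual, expected, rel_tol) {
  expect_lt(max(abs(actual - expected) / abs(expected)), rel_tol)
}
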