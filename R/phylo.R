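# Phylogenetic covariance (shared path length to root) with a small ridge
# on zero-length terminal branches so V stays invertible.
phylo_vcv <- function(tree, eps = 1e-8) {
  V <- ape::vcv(tree)
  if (any(diag(V) <= 0)) diag(V) <- diag(V) + eps
  V
}

blomberg_k_stat <- function(V, y) {
  n <- length(y)
  Vi <- solve(V)
  sum_vi <- sum(Vi)
  w <- colSums(Vi)
  ahat <- sum(w * y) / sum_vi
  d <- y - ahat
  mse0 <- sum(d^2) / (n - 1)
  mse <- drop(crossprod(d, Vi %*% d)) / (n - 1)
  expected <- (sum(diag(V)) - n / sum_vi) / (n - 1)
  list(K = (mse0 / mse) / expected, mse0 = mse0, mse = mse,
       expected_ratio = expected, Vi = Vi, w = w, sum_vi = sum_vi)
}

#' Blomberg's K phylogenetic signal statistic
#'
#' K is the ratio of the observed MSE0/MSE partitioning of trait variance
#' on the tree to its Brownian-motion expectation:
#' MSE0 = sum((y - a)^2)/(n-1) with a the GLS phylogenetic mean,
#' MSE = (y - a)' V^-1 (y - a)/(n-1), and the expectation term
#' (tr(V) - n / sum(V^-1)) / (n - 1). K = 1 is the Brownian expectation;
#' K near 0 indicates phylogenetically random traits. K is invariant to
#' affine trait transforms and to tip relabelling. On a star phylogeny
#' (V = I) K equals 1 exactly for any trait.
#'
#' @param tree ape "phylo" object; tips are matched to `names(trait)` and
#'   mismatches pruned (with counts recorded).
#' @param trait named numeric vector of tip values (>= 3 matched tips).
#' @param eps ridge added to zero diagonal entries of V.
#' @return object of class `phylo_signal`: K, mse0, mse, expected ratio,
#'   n, n_pruned.
#' @export
blomberg_k <- function(tree, trait, eps = 1e-8) {
  if (is.null(names(trait))) {
    if (length(trait) != length(tree$tip.label))
      stop("unnamed trait vector must match the number of tips")
    names(trait) <- tree$tip.label
  }
  common <- intersect(tree$tip.label, names(trait))
  n_pruned <- length(tree$tip.label) - length(common) +
    sum(!names(trait) %in% tree$tip.label)
  if (length(common) < 3L) stop("need >= 3 matched taxa")
  if (length(common) < length(tree$tip.label))
    tree <- ape::drop.tip(tree, setdiff(tree$tip.label, common))
  y <- trait[tree$tip.label]
  V <- phylo_vcv(tree, eps)
  st <- blomberg_k_stat(V, y)
  structure(list(K = st$K, mse0 = st$mse0, mse = st$mse,
                 expected_ratio = st$expected_ratio,
                 n = length(y), n_pruned = n_pruned),
            class = "phylo_signal")
}

#' Permutation test for Blomberg's K
#'
#' The null distribution is generated by shuffling trait values across tips
#' (destroying any phylogenetic structure while keeping the trait
#' distribution); p = (1 + #\{K_perm >= K_obs\}) / (n_perm + 1). Permuted
#' statistics are computed with vectorised quadratic forms, so the default
#' 999 permutations are cheap.
#'
#' @inheritParams blomberg_k
#' @param n_perm number of permutations (>= 99 recommended; fewer warns).
#' @param seed integer seed for the permutations.
#' @return a `phylo_signal` with p-value, n_perm and seed fields added.
#' @export
blomberg_k_test <- function(tree, trait, n_perm = 999, seed = 1L,
                            eps = 1e-8) {
  if (n_perm < 99) warning("n_perm < 99 gives a coarse p-value")
  if (is.null(names(trait))) {
    if (length(trait) != length(tree$tip.label))
      stop("unnamed trait vector must match the number of tips")
    names(trait) <- tree$tip.label
  }
  common <- intersect(tree$tip.label, names(trait))
  if (length(common) < 3L) stop("need >= 3 matched taxa")
  if (length(common) < length(tree$tip.label))
    tree <- ape::drop.tip(tree, setdiff(tree$tip.label, common))
  y <- trait[tree$tip.label]
  n <- length(y)
  V <- phylo_vcv(tree, eps)
  st <- blomberg_k_stat(V, y)

  set.seed(seed)
  P <- replicate(n_perm, sample(y))            # n x n_perm
  A <- st$w %*% P / st$sum_vi                  # GLS means, 1 x n_perm
  D <- sweep(P, 2, A)                          # residuals about GLS mean
  mse0 <- colSums(D^2) / (n - 1)
  mse <- colSums(D * (st$Vi %*% D)) / (n - 1)
  K_perm <- (mse0 / mse) / st$expected_ratio
  p <- (1 + sum(K_perm >= st$K)) / (n_perm + 1)

  structure(list(K = st$K, mse0 = st$mse0, mse = st$mse,
                 expected_ratio = st$expected_ratio, n = n,
                 p = p, n_perm = n_perm, seed = seed),
            class = "phylo_signal")
}

#' @export
print.phylo_signal <- function(x, ...) {
  cat(sprintf("Blomberg's K = %.4f (n = %d)%s\n", x$K, x$n,
              if (!is.null(x$p))
                sprintf(", permutation p = %.4g (%d perms)", x$p, x$n_perm)
              else ""))
  invisible(x)
}

#' Mean clade age of the species present in each grid cell
#'
#' Unweighted mean over the species present of their clade's (family or
#' genus) stem age: each species contributes its clade's age, so three
#' congeners of a 40-Myr genus contribute 40 three times. Species without
#' a mapped, aged clade are excluded and counted.
#'
#' @param presence a `presence_matrix`.
#' @param clade_map data.frame (species, clade).
#' @param ages data.frame (clade, age) in Myr.
#' @return data.frame (cell_id, mean_clade_age, n_aged); empty cells get
#'   NA. `attr(, "n_unmapped")` counts species without a usable age.
#' @export
cell_mean_clade_age <- function(presence, clade_map, ages) {
  if (any(ages$age <= 0)) stop("clade ages must be > 0")
  sp <- colnames(presence)
  clade <- clade_map$clade[match(sp, clade_map$species)]
  age <- ages$age[match(clade, ages$clade)]
  usable <- !is.na(age)
  pm <- presence[, usable, drop = FALSE]
  a <- age[usable]
  n_aged <- as.integer(pm %*% rep(1, length(a)))
  total <- as.numeric(pm %*% a)
  out <- data.frame(cell_id = as.integer(rownames(presence)),
                    mean_clade_age = ifelse(n_aged > 0,
                                            total / pmax(n_aged, 1L),
                                            NA_real_),
                    n_aged = n_aged)
  attr(out, "n_unmapped") <- sum(!usable)
  out
}

#' Clade-age x leaf-size interaction on productivity
#'
#' OLS of productivity on standardised leaf size, standardised mean clade
#' age and their interaction (the product of the z-scores). The sign and
#' significance of the interaction coefficient measure whether older
#' assemblages show weaker leaf size-productivity coupling.
#'
#' @param productivity response (GPP or NPP per cell).
#' @param leaf_size community mean leaf size per cell.
#' @param clade_age mean clade age per cell (Myr).
#' @return list: `coefficients` (data.frame term, estimate, se, t, p) and
#'   the model R^2.
#' @export
age_interaction_model <- function(productivity, leaf_size, clade_age) {
  ok <- stats::complete.cases(productivity, leaf_size, clade_age)
  y <- productivity[ok]
  if (sd(leaf_size[ok]) == 0 || sd(clade_age[ok]) == 0)
    stop("zero-variance predictor")
  zl <- as.numeric(scale(leaf_size[ok]))
  za <- as.numeric(scale(clade_age[ok]))
  X <- cbind(leaf_size = zl, clade_age = za, interaction = zl * za)
  if (kappa(cbind(1, X)) > 1e6) stop("predictors too collinear")
  fit <- lm(y ~ X)
  cf <- summary(fit)$coefficients
  rownames(cf) <- sub("^X", "", rownames(cf))
  list(coefficients = data.frame(term = rownames(cf),
                                 estimate = cf[, 1], se = cf[, 2],
                                 t = cf[, 3], p = cf[, 4],
                                 row.names = NULL),
       r2 = summary(fit)$r.squared, n = length(y))
}
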