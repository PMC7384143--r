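# -- Dutilleul's modified t-test -------------------------------------------

#' Estimate spatial correlation matrices for two surfaces
#'
#' Pairwise distances are binned into equal-width distance classes (default
#' count: Sturges' rule on the number of pairs); for each variable a
#' Moran-type autocorrelation is estimated per class, and the n x n
#' correlation matrix is filled by class membership with unit diagonal.
#' Negative class estimates are retained. Classes with no pairs are merged
#' with their lower neighbour.
#'
#' @param values_a,values_b the two surfaces (same cells).
#' @param coords two-column matrix/data.frame of cell coordinates.
#' @param n_classes number of distance classes; NULL for Sturges' rule.
#' @return object of class `spatial_covariance`: Sigma_a, Sigma_b, breaks,
#'   per-class autocorrelation estimates.
#' @export
estimate_spatial_covariance <- function(values_a, values_b, coords,
                                        n_classes = NULL) {
  coords <- as.matrix(coords)
  n <- length(values_a)
  stopifnot(length(values_b) == n, nrow(coords) == n, n >= 10L)
  if (anyDuplicated(coords)) stop("coordinates must be distinct")
  if (var(values_a) == 0 || var(values_b) == 0)
    stop("constant surface; spatial correlation undefined")

  D <- as.matrix(stats::dist(coords))
  ut <- upper.tri(D)
  dv <- D[ut]
  if (is.null(n_classes)) n_classes <- ceiling(log2(length(dv)) + 1)
  if (n_classes < 1L) stop("n_classes must be >= 1")
  breaks <- seq(0, max(dv) * (1 + 1e-9), length.out = n_classes + 1)
  cls <- cut(dv, breaks, include.lowest = TRUE, labels = FALSE)

  class_corr <- function(z) {
    zc <- z - mean(z)
    prods <- tcrossprod(zc)[ut] / mean(zc^2)
    as.numeric(tapply(prods, cls, mean))
  }
  ra <- class_corr(values_a)
  rb <- class_corr(values_b)

  # merge empty classes into the nearest populated lower class
  present <- sort(unique(cls))
  n_merged <- n_classes - length(present)
  fill <- function(r) {
    out <- rep(NA_real_, n_classes)
    out[present] <- r[!is.na(r)]
    for (k in seq_len(n_classes))
      if (is.na(out[k])) out[k] <- out[max(which(!is.na(out[seq_len(k)])))]
    out
  }
  ra <- fill(ra); rb <- fill(rb)

  build <- function(r) {
    S <- diag(n)
    S[ut] <- r[cls]
    S[lower.tri(S)] <- t(S)[lower.tri(S)]
    S
  }
  structure(list(Sigma_a = build(ra), Sigma_b = build(rb),
                 breaks = breaks, class_autocorr = cbind(a = ra, b = rb),
                 n_merged = n_merged),
            class = "spatial_covariance")
}

#' Dutilleul's modified t-test for the correlation of two surfaces
#'
#' Tests the Pearson correlation between two spatially autocorrelated
#' surfaces with an effective sample size
#' M = 1 + tr(B Sa) tr(B Sb) / tr(B Sa B Sb), where B = I - 11'/n is the
#' centering matrix and Sa, Sb the estimated spatial correlation matrices.
#' The corrected statistic is t = r sqrt((M - 2)/(1 - r^2)) on M - 2
#' degrees of freedom. With identity correlation matrices the classical
#' test (M = n) is recovered exactly. M is clamped to (2, n]; if clamping
#' to the floor occurs, p is reported as 1 and flagged.
#'
#' @param values_a,values_b the two surfaces.
#' @param coords cell coordinates (ignored when `spcov` is given).
#' @param spcov optional precomputed [estimate_spatial_covariance()].
#' @param n_classes passed to the covariance estimator.
#' @return object of class `modified_t_test`: r, M_hat, df, t, p,
#'   clamped flag.
#' @export
modified_t_test <- function(values_a, values_b, coords = NULL, spcov = NULL,
                            n_classes = NULL) {
  n <- length(values_a)
  stopifnot(length(values_b) == n)
  if (is.null(spcov)) {
    if (is.null(coords)) stop("either coords or spcov is required")
    spcov <- estimate_spatial_covariance(values_a, values_b, coords,
                                         n_classes)
  }
  Sa <- spcov$Sigma_a; Sb <- spcov$Sigma_b

  # traces with the centering matrix via double centering (B idempotent):
  # tr(B S) = tr(S) - n * mean(S); tr(B Sa B Sb) = sum((B Sa B) * Sb)
  tr_bs <- function(S) sum(diag(S)) - n * mean(S)
  ca <- colMeans(Sa); ma <- mean(Sa)
  BSaB <- Sa - matrix(ca, n, n) - matrix(ca, n, n, byrow = TRUE) + ma
  denom <- sum(BSaB * Sb)
  M_hat <- 1 + tr_bs(Sa) * tr_bs(Sb) / denom

  clamped <- FALSE
  if (!is.finite(M_hat) || M_hat <= 2) {
    M_hat <- 2; clamped <- TRUE
  } else if (M_hat > n) {
    M_hat <- n; clamped <- TRUE
  }
  r <- cor(values_a, values_b)
  if (M_hat <= 2) {
    t <- NA_real_; p <- 1
  } else {
    t <- r * sqrt((M_hat - 2) / (1 - r^2))
    p <- 2 * pt(-abs(t), df = M_hat - 2)
  }
  structure(list(r = r, M_hat = M_hat, df = M_hat - 2, t = t, p = p,
                 clamped = clamped, n = n),
            class = "modified_t_test")
}

#' @export
print.modified_t_test <- function(x, ...) {
  cat(sprintf(
    "modified t-test: r = %.4f, M = %.2f (n = %d), t = %.3f, p = %.4g%s\n",
    x$r, x$M_hat, x$n, x$t, x$p, if (x$clamped) " [clamped]" else ""))
  invisible(x)
}

# -- R^2 partitioning -------------------------------------------------------

# OLS R^2 of y on the predictor columns in `cols` (integer indices into X);
# empty set -> 0.  Errors on rank deficiency, naming the subset.
subset_r2 <- function(y, X, cols, allow_singular = FALSE) {
  if (!length(cols)) return(0)
  Xs <- cbind(1, X[, cols, drop = FALSE])
  q <- qr(Xs)
  if (!allow_singular && q$rank < ncol(Xs))
    stop("singular fit for predictor subset {",
         paste(colnames(X)[cols], collapse = ", "), "}")
  res <- qr.resid(q, y)
  1 - sum(res^2) / sum((y - mean(y))^2)
}

#' Hierarchical partitioning of R-squared
#'
#' Fits all 2^k - 1 subset OLS models and decomposes the full-model R^2
#' into per-predictor independent effects I_i (the average over hierarchy
#' levels of the mean R^2 increment from adding predictor i to subsets that
#' exclude it) and joint effects J_i = R^2({i}) - I_i. The independent
#' effects sum exactly to the full-model R^2.
#'
#' @param y response.
#' @param X matrix or data.frame of k <= 8 predictors.
#' @return object of class `hier_partition`: data.frame of I, J and
#'   marginal R^2 per predictor, the full-model R^2, and the subset-R^2
#'   ledger (one row per non-empty subset).
#' @export
hierarchical_partition <- function(y, X) {
  X <- as.matrix(X)
  k <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(k))
  if (k < 1L) stop("need at least one predictor")
  if (k > 8L) stop("hierarchical partitioning limited to k <= 8 predictors")
  if (nrow(X) <= k + 2L) stop("need n > k + 2 observations")

  nsub <- 2^k
  r2 <- numeric(nsub)                    # indexed by bitmask + 1
  for (m in seq_len(nsub - 1L)) {
    cols <- which(bitwAnd(m, 2^(seq_len(k) - 1L)) > 0)
    r2[m + 1L] <- subset_r2(y, X, cols)
  }

  I <- numeric(k)
  for (i in seq_len(k)) {
    bit <- 2^(i - 1L)
    others <- setdiff(seq_len(k), i)
    # average increments within each level, then across the k levels
    lev_sum <- numeric(k)   # level = |S| + 1 where S excludes i
    lev_cnt <- numeric(k)
    masks_wo_i <- which(bitwAnd(seq_len(nsub) - 1L, bit) == 0) - 1L
    for (m in masks_wo_i) {
      s <- sum(bitwAnd(m, 2^(seq_len(k) - 1L)) > 0)
      inc <- r2[m + bit + 1L] - r2[m + 1L]
      lev_sum[s + 1L] <- lev_sum[s + 1L] + inc
      lev_cnt[s + 1L] <- lev_cnt[s + 1L] + 1
    }
    I[i] <- mean(lev_sum[lev_cnt > 0] / lev_cnt[lev_cnt > 0])
  }
  marg <- r2[2^(seq_len(k) - 1L) + 1L]
  ledger <- data.frame(
    mask = seq_len(nsub - 1L),
    subset = vapply(seq_len(nsub - 1L), function(m)
      paste(colnames(X)[which(bitwAnd(m, 2^(seq_len(k) - 1L)) > 0)],
            collapse = "+"), character(1)),
    r2 = r2[-1L])
  structure(list(
    effects = data.frame(predictor = colnames(X), independent = I,
                         joint = marg - I, marginal_r2 = marg),
    full_r2 = r2[nsub], ledger = ledger, k = k),
    class = "hier_partition")
}

#' Three-way commonality (Venn) partition of R-squared
#'
#' Decomposes the three-predictor OLS R^2 into unique, pairwise-common and
#' three-way-common components from the seven subset R^2 values
#' (inclusion-exclusion). Components can be negative (suppression) and are
#' reported as-is; the seven components sum exactly to the full R^2.
#'
#' @param y response.
#' @param A,B,C the three predictors.
#' @param names optional predictor names (for labelling).
#' @return object of class `venn_partition3`: named component vector
#'   (unique_A, unique_B, unique_C, common_AB, common_AC, common_BC,
#'   common_ABC), the full R^2 and the subset ledger.
#' @export
venn_partition3 <- function(y, A, B, C, names = c("A", "B", "C")) {
  X <- cbind(A = A, B = B, C = C)
  r2 <- function(cols) subset_r2(y, X, cols, allow_singular = TRUE)
  rA <- r2(1); rB <- r2(2); rC <- r2(3)
  rAB <- r2(c(1, 2)); rAC <- r2(c(1, 3)); rBC <- r2(c(2, 3))
  rABC <- r2(1:3)
  comp <- c(
    unique_A = rABC - rBC,
    unique_B = rABC - rAC,
    unique_C = rABC - rAB,
    common_AB = rAC + rBC - rC - rABC,
    common_AC = rAB + rBC - rB - rABC,
    common_BC = rAB + rAC - rA - rABC,
    common_ABC = rA + rB + rC - rAB - rAC - rBC + rABC)
  structure(list(components = comp, full_r2 = rABC,
                 subset_r2 = c(A = rA, B = rB, C = rC, AB = rAB, AC = rAC,
                               BC = rBC, ABC = rABC),
                 names = names),
            class = "venn_partition3")
}

# -- soil composite ---------------------------------------------------------

#' First principal component of the three soil variables
#'
#' Standardises soil pH, organic carbon and cation exchange capacity to
#' z-scores and returns the leading principal-component scores with the
#' sign convention that the organic-carbon loading is non-negative.
#'
#' @param ph,organic_carbon,cation_exchange the three soil variables.
#' @return list: `scores` (PC1 per row), `variance_fraction`, `loadings`.
#' @export
soil_pca <- function(ph, organic_carbon, cation_exchange) {
  M <- cbind(ph = ph, oc = organic_carbon, cec = cation_exchange)
  M <- M[stats::complete.cases(M), , drop = FALSE]
  if (nrow(M) < 3L) stop("need at least 3 complete rows")
  if (any(apply(M, 2, sd) == 0)) stop("zero-variance soil column")
  pc <- prcomp(M, center = TRUE, scale. = TRUE)
  load1 <- pc$rotation[, 1]
  sgn <- if (load1[["oc"]] < 0) -1 else 1
  list(scores = sgn * pc$x[, 1],
       variance_fraction = pc$sdev[1]^2 / sum(pc$sdev^2),
       loadings = sgn * load1)
}
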