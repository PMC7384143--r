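#' Specify a piecewise structural equation model
#'
#' A piecewise SEM is a directed acyclic graph whose endogenous nodes are
#' each fitted by a separate component regression on their parents. The
#' spec records the edge list and optional response transforms (applied
#' before standardisation), e.g. square-root transforms of GPP/NPP.
#'
#' @param edges data.frame with columns `from` and `to`.
#' @param transforms named list mapping variable names to transform names
#'   ("sqrt" or "log") applied before z-standardisation.
#' @return object of class `sem_spec` with a topological node order.
#' @export
sem_spec <- function(edges, transforms = list()) {
  stopifnot(all(c("from", "to") %in% names(edges)))
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  nodes <- unique(c(edges$from, edges$to))

  # Kahn's algorithm: detect cycles and get a topological order
  order <- character(0)
  indeg <- vapply(nodes, function(v) sum(edges$to == v), integer(1))
  avail <- nodes[indeg == 0]
  rem <- edges
  while (length(avail)) {
    v <- avail[1]; avail <- avail[-1]
    order <- c(order, v)
    out <- rem$from == v
    for (w in rem$to[out]) {
      if (sum(rem$to == w & !out) == 0) avail <- c(avail, w)
    }
    rem <- rem[!out, , drop = FALSE]
  }
  if (nrow(rem) > 0) stop("SEM specification contains a cycle")
  structure(list(edges = edges, nodes = nodes, order = order,
                 transforms = transforms),
            class = "sem_spec")
}

#' Fit a piecewise structural equation model
#'
#' Applies the spec's transforms, z-standardises every variable, then fits
#' each endogenous node by OLS on its parents. On standardised data with a
#' single parent the path coefficient equals the Pearson correlation.
#' p-values are classical OLS t-tests.
#'
#' @param spec a [sem_spec()].
#' @param data data.frame containing every spec variable (complete cases
#'   used).
#' @return object of class `sem_fit`: `paths` (from, to, coefficient, se,
#'   p), `component_r2` per endogenous node, n.
#' @export
fit_piecewise_sem <- function(spec, data) {
  stopifnot(inherits(spec, "sem_spec"))
  miss <- setdiff(spec$nodes, names(data))
  if (length(miss)) stop("data lacks variables: ", paste(miss, collapse = ", "))
  d <- data[, spec$nodes, drop = FALSE]
  d <- d[stats::complete.cases(d), , drop = FALSE]
  for (v in names(spec$transforms)) {
    f <- switch(spec$transforms[[v]], sqrt = sqrt, log = log,
                stop("unknown transform: ", spec$transforms[[v]]))
    d[[v]] <- f(d[[v]])
  }
  for (v in spec$nodes) {
    if (sd(d[[v]]) == 0) stop("zero-variance SEM node: ", v)
    d[[v]] <- as.numeric(scale(d[[v]]))
  }

  endo <- unique(spec$edges$to)
  paths <- list(); r2 <- setNames(numeric(length(endo)), endo)
  for (v in endo) {
    parents <- spec$edges$from[spec$edges$to == v]
    X <- as.matrix(d[, parents, drop = FALSE])
    q <- qr(cbind(1, X))
    if (q$rank < ncol(X) + 1L) stop("singular component regression for ", v)
    fit <- lm(d[[v]] ~ X)
    cf <- summary(fit)$coefficients
    paths[[v]] <- data.frame(from = parents, to = v,
                             coefficient = cf[-1, 1], se = cf[-1, 2],
                             p = cf[-1, 4], row.names = NULL)
    r2[v] <- summary(fit)$r.squared
  }
  structure(list(paths = do.call(rbind, paths), component_r2 = r2,
                 spec = spec, n = nrow(d)),
            class = "sem_fit")
}

# all directed paths from `from` to `to` in the edge list (DFS)
enumerate_paths <- function(edges, from, to) {
  out <- list()
  walk <- function(v, path) {
    if (v == to && length(path) > 1) {
      out[[length(out) + 1L]] <<- path
      return(invisible())
    }
    for (w in edges$to[edges$from == v]) {
      if (!w %in% path) walk(w, c(path, w))
    }
  }
  walk(from, from)
  out
}

#' Direct, indirect and total effects from a fitted piecewise SEM
#'
#' The direct effect of a source on a sink is the coefficient of the edge
#' between them (0 when absent); the indirect effect is the sum over all
#' directed paths of length >= 2 of the product of edge coefficients; the
#' total effect is their sum. Exact path-product arithmetic given the
#' fitted coefficients.
#'
#' @param fit a `sem_fit`.
#' @return data.frame (from, to, direct, indirect, total) for every ordered
#'   pair connected by at least one directed path.
#' @export
effects_decomposition <- function(fit) {
  stopifnot(inherits(fit, "sem_fit"))
  ed <- fit$paths
  coef_of <- function(a, b) {
    i <- which(ed$from == a & ed$to == b)
    if (length(i)) ed$coefficient[i] else 0
  }
  nodes <- fit$spec$nodes
  rows <- list()
  for (a in nodes) for (b in setdiff(nodes, a)) {
    paths <- enumerate_paths(ed, a, b)
    if (!length(paths)) next
    direct <- coef_of(a, b)
    indirect <- 0
    for (p in paths) {
      if (length(p) == 2L) next
      pr <- 1
      for (s in seq_len(length(p) - 1L)) pr <- pr * coef_of(p[s], p[s + 1L])
      indirect <- indirect + pr
    }
    rows[[paste(a, b)]] <- data.frame(from = a, to = b, direct = direct,
                                      indirect = indirect,
                                      total = direct + indirect)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.sem_fit <- function(x, ...) {
  cat("piecewise SEM (n =", x$n, ")\n")
  print(x$paths, digits = 3)
  invisible(x)
}
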