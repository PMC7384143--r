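#' Fit a leaf-size to productivity transfer function
#'
#' The central form is the inverse logistic
#' y = (1/r) (alpha - ln(K/x - 1)), x < K. Given K the model is linear in
#' (alpha/r, 1/r), so it is fitted by profiling: a one-dimensional
#' least-squares search over K (bounded below by max(x) (1 + 1e-6) so the
#' log stays defined) with an exact inner OLS. If the profile optimum
#' pushes K against its lower bound, the largest-trait cell is excluded and
#' the model refitted (at most `max_rounds` rounds), mirroring the
#' different usable-cell counts of transfer-function tables; cells with
#' x <= 0 are excluded up front and counted. Linear and sqrt-linear forms
#' delegate to [fit_model()].
#'
#' @param x community mean leaf size (cm or cm^2).
#' @param y productivity (gC m-2 yr-1).
#' @param form "inv_logistic", "linear" or "sqrt_linear".
#' @param trait,productivity,region optional labels stored in the model.
#' @param k_upper_mult upper K search bound as a multiple of max(x).
#' @param max_rounds maximum boundary-exclusion refit rounds.
#' @return object of class `transfer_model`: form, params, r2, n,
#'   n_excluded, labels.
#' @export
fit_transfer <- function(x, y, form = c("inv_logistic", "linear",
                                        "sqrt_linear"),
                         trait = NA_character_,
                         productivity = NA_character_,
                         region = NA_character_,
                         k_upper_mult = 20, max_rounds = 5) {
  form <- match.arg(form)
  ok <- is.finite(x) & is.finite(y)
  n_nonfinite <- sum(!ok)
  x <- x[ok]; y <- y[ok]

  if (form != "inv_logistic") {
    fit <- fit_model(x, y, family = if (form == "linear") "linear"
                     else "sqrt_linear")
    out <- list(form = form, params = fit$params, r2 = fit$r2, n = fit$n,
                n_excluded = n_nonfinite, trait = trait,
                productivity = productivity, region = region,
                transform = fit$transform)
    class(out) <- "transfer_model"
    return(out)
  }

  pos <- x > 0
  n_excluded <- n_nonfinite + sum(!pos)
  x <- x[pos]; y <- y[pos]
  if (length(x) < 10L) stop("fewer than 10 usable cells")

  profile_fit <- function(x, y) {
    lo <- max(x) * (1 + 1e-6)
    hi <- max(x) * k_upper_mult
    sse_at <- function(K) {
      z <- log(K / x - 1)
      f <- lm.fit(cbind(1, z), y)
      sum(f$residuals^2)
    }
    opt <- optimize(sse_at, c(lo, hi), tol = 1e-9)
    K <- opt$minimum
    z <- log(K / x - 1)
    f <- lm.fit(cbind(1, z), y)
    co <- f$coefficients                 # y = alpha/r - (1/r) z
    r <- -1 / co[2]
    alpha <- co[1] * r
    list(K = K, alpha = unname(alpha), r = unname(r),
         sse = sum(f$residuals^2), at_lower = (K - lo) < 1e-6 * lo)
  }

  rounds <- 0
  repeat {
    pf <- profile_fit(x, y)
    if (!pf$at_lower || rounds >= max_rounds || length(x) <= 10L) break
    drop <- which.max(x)                 # boundary solution: shed largest x
    x <- x[-drop]; y <- y[-drop]
    n_excluded <- n_excluded + 1L
    rounds <- rounds + 1
  }
  if (pf$r <= 0)
    stop("inverse-logistic fit degenerate: non-positive rate r")
  params <- logistic_params(pf$K, pf$alpha, pf$r)
  yhat <- inv_logistic_eval(x, params)
  out <- list(form = "inv_logistic", params = params,
              r2 = r_squared(y, yhat), n = length(x),
              n_excluded = n_excluded, trait = trait,
              productivity = productivity, region = region,
              sse = pf$sse)
  class(out) <- "transfer_model"
  out
}

#' Predict productivity from a transfer model
#'
#' For the inverse-logistic form, predictions are defined only on
#' 0 < x < K; out-of-domain values yield NA (never silent extrapolation or
#' clamping to the asymptote) and are counted in `attr(, "n_out_of_domain")`
#' with a warning.
#'
#' @param model a `transfer_model`.
#' @param x new trait values.
#' @return predicted productivity, NA where out of domain.
#' @export
predict_transfer <- function(model, x) {
  if (model$form == "inv_logistic") {
    p <- model$params
    okx <- is.finite(x) & x > 0 & x < p$K
    out <- rep(NA_real_, length(x))
    out[okx] <- inv_logistic_eval(x[okx], p)
    n_out <- sum(!okx)
    if (n_out > 0)
      warning(n_out, " trait values outside (0, K); returned NA")
    attr(out, "n_out_of_domain") <- n_out
    return(out)
  }
  fake <- list(family = if (model$form == "linear") "linear"
               else "sqrt_linear", params = model$params)
  predict_model(structure(fake, class = "leaf_model_fit"), x)
}

#' Evaluate transfer-function predictions
#'
#' Computes the standard error of estimate
#' SE = sqrt(sum((y_est - y_real)^2) / (n - 1)), its percentage of the
#' observed range SE% = 100 SE / (max(y_real) - min(y_real)), R^2, and the
#' slope/intercept of the OLS regression of observed on predicted values
#' (for comparison with the 1:1 line). Pairs with a missing prediction are
#' dropped and counted.
#'
#' @param y_est predicted productivity.
#' @param y_real observed productivity.
#' @return object of class `transfer_evaluation`: se, se_pct, r2, n,
#'   slope, intercept, n_dropped.
#' @export
evaluate_transfer <- function(y_est, y_real) {
  stopifnot(length(y_est) == length(y_real))
  ok <- is.finite(y_est) & is.finite(y_real)
  y_est <- y_est[ok]; y_real <- y_real[ok]
  n <- length(y_real)
  if (n < 2L) stop("need at least 2 usable prediction pairs")
  se <- sqrt(sum((y_est - y_real)^2) / (n - 1))
  rng <- diff(range(y_real))
  se_pct <- if (rng > 0) 100 * se / rng else {
    warning("zero observed range; SE%% undefined")
    NA_real_
  }
  fit <- lm(y_real ~ y_est)
  structure(list(se = se, se_pct = se_pct,
                 r2 = r_squared(y_real, y_est), n = n,
                 slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 n_dropped = sum(!ok)),
            class = "transfer_evaluation")
}

#' @export
print.transfer_evaluation <- function(x, ...) {
  cat(sprintf(
    "transfer evaluation (n = %d): SE = %.3f, SE%% = %.3f, R2 = %.4f, obs~pred slope = %.3f\n",
    x$n, x$se, x$se_pct, x$r2, x$slope))
  invisible(x)
}

#' Cross-region validation of a transfer model
#'
#' Predicts region B's productivity from region B's community trait means
#' using a model fitted in region A and evaluates the predictions against
#' region B's observed productivity (1:1-line comparison).
#'
#' @param model `transfer_model` fitted on region A.
#' @param cells_b region-B cell table.
#' @param trait_col,prod_col column names of the trait mean and observed
#'   productivity in `cells_b` (defaults derived from the model's labels).
#' @return list: `evaluation` (a `transfer_evaluation`) and `paired`
#'   (per-cell data.frame of trait, predicted and observed values).
#' @export
cross_region_validate <- function(model, cells_b,
                                  trait_col = paste0("mean_", model$trait),
                                  prod_col = model$productivity) {
  if (!trait_col %in% names(cells_b)) stop("missing trait column ", trait_col)
  if (!prod_col %in% names(cells_b)) stop("missing column ", prod_col)
  x <- cells_b[[trait_col]]
  obs <- cells_b[[prod_col]]
  pred <- suppressWarnings(predict_transfer(model, x))
  if (!any(is.finite(pred) & is.finite(obs)))
    stop("no in-domain cells in region B")
  paired <- data.frame(cell_id = cells_b$cell_id, trait = x,
                       predicted = as.numeric(pred), observed = obs)
  list(evaluation = evaluate_transfer(pred, obs), paired = paired)
}

#' Table of transfer functions for all trait x productivity pairs
#'
#' Fits the chosen form for every combination of trait measure (length,
#' width, length-width product) and productivity measure (GPP, NPP)
#' present in the cell table, reporting K, alpha, r, R^2, usable cell
#' count, SE and SE%.
#'
#' @param cells cell table with mean_length, mean_width, mean_lw_product
#'   and GPP, NPP columns.
#' @param form transfer form, default inverse logistic.
#' @param region optional region label.
#' @return list with `table` (one row per pair) and `models` (named list
#'   of `transfer_model`s, names like "GPP_length").
#' @export
transfer_table <- function(cells, form = "inv_logistic",
                           region = NA_character_) {
  traits <- c("length", "width", "lw_product")
  prods <- c("GPP", "NPP")
  rows <- list(); models <- list()
  for (pr in prods) for (tr in traits) {
    x <- cells[[paste0("mean_", tr)]]
    y <- cells[[pr]]
    m <- fit_transfer(x, y, form = form, trait = tr, productivity = pr,
                      region = region)
    yhat <- suppressWarnings(predict_transfer(m, x))
    ev <- evaluate_transfer(yhat, y)
    key <- paste(pr, tr, sep = "_")
    models[[key]] <- m
    rows[[key]] <- data.frame(
      productivity = pr, trait = tr,
      K = if (form == "inv_logistic") m$params$K else NA_real_,
      alpha = if (form == "inv_logistic") m$params$alpha else NA_real_,
      r = if (form == "inv_logistic") m$params$r else NA_real_,
      r2 = m$r2, n_cells = m$n, se = ev$se, se_pct = ev$se_pct,
      stringsAsFactors = FALSE)
  }
  list(table = do.call(rbind, rows), models = models)
}

#' Serialise / restore a transfer model as JSON
#'
#' The JSON exchange format lets a model fitted in one region (or run) be
#' applied in another.
#'
#' @param model a `transfer_model`.
#' @param path file path.
#' @return `write_transfer_json` returns the path invisibly;
#'   `read_transfer_json` returns the `transfer_model`.
#' @export
write_transfer_json <- function(model, path) {
  obj <- list(form = model$form, trait = model$trait,
              productivity = model$productivity, region = model$region,
              params = as.list(unclass(model$params)), r2 = model$r2,
              n = model$n, n_excluded = model$n_excluded)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transfer_json
#' @export
read_transfer_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- if (obj$form == "inv_logistic")
    logistic_params(obj$params$K, obj$params$alpha, obj$params$r)
  else unlist(obj$params)
  out <- list(form = obj$form, params = params, r2 = obj$r2, n = obj$n,
              n_excluded = obj$n_excluded, trait = obj$trait,
              productivity = obj$productivity, region = obj$region)
  class(out) <- "transfer_model"
  out
}

#' @export
print.transfer_model <- function(x, ...) {
  if (x$form == "inv_logistic") {
    cat(sprintf(
      "inverse-logistic transfer (%s ~ %s, n = %d, excluded %d): K = %.4g, alpha = %.4g, r = %.4g, R2 = %.4f\n",
      x$productivity, x$trait, x$n, x$n_excluded,
      x$params$K, x$params$alpha, x$params$r, x$r2))
  } else {
    cat(sprintf("%s transfer (%s ~ %s, n = %d): a = %.4g, b = %.4g, R2 = %.4f\n",
                x$form, x$productivity, x$trait, x$n,
                x$params[["a"]], x$params[["b"]], x$r2))
  }
  invisible(x)
}
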