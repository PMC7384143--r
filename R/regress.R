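#' Coefficient of determination on a common scale
#'
#' R^2 = 1 - SSE/SST with SST about the mean of `y`. For non-nested
#' nonlinear predictions the value can be negative.
#'
#' @param y observed values.
#' @param yhat predicted values, same length.
#' @return R^2 (at most 1, unbounded below).
#' @export
r_squared <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), length(y) >= 2L)
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop("var(y) is zero; R^2 undefined")
  1 - sum((y - yhat)^2) / sst
}

#' Fit a candidate trait-climate / trait-productivity model family
#'
#' Families: `linear` (y = a + b x), `sqrt_linear` (sqrt(y) = a + b x),
#' `exponential` (y = a b^x), `power` (y = a x^b) and `logistic`
#' (y = K / (1 + exp(alpha - r x)), the forward trait model). Nonlinear
#' families are fitted by full least squares (Levenberg-Marquardt) on the
#' raw response, started from a log-linearised warm start; the logistic is
#' additionally multi-started from three asymptote inflations of max(y),
#' with K bounded below by max(y) (1 + 1e-6) so the linearisation stays
#' defined, and the best SSE wins. R^2 is reported on the untransformed
#' response except for `sqrt_linear`, where it is on the sqrt scale and
#' flagged by `transform`.
#'
#' @param x predictor.
#' @param y response (must be > 0 for sqrt/exponential/power/logistic).
#' @param family model family.
#' @param k_mult asymptote inflation factors used as logistic multi-starts.
#' @param control `minpack.lm::nls.lm.control` list for nonlinear fits.
#' @return object of class `leaf_model_fit`: family, params, r2, n,
#'   transform, diagnostics (sse, warm-start sse, convergence info).
#' @export
fit_model <- function(x, y,
                      family = c("linear", "sqrt_linear", "exponential",
                                 "power", "logistic"),
                      k_mult = c(1.05, 1.5, 3),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 500, ftol = 1e-10)) {
  family <- match.arg(family)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(y)
  min_n <- if (family %in% c("linear", "sqrt_linear")) 3L else 5L
  if (n < min_n) stop("need at least ", min_n, " points for family ", family)
  if (var(y) == 0) stop("constant response; degenerate input")
  if (family %in% c("sqrt_linear", "exponential", "power", "logistic") &&
      any(y <= 0))
    stop("family ", family, " requires y > 0")
  if (family == "power" && any(x <= 0))
    stop("power family requires x > 0")

  out <- list(family = family, n = n, transform = "none")

  if (family == "linear") {
    fit <- lm(y ~ x)
    out$params <- c(a = unname(coef(fit)[1]), b = unname(coef(fit)[2]))
    out$r2 <- r_squared(y, fitted(fit))
    out$diagnostics <- list(sse = sum(resid(fit)^2), converged = TRUE)
  } else if (family == "sqrt_linear") {
    sy <- sqrt(y)
    fit <- lm(sy ~ x)
    out$params <- c(a = unname(coef(fit)[1]), b = unname(coef(fit)[2]))
    out$r2 <- r_squared(sy, fitted(fit))
    out$transform <- "sqrt"
    out$diagnostics <- list(sse = sum(resid(fit)^2), converged = TRUE)
  } else if (family %in% c("exponential", "power")) {
    # log-linear warm start, then full nonlinear LS on the raw scale
    if (family == "exponential") {
      ws <- lm(log(y) ~ x)
      start <- list(a = exp(coef(ws)[[1]]), b = exp(coef(ws)[[2]]))
      form <- y ~ a * b^x
    } else {
      ws <- lm(log(y) ~ log(x))
      start <- list(a = exp(coef(ws)[[1]]), b = coef(ws)[[2]])
      form <- y ~ a * x^b
    }
    warm_sse <- sum((y - eval(form[[3]], c(start, list(x = x))))^2)
    fit <- minpack.lm::nlsLM(form, data = data.frame(x = x, y = y),
                             start = start, control = control)
    out$params <- coef(fit)
    out$r2 <- r_squared(y, fitted(fit))
    out$diagnostics <- list(sse = sum(resid(fit)^2), warm_sse = warm_sse,
                            converged = fit$convInfo$isConv)
  } else {
    best <- NULL
    for (km in k_mult) {
      K0 <- km * max(y)
      z <- log(K0 / y - 1)
      ws <- lm(z ~ x)                      # z = alpha - r x
      start <- list(K = K0, alpha = coef(ws)[[1]], r = max(-coef(ws)[[2]],
                                                           1e-8))
      warm_sse <- sum((y - start$K / (1 + exp(start$alpha - start$r * x)))^2)
      fit <- tryCatch(
        minpack.lm::nlsLM(y ~ K / (1 + exp(alpha - r * x)),
                          data = data.frame(x = x, y = y), start = start,
                          lower = c(K = max(y) * (1 + 1e-6), alpha = -Inf,
                                    r = 1e-12),
                          control = control),
        error = function(e) NULL)
      if (is.null(fit)) next
      sse <- sum(resid(fit)^2)
      if (is.null(best) || sse < best$sse)
        best <- list(fit = fit, sse = sse, warm_sse = warm_sse)
    }
    if (is.null(best))
      stop("logistic fit failed to converge from all warm starts")
    out$params <- coef(best$fit)
    out$r2 <- r_squared(y, fitted(best$fit))
    out$diagnostics <- list(sse = best$sse, warm_sse = best$warm_sse,
                            converged = best$fit$convInfo$isConv)
  }
  class(out) <- "leaf_model_fit"
  out
}

#' Predict from a fitted model family
#'
#' Evaluates the family's formula at new predictor values. For
#' `sqrt_linear` the fitted sqrt-response is squared; negative fitted
#' sqrt-responses are clipped to zero with a warning.
#'
#' @param fit a `leaf_model_fit`.
#' @param x new predictor values.
#' @return predicted response on the raw scale.
#' @export
predict_model <- function(fit, x) {
  p <- fit$params
  switch(fit$family,
    linear = p[["a"]] + p[["b"]] * x,
    sqrt_linear = {
      s <- p[["a"]] + p[["b"]] * x
      if (any(s < 0)) {
        warning(sum(s < 0), " predictions clipped at sqrt(y) = 0")
        s <- pmax(s, 0)
      }
      s^2
    },
    exponential = p[["a"]] * p[["b"]]^x,
    power = p[["a"]] * x^p[["b"]],
    logistic = p[["K"]] / (1 + exp(p[["alpha"]] - p[["r"]] * x)),
    stop("unknown family: ", fit$family))
}

#' @export
print.leaf_model_fit <- function(x, ...) {
  cat(sprintf("%s fit (n = %d): %s; R2 = %.4f%s\n", x$family, x$n,
              paste(sprintf("%s = %.6g", names(x$params), x$params),
                    collapse = ", "),
              x$r2,
              if (x$transform != "none")
                paste0(" (on ", x$transform, " scale)") else ""))
  invisible(x)
}
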