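# forward evaluation of the inverse-logistic transfer form
# y = (1/r) (alpha - log(K/x - 1)), 0 < x < K
inv_logistic_eval <- function(x, p) (p$alpha - log(p$K / x - 1)) / p$r

#' Generate productivity surfaces from community trait means
#'
#' GPP and NPP are generated from one driver trait's community mean by the
#' inverse-logistic transfer form plus additive Gaussian noise with sd equal
#' to `noise_frac` times the noiseless productivity range. Optionally a
#' per-year stack adds i.i.d. Gaussian year effects (no temporal
#' autocorrelation), so ranked-year means are exercisable. LAI is generated
#' as a monotone noisy (logistic) function of AET when an `AET` column is
#' present.
#'
#' Noise is additive on the productivity scale and is deliberately not
#' clamped: clamping would destroy the Gaussian error structure that the
#' refitting round trips assume. Counts of cells where noise produced
#' negative productivity or NPP > GPP are recorded in attributes
#' `n_negative` and `n_npp_gt_gpp`.
#'
#' @param cells cell table containing the driver trait's community mean
#'   column (e.g. `mean_length`) and optionally `AET`.
#' @param scenario a [leaf_scenario()].
#' @param seed integer seed.
#' @param driver trait driving the generator: "length", "width" or
#'   "lw_product" (column `mean_<driver>` must exist).
#' @param years if TRUE, attach per-year matrices as attributes
#'   `gpp_years`, `npp_years` (cells x n_years).
#' @return the cell table with GPP, NPP (and LAI) columns added.
#' @export
make_productivity <- function(cells, scenario, seed = scenario$seed,
                              driver = c("length", "width", "lw_product"),
                              years = FALSE) {
  validate_scenario(scenario)
  driver <- match.arg(driver)
  col <- paste0("mean_", driver)
  if (!col %in% names(cells)) stop("cells must contain column ", col)
  x <- cells[[col]]
  if (anyNA(x)) stop("driver trait means contain NA; filter cells first")

  pg <- scenario$transfer$GPP[[driver]]
  pn <- scenario$transfer$NPP[[driver]]
  bad <- which(x >= pg$K | x >= pn$K)
  if (length(bad))
    stop("trait mean >= K in cells: ",
         paste(head(cells$cell_id[bad], 10L), collapse = ", "),
         if (length(bad) > 10L) " ..." else "")

  set.seed(seed)
  mu_g <- inv_logistic_eval(x, pg)
  mu_n <- inv_logistic_eval(x, pn)
  rng_g <- diff(range(mu_g))
  rng_n <- diff(range(mu_n))
  gpp <- mu_g + rnorm(length(x), 0, scenario$noise_frac * rng_g)
  npp <- mu_n + rnorm(length(x), 0, scenario$noise_frac * rng_n)

  out <- cells
  out$GPP <- gpp
  out$NPP <- npp
  if ("AET" %in% names(cells)) {
    lai <- 6 * stats::plogis((cells$AET - 250) / 120) +
      rnorm(length(x), 0, 0.3 * min(1, scenario$noise_frac / 0.08))
    out$LAI <- pmax(lai, 0)
  }
  attr(out, "n_negative") <- sum(gpp < 0 | npp < 0)
  attr(out, "n_npp_gt_gpp") <- sum(npp > gpp)

  if (years) {
    ys_g <- scenario$year_sd_frac * rng_g
    ys_n <- scenario$year_sd_frac * rng_n
    set.seed(substream_seed(seed, "years"))
    attr(out, "gpp_years") <- gpp +
      matrix(rnorm(length(x) * scenario$n_years, 0, ys_g),
             nrow = length(x))
    attr(out, "npp_years") <- npp +
      matrix(rnorm(length(x) * scenario$n_years, 0, ys_n),
             nrow = length(x))
  }
  out
}

#' Validate a cell table against its observational invariants
#'
#' Checks one row per cell, non-negative richness, and (where both are
#' present and non-missing) GPP >= NPP >= 0.
#'
#' @param cells a cell table.
#' @return invisibly TRUE, or an error describing the violation.
#' @export
validate_cell_table <- function(cells) {
  if (anyDuplicated(cells$cell_id)) stop("duplicate cell_id rows")
  if ("richness" %in% names(cells) && any(cells$richness < 0))
    stop("negative richness")
  if (all(c("GPP", "NPP") %in% names(cells))) {
    ok <- stats::complete.cases(cells[, c("GPP", "NPP")])
    if (any(cells$NPP[ok] < 0 | cells$GPP[ok] < cells$NPP[ok]))
      stop("productivity invariant GPP >= NPP >= 0 violated")
  }
  invisible(TRUE)
}
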