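# inverse of the forward logistic y = K/(1 + exp(alpha - r x)):
# x = (alpha - log(K/y - 1)) / r, defined for 0 < y < K
inv_forward_logistic <- function(y, p) (p$alpha - log(p$K / y - 1)) / p$r

#' Generate a synthetic species pool with trait-coupled niches
#'
#' Each species receives a median leaf length (log-normal, truncated below
#' the forward-model asymptote), a symmetric min-max range around the
#' median, widths as length times a log-normal ratio, a life-form label
#' (habit and phenology), and an AET niche optimum. The optimum is a
#' monotone increasing function of median leaf size (the inverse of the
#' scenario's forward trait-AET logistic) plus Gaussian noise; setting
#' `niche_coupling = 0` decouples size and niche entirely. This encodes the
#' macroecological assumption that small-leaved species sort into cells
#' where water or energy (hence AET) is low.
#'
#' @param scenario a [leaf_scenario()].
#' @param seed integer seed.
#' @return list with `traits` (data.frame species, habit, phenology,
#'   length_min/max, width_min/max, cm) and `niche` (data.frame species,
#'   optimum (mm AET), breadth (mm), length_med, width_med).
#' @export
make_species_pool <- function(scenario, seed = scenario$seed) {
  validate_scenario(scenario)
  set.seed(seed)
  n <- scenario$n_species
  fw <- scenario$trait_forward

  # Truncate species lengths below the forward-model and transfer
  # asymptotes (inverse-CDF truncation of the log-normal, so no atoms):
  # community means must stay strictly inside the transfer domain x < K.
  len_cap <- 0.92 * min(fw$K,
                        scenario$transfer$GPP$length$K,
                        scenario$transfer$NPP$length$K)
  lo <- stats::plnorm(0.3, scenario$length_meanlog, scenario$length_sdlog)
  hi <- stats::plnorm(len_cap, scenario$length_meanlog, scenario$length_sdlog)
  len_med <- stats::qlnorm(runif(n, lo, hi),
                           scenario$length_meanlog, scenario$length_sdlog)
  ratio <- scenario$width_ratio_mean *
    rlnorm(n, -scenario$width_ratio_sdlog^2 / 2, scenario$width_ratio_sdlog)
  wid_cap <- 0.92 * min(scenario$transfer$GPP$width$K,
                        scenario$transfer$NPP$width$K)
  wid_med <- pmin(len_med * ratio, wid_cap)

  half <- runif(n, scenario$range_rel_halfwidth[1],
                scenario$range_rel_halfwidth[2])
  traits <- data.frame(
    species = sprintf("sp%04d", seq_len(n)),
    habit = sample(c("tree", "shrub", "liana"), n, replace = TRUE,
                   prob = c(0.45, 0.45, 0.10)),
    phenology = sample(c("deciduous", "evergreen", "unknown"), n,
                       replace = TRUE, prob = c(0.5, 0.4, 0.1)),
    length_min = len_med * (1 - half), length_max = len_med * (1 + half),
    width_min = wid_med * (1 - half), width_max = wid_med * (1 + half),
    stringsAsFactors = FALSE)

  opt_map <- inv_forward_logistic(len_med, fw)
  optimum <- mean(opt_map) +
    scenario$niche_coupling * (opt_map - mean(opt_map)) +
    rnorm(n, 0, scenario$niche_noise_sd)

  niche <- data.frame(species = traits$species, optimum = optimum,
                      breadth = scenario$niche_breadth,
                      length_med = len_med, width_med = wid_med,
                      stringsAsFactors = FALSE)
  list(traits = traits, niche = niche)
}

#' Sample species ranges as presence/absence over the grid
#'
#' Presence in a cell is Bernoulli with probability
#' exp(-(AET_cell - optimum)^2 / (2 breadth^2)). A species drawing zero
#' cells is re-sampled (up to `max_resample` times), then deterministically
#' placed in its highest-probability cell, so every species occupies at
#' least one cell. Bernoulli sampling (not thresholding) creates the
#' realistic richness gradients the downstream >= 20-species filter acts on.
#'
#' @param pool output of [make_species_pool()].
#' @param climate cell table from [make_climate_fields()] (needs AET).
#' @param scenario a [leaf_scenario()].
#' @param seed integer seed.
#' @return a `presence_matrix` (cells x species logical matrix).
#' @export
make_ranges <- function(pool, climate, scenario, seed = scenario$seed,
                        max_resample = 20L) {
  validate_scenario(scenario)
  stopifnot("AET" %in% names(climate))
  if (scenario$niche_breadth <= 0) stop("niche breadth must be > 0")
  set.seed(seed)
  aet <- climate$AET
  ncell <- length(aet)
  sp <- pool$niche$species
  pm <- matrix(FALSE, nrow = ncell, ncol = length(sp),
               dimnames = list(as.character(climate$cell_id), sp))
  for (k in seq_along(sp)) {
    p <- exp(-(aet - pool$niche$optimum[k])^2 /
               (2 * pool$niche$breadth[k]^2))
    pres <- runif(ncell) < p
    tries <- 0L
    while (!any(pres) && tries < max_resample) {
      pres <- runif(ncell) < p
      tries <- tries + 1L
    }
    if (!any(pres)) pres[which.max(p)] <- TRUE
    pm[, k] <- pres
  }
  class(pm) <- c("presence_matrix", class(pm))
  pm
}
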