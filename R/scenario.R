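#' Logistic / inverse-logistic parameter triple
#'
#' The triple (K, alpha, r) is shared by the forward logistic trait model
#' y = K / (1 + exp(alpha - r x)) and the inverse-logistic transfer function
#' y = (1/r) (alpha - ln(K/x - 1)), x < K. `K` is the upper asymptote in the
#' units of the logistic response, `alpha` is dimensionless and `r` is per
#' unit of predictor.
#'
#' @param K upper asymptote, > 0.
#' @param alpha dimensionless location parameter.
#' @param r rate parameter, > 0.
#' @return an object of class `logistic_params`.
#' @export
logistic_params <- function(K, alpha, r) {
  stopifnot(is.numeric(K), is.numeric(alpha), is.numeric(r),
            length(K) == 1L, length(alpha) == 1L, length(r) == 1L)
  if (!is.finite(K) || K <= 0) stop("K must be a positive finite number")
  if (!is.finite(r) || r <= 0) stop("r must be a positive finite number")
  structure(list(K = K, alpha = alpha, r = r), class = "logistic_params")
}

#' @export
print.logistic_params <- function(x, ...) {
  cat(sprintf("logistic params: K = %g, alpha = %g, r = %g\n",
              x$K, x$alpha, x$r))
  invisible(x)
}

#' Default transfer parameters for the six trait x productivity pairs
#'
#' Inverse-logistic (K, alpha, r) triples for community mean leaf length,
#' width and length-width product against GPP and NPP (gC m-2 yr-1). These
#' drive the forward productivity generator and are the reference values
#' the round-trip checks recover.
#'
#' @return nested list `$GPP`/`$NPP` by trait of [logistic_params()].
#' @export
default_transfer_params <- function() {
  list(
    GPP = list(
      length     = logistic_params(11.602, 1.470, 0.002),
      width      = logistic_params(5.228,  1.558, 0.002),
      lw_product = logistic_params(50.641, 2.985, 0.003)
    ),
    NPP = list(
      length     = logistic_params(11.500, 1.567, 0.004),
      width      = logistic_params(5.208,  1.669, 0.005),
      lw_product = logistic_params(50.567, 3.089, 0.006)
    )
  )
}

#' Build a synthetic-study scenario
#'
#' A scenario bundles every parameter of the synthetic data generator: the
#' analysis grid, Gaussian-random-field (GRF) parameters of the environmental
#' surfaces, the species trait and niche model, the forward trait and transfer
#' logistic parameters, productivity noise, and the phylogeny simulator.
#' Defaults emulate a temperate-to-subtropical study region: community mean
#' leaf lengths of a few to ~10 cm, actual evapotranspiration (AET) of
#' roughly 50-700 mm, GPP spanning a few hundred to ~2500 gC m-2 yr-1, and
#' productivity noise equal to 8% of the generated range (the scale implied
#' by transfer-function SE% values of 8-9%).
#'
#' @param nx,ny grid dimensions (cells).
#' @param cell_km cell size in km (default 50).
#' @param n_species number of species in the pool.
#' @param grf named list of per-field GRF parameters, each
#'   `c(mean =, sd =, range =)` with `range` the exponential correlation
#'   range in km.
#' @param seasonal_amp temperature difference (deg C) between warmest/coldest
#'   quarter and the annual mean.
#' @param length_meanlog,length_sdlog log-normal parameters of species median
#'   leaf length (cm).
#' @param width_ratio_mean,width_ratio_sdlog width = length * ratio with
#'   log-normal ratio noise.
#' @param range_rel_halfwidth two values: the relative half-width of the
#'   species min-max trait range is drawn uniformly between them.
#' @param niche_coupling coupling in [0, 1+] between species median leaf size
#'   and the AET niche optimum (0 decouples them).
#' @param niche_noise_sd sd (mm) of noise on the niche optimum.
#' @param niche_breadth Gaussian niche breadth (mm AET).
#' @param trait_forward `logistic_params` of the forward trait model
#'   (community leaf length vs AET); its inverse maps median size to the
#'   niche optimum.
#' @param transfer nested list `$GPP`/`$NPP` by trait of `logistic_params`
#'   used to generate productivity from community trait means.
#' @param noise_frac productivity noise sd as a fraction of the noiseless
#'   productivity range.
#' @param n_years years in the optional per-year productivity stack.
#' @param year_sd_frac sd of i.i.d. yearly effects, as a fraction of range.
#' @param birth,death birth-death rates (per Myr) of the simulated phylogeny.
#' @param signal_weight Pagel-style mixing weight in [0,1]: 1 = pure Brownian
#'   trait evolution, 0 = phylogenetically random traits.
#' @param seed master seed (integer).
#' @return an object of class `leaf_scenario`.
#' @export
leaf_scenario <- function(nx = 30, ny = 30, cell_km = 50, n_species = 400,
                          grf = list(
                            MAT  = c(mean = 10,  sd = 8,    range = 400),
                            MAP  = c(mean = 800, sd = 350,  range = 400),
                            SRAD = c(mean = 1.6, sd = 0.25, range = 600),
                            soil = c(mean = 0,   sd = 1,    range = 300)
                          ),
                          seasonal_amp = 8,
                          length_meanlog = log(6), length_sdlog = 0.55,
                          width_ratio_mean = 0.45, width_ratio_sdlog = 0.25,
                          range_rel_halfwidth = c(0.2, 0.6),
                          niche_coupling = 1, niche_noise_sd = 60,
                          niche_breadth = 120,
                          trait_forward = logistic_params(16, 1.0, 0.006),
                          transfer = default_transfer_params(),
                          noise_frac = 0.08,
                          n_years = 16, year_sd_frac = 0.05,
                          birth = 0.15, death = 0.05, signal_weight = 0.3,
                          seed = 1L) {
  sc <- list(nx = as.integer(nx), ny = as.integer(ny), cell_km = cell_km,
             n_species = as.integer(n_species), grf = grf,
             seasonal_amp = seasonal_amp,
             length_meanlog = length_meanlog, length_sdlog = length_sdlog,
             width_ratio_mean = width_ratio_mean,
             width_ratio_sdlog = width_ratio_sdlog,
             range_rel_halfwidth = range_rel_halfwidth,
             niche_coupling = niche_coupling,
             niche_noise_sd = niche_noise_sd,
             niche_breadth = niche_breadth,
             trait_forward = trait_forward, transfer = transfer,
             noise_frac = noise_frac, n_years = as.integer(n_years),
             year_sd_frac = year_sd_frac,
             birth = birth, death = death, signal_weight = signal_weight,
             seed = as.integer(seed))
  class(sc) <- "leaf_scenario"
  validate_scenario(sc)
  sc
}

validate_scenario <- function(sc) {
  stopifnot(inherits(sc, "leaf_scenario"))
  if (sc$nx * sc$ny < 1L) stop("grid must contain at least one cell")
  if (sc$cell_km <= 0) stop("cell_km must be > 0")
  if (sc$n_species < 1L) stop("n_species must be >= 1")
  for (nm in names(sc$grf)) {
    p <- sc$grf[[nm]]
    if (!all(c("mean", "sd", "range") %in% names(p)))
      stop("grf field '", nm, "' needs mean, sd and range")
    if (p[["sd"]] < 0) stop("grf field '", nm, "': sd must be >= 0")
    if (p[["range"]] <= 0) stop("grf field '", nm, "': range must be > 0")
  }
  if (sc$length_sdlog < 0 || sc$width_ratio_sdlog < 0)
    stop("trait sdlog parameters must be >= 0")
  if (sc$niche_breadth <= 0) stop("niche_breadth must be > 0")
  if (sc$niche_noise_sd < 0) stop("niche_noise_sd must be >= 0")
  if (sc$noise_frac < 0) stop("noise_frac must be >= 0")
  if (sc$signal_weight < 0 || sc$signal_weight > 1)
    stop("signal_weight must lie in [0, 1]")
  if (sc$birth <= sc$death || sc$death < 0)
    stop("need birth rate > death rate >= 0")
  invisible(sc)
}

#' @export
print.leaf_scenario <- function(x, ...) {
  cat(sprintf(
    "leaf_scenario: %d x %d cells of %g km, %d species, noise_frac = %g\n",
    x$nx, x$ny, x$cell_km, x$n_species, x$noise_frac))
  invisible(x)
}

# Deterministic per-stage substreams from one master seed.  Offsets keep the
# derived seed a valid 32-bit integer.
substream_seed <- function(seed, stage) {
  offs <- c(climate = 11L, pool = 23L, ranges = 37L, productivity = 53L,
            phylogeny = 71L, years = 89L, region_b = 101L, misc = 131L)
  if (!stage %in% names(offs)) stop("unknown substream stage: ", stage)
  as.integer((as.numeric(seed) * 1009 + offs[[stage]]) %% .Machine$integer.max)
}
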