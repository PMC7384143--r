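# Gaussian random field simulation on cell centres with exponential
# covariance C(d) = sill * exp(-d / range).  Exact covariance-matrix
# Cholesky; fine for desk-scale grids (<= ~5000 cells).  An FFT-based
# simulator would be the upgrade path for larger grids.
grf_chol <- function(coords, range_km, nugget = 1e-10) {
  D <- as.matrix(stats::dist(coords))
  chol(exp(-D / range_km) + diag(nugget, nrow(D)))
}

grf_draw <- function(L, mean, sd) {
  n <- ncol(L)
  if (sd == 0) return(rep(mean, n))
  mean + sd * drop(crossprod(L, rnorm(n)))
}

#' Simulate a Gaussian random field on arbitrary coordinates
#'
#' Draws realisations of a Gaussian random field with exponential spatial
#' covariance C(d) = sd^2 exp(-d / range_km) by exact Cholesky
#' factorisation of the covariance matrix.
#'
#' @param coords two-column matrix/data.frame of coordinates (km).
#' @param range_km correlation range (> 0).
#' @param mean,sd field mean and marginal standard deviation (sd = 0 gives
#'   a constant field).
#' @param n_draws number of independent realisations.
#' @param seed optional seed.
#' @return numeric matrix, nrow(coords) x n_draws.
#' @export
simulate_grf <- function(coords, range_km, mean = 0, sd = 1, n_draws = 1,
                         seed = NULL) {
  if (range_km <= 0) stop("range_km must be > 0")
  if (sd < 0) stop("sd must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  coords <- as.matrix(coords)
  L <- grf_chol(coords, range_km)
  vapply(seq_len(n_draws), function(i) grf_draw(L, mean, sd),
         numeric(nrow(coords)))
}

#' Simulate spatially autocorrelated environmental fields
#'
#' Generates one value per grid cell for each environmental surface. The
#' primitive fields (MAT, MAP, SRAD and a shared soil driver) are Gaussian
#' random fields with exponential spatial covariance; the remaining columns
#' are derived: MTWQ/MTCQ as MAT plus/minus the seasonal amplitude with
#' small GRF perturbations, MPWQ as a fraction of MAP, potential
#' evapotranspiration (PET) as an energy proxy from MAT, AET as a smooth
#' minimum of water supply (MAP) and energy demand (PET) so that it
#' correlates with both, AI = MAP/PET, and three correlated soil variables
#' (pH, organic carbon, cation exchange capacity) sharing the soil driver.
#'
#' @param scenario a [leaf_scenario()].
#' @param seed integer seed; identical seed + scenario gives a bit-identical
#'   table.
#' @return data.frame (cell table) with cell_id, x, y and environment
#'   columns MAT, MTWQ, MTCQ, MAP, MPWQ, AI, AET, SRAD, soil_ph, soil_oc,
#'   soil_cec.
#' @export
make_climate_fields <- function(scenario, seed = scenario$seed) {
  validate_scenario(scenario)
  grid <- grid_spec(scenario$nx, scenario$ny, scenario$cell_km)
  cc <- cell_centres(grid)
  set.seed(seed)
  coords <- cc[, c("x", "y")]

  # one Cholesky factor per distinct correlation range
  ranges <- vapply(scenario$grf, function(p) p[["range"]], numeric(1))
  chols <- lapply(unique(ranges), function(r) grf_chol(coords, r))
  names(chols) <- as.character(unique(ranges))
  draw <- function(field) {
    p <- scenario$grf[[field]]
    grf_draw(chols[[as.character(p[["range"]])]], p[["mean"]], p[["sd"]])
  }

  MAT <- draw("MAT")
  MAP <- pmax(draw("MAP"), 1)          # precipitation floor, mm
  SRAD <- pmax(draw("SRAD"), 0.1)
  soil_shared <- draw("soil")

  pert <- function(sdfrac, range_key = "MAT") {
    p <- scenario$grf[[range_key]]
    grf_draw(chols[[as.character(p[["range"]])]], 0, sdfrac * p[["sd"]])
  }
  MTWQ <- MAT + scenario$seasonal_amp + pert(0.25)
  MTCQ <- MAT - scenario$seasonal_amp + pert(0.25)
  MPWQ <- pmax(0.45 * MAP + pert(0.10, "MAP"), 0.5)

  PET <- pmax(58.93 * pmax(MAT, 0.5), 1)   # energy demand proxy, mm
  AET <- MAP * PET / (MAP + PET)           # smooth minimum of supply/demand
  AI <- MAP / PET

  soil_ph  <- 6.5 - 0.8 * soil_shared + 0.4 * rnorm(nrow(cc))
  soil_oc  <- 2.0 + 1.0 * soil_shared + 0.4 * rnorm(nrow(cc))
  soil_cec <- 15  + 5.0 * soil_shared + 2.0 * rnorm(nrow(cc))

  out <- data.frame(cell_id = cc$cell_id, x = cc$x, y = cc$y,
                    MAT = MAT, MTWQ = MTWQ, MTCQ = MTCQ,
                    MAP = MAP, MPWQ = MPWQ, AI = AI, AET = AET,
                    SRAD = SRAD, soil_ph = soil_ph, soil_oc = soil_oc,
                    soil_cec = soil_cec)
  attr(out, "grid") <- grid
  out
}
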