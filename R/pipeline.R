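#' Configuration for the end-to-end synthetic study
#'
#' @param scenario a [leaf_scenario()].
#' @param seed master seed; every stage derives its own substream from it.
#' @param min_richness cells with fewer species are dropped before any
#'   regression (default 20).
#' @param bonferroni_n divisor of the 0.05 family-wise level applied to the
#'   trait-climate correlation matrix (default 48).
#' @param n_perm permutations for the phylogenetic-signal test.
#' @param stages character vector of stages to run; any of "climate",
#'   "transfer", "cross_region", "phylo", "sem".
#' @param transfer_roundtrip if TRUE the transfer table is computed in
#'   round-trip mode: each trait x productivity row is fitted on
#'   productivity generated from its own trait with its own parameters
#'   (used to verify exact parameter recovery at zero noise). If FALSE
#'   (default) all six rows are fitted against the single GPP/NPP surface
#'   generated from the driver trait.
#' @param driver trait driving productivity generation (default "length").
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(scenario = leaf_scenario(), seed = scenario$seed,
                            min_richness = 20, bonferroni_n = 48,
                            n_perm = 199,
                            stages = c("climate", "transfer", "cross_region",
                                       "phylo", "sem"),
                            transfer_roundtrip = FALSE,
                            driver = "length") {
  if (bonferroni_n < 1) stop("Bonferroni divisor must be >= 1")
  structure(list(scenario = scenario, seed = as.integer(seed),
                 min_richness = min_richness, bonferroni_n = bonferroni_n,
                 n_perm = n_perm, stages = stages,
                 transfer_roundtrip = transfer_roundtrip, driver = driver),
            class = "pipeline_config")
}

# simulate one region and assemble its richness-filtered cell table
simulate_region <- function(scenario, seed, driver = "length") {
  climate <- make_climate_fields(scenario, substream_seed(seed, "climate"))
  pool <- make_species_pool(scenario, substream_seed(seed, "pool"))
  presence <- make_ranges(pool, climate, scenario,
                          substream_seed(seed, "ranges"))
  cells <- community_trait_table(presence, pool$traits, climate)
  soil <- soil_pca(cells$soil_ph, cells$soil_oc, cells$soil_cec)
  cells$soilPC1 <- as.numeric(soil$scores)
  list(climate = climate, pool = pool, presence = presence, cells = cells,
       soil_variance_fraction = soil$variance_fraction)
}

#' Run the full synthetic study pipeline
#'
#' Sequences simulate -> grid/traits -> richness filter -> trait-climate
#' fits with modified t-tests and hierarchical partitioning -> productivity
#' generation -> transfer-function table -> cross-region validation ->
#' phylogenetic signal and clade-age interaction -> piecewise SEMs, and
#' returns a structured result bundle. All thresholds actually applied
#' (richness filter, Bonferroni level, excluded cells) are recorded in the
#' bundle.
#'
#' @param config a [pipeline_config()].
#' @return nested list of stage results (class `pipeline_result`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  sc <- config$scenario
  res <- list(config = config)

  regA <- simulate_region(sc, config$seed, config$driver)
  cellsA <- filter_richness(regA$cells[!is.na(regA$cells$mean_length), ],
                            config$min_richness)
  n_removed <- attr(cellsA, "n_removed")
  cellsA <- make_productivity(cellsA, sc,
                              substream_seed(config$seed, "productivity"),
                              driver = config$driver, years = TRUE)
  res$region_a <- list(cells = cellsA, n_removed = n_removed,
                       soil_variance_fraction = regA$soil_variance_fraction)

  if ("climate" %in% config$stages) {
    env_vars <- c("MAP", "MPWQ", "AI", "MAT", "MTWQ", "MTCQ", "AET", "SRAD")
    traits <- c("length", "width", "lw_product")
    alpha <- 0.05 / config$bonferroni_n
    coords <- cellsA[, c("x", "y")]
    grid_rows <- list()
    for (tr in traits) {
      yv <- cellsA[[paste0("mean_", tr)]]
      for (ev in env_vars) {
        xv <- cellsA[[ev]]
        lg <- tryCatch(fit_model(xv, yv, "logistic"),
                       error = function(e) NULL)
        mt <- modified_t_test(xv, yv, coords)
        grid_rows[[paste(tr, ev)]] <- data.frame(
          trait = tr, env = ev,
          r2 = if (is.null(lg)) NA_real_ else lg$r2,
          r = mt$r, M_hat = mt$M_hat, p = mt$p,
          significant = mt$p < alpha)
      }
    }
    hp <- hierarchical_partition(
      cellsA$mean_length,
      cellsA[, c("AET", "MAP", "MAT", "SRAD")])
    res$climate <- list(correlations = do.call(rbind, grid_rows),
                        alpha = alpha, hier_partition = hp)
  }

  if ("transfer" %in% config$stages) {
    if (config$transfer_roundtrip) {
      rows <- list(); models <- list()
      for (pr in c("GPP", "NPP")) for (tr in c("length", "width",
                                               "lw_product")) {
        gen <- make_productivity(cellsA, sc,
                                 substream_seed(config$seed, "productivity"),
                                 driver = tr)
        m <- fit_transfer(gen[[paste0("mean_", tr)]], gen[[pr]],
                          trait = tr, productivity = pr, region = "A")
        yhat <- suppressWarnings(
          predict_transfer(m, gen[[paste0("mean_", tr)]]))
        ev <- evaluate_transfer(yhat, gen[[pr]])
        key <- paste(pr, tr, sep = "_")
        models[[key]] <- m
        rows[[key]] <- data.frame(productivity = pr, trait = tr,
                                  K = m$params$K, alpha = m$params$alpha,
                                  r = m$params$r, r2 = m$r2, n_cells = m$n,
                                  se = ev$se, se_pct = ev$se_pct)
      }
      res$transfer <- list(table = do.call(rbind, rows), models = models,
                           roundtrip = TRUE)
    } else {
      tt <- transfer_table(cellsA, region = "A")
      tt$roundtrip <- FALSE
      res$transfer <- tt
    }
  }

  if ("cross_region" %in% config$stages) {
    seedB <- substream_seed(config$seed, "region_b")
    regB <- simulate_region(sc, seedB, config$driver)
    cellsB <- filter_richness(regB$cells[!is.na(regB$cells$mean_length), ],
                              config$min_richness)
    cellsB <- make_productivity(cellsB, sc,
                                substream_seed(seedB, "productivity"),
                                driver = config$driver)
    key <- paste0("GPP_", config$driver)
    model <- if (!is.null(res$transfer)) res$transfer$models[[key]]
    else fit_transfer(cellsA[[paste0("mean_", config$driver)]],
                      cellsA$GPP, trait = config$driver,
                      productivity = "GPP", region = "A")
    cv <- cross_region_validate(model, cellsB)
    res$cross_region <- list(evaluation = cv$evaluation,
                             paired = cv$paired, cells_b = cellsB)
  }

  if ("phylo" %in% config$stages) {
    ph <- make_phylogeny(sc, substream_seed(config$seed, "phylogeny"))
    # identify tips with the species pool so leaf size maps onto the tree
    ph$tree$tip.label <- colnames(regA$presence)
    size_trait <- log(regA$pool$niche$length_med)
    names(size_trait) <- regA$pool$niche$species
    sig <- blomberg_k_test(ph$tree, size_trait, n_perm = config$n_perm,
                           seed = substream_seed(config$seed, "misc"))
    cl <- clade_table(ph$tree, cut_age = 15, prefix = "genus")
    ages <- cell_mean_clade_age(regA$presence, cl$map, cl$ages)
    merged <- merge(cellsA, ages, by = "cell_id")
    ai <- tryCatch(
      age_interaction_model(merged$GPP, merged$mean_length,
                            merged$mean_clade_age),
      error = function(e) NULL)
    res$phylo <- list(signal = sig, cell_ages = ages,
                      age_interaction = ai)
  }

  if ("sem" %in% config$stages) {
    dat <- cellsA
    dat$leaf_size <- dat$mean_length
    specs <- list(
      climate_trait = sem_spec(
        data.frame(from = c("AET", "leaf_size", "AET"),
                   to = c("leaf_size", "GPP", "GPP")),
        transforms = list(GPP = "sqrt")),
      trait_lai = sem_spec(
        data.frame(from = c("leaf_size", "LAI", "leaf_size"),
                   to = c("LAI", "GPP", "GPP")),
        transforms = list(GPP = "sqrt")),
      climate_trait_lai = sem_spec(
        data.frame(from = c("AET", "AET", "leaf_size", "LAI", "AET",
                            "leaf_size"),
                   to = c("leaf_size", "LAI", "GPP", "GPP", "GPP", "LAI")),
        transforms = list(GPP = "sqrt")))
    res$sem <- lapply(specs, function(s) {
      f <- fit_piecewise_sem(s, dat)
      list(fit = f, effects = effects_decomposition(f))
    })
  }

  class(res) <- "pipeline_result"
  res
}

#' Write a machine-readable summary of a pipeline run
#'
#' @param result a `pipeline_result`.
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
write_pipeline_json <- function(result, path) {
  out <- list(
    n_cells = nrow(result$region_a$cells),
    n_removed_richness = result$region_a$n_removed,
    soil_variance_fraction = result$region_a$soil_variance_fraction)
  if (!is.null(result$climate)) {
    out$climate_alpha <- result$climate$alpha
    out$climate <- result$climate$correlations
    out$hier_partition <- result$climate$hier_partition$effects
  }
  if (!is.null(result$transfer)) out$transfer_table <- result$transfer$table
  if (!is.null(result$cross_region))
    out$cross_region <- unclass(result$cross_region$evaluation)
  if (!is.null(result$phylo)) {
    out$blomberg_K <- result$phylo$signal$K
    out$blomberg_p <- result$phylo$signal$p
  }
  if (!is.null(result$sem))
    out$sem_effects <- lapply(result$sem, function(s) s$effects)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
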