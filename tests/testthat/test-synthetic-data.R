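test_that("climate fields are seeded, spatially structured and consistent", {
  sc <- small_scenario()
  a <- make_climate_fields(sc, seed = 42)
  b <- make_climate_fields(sc, seed = 42)
  expect_identical(a, b)                         # bitwise determinism
  expect_false(identical(a$MAT, make_climate_fields(sc, seed = 43)$MAT))

  # AET is a monotone blend of water supply and energy demand
  expect_gt(cor(a$AET, a$MAP), 0.3)
  expect_gt(cor(a$AET, a$MAT), 0.3)
  expect_true(all(a$AET <= a$MAP + 1e-9))

  # zero marginal variance collapses the field to its mean
  sc0 <- small_scenario()
  sc0$grf$MAT["sd"] <- 0
  expect_equal(unique(make_climate_fields(sc0, seed = 1)$MAT), 10)

  expect_error(leaf_scenario(grf = list(MAT = c(mean = 0, sd = 1,
                                                range = -5))),
               "range")
})

test_that("a vanishing correlation range gives spatially white fields", {
  grid <- grid_spec(40, 40, cell_km = 50)
  cc <- cell_centres(grid)
  # rook-neighbour weights for the lag-1 Moran's I oracle (ape::Moran.I)
  w <- outer(seq_len(nrow(cc)), seq_len(nrow(cc)), function(i, j) {
    (abs(cc$x[i] - cc$x[j]) + abs(cc$y[i] - cc$y[j])) == grid$cell_km
  }) * 1
  set.seed(44)
  I <- replicate(10, {
    z <- simulate_grf(cc[, c("x", "y")], range_km = 1e-6)
    ape::Moran.I(drop(z), w)$observed
  })
  expect_lt(abs(mean(I)), 0.05)

  # and a long range gives strong positive lag-1 autocorrelation
  z <- simulate_grf(cc[, c("x", "y")], range_km = 500, seed = 45)
  expect_gt(ape::Moran.I(drop(z), w)$observed, 0.5)
})

test_that("species pools couple niche optima to leaf size as configured", {
  sc <- leaf_scenario(n_species = 1000, seed = 46)
  pool <- make_species_pool(sc, seed = 46)
  expect_gt(cor(pool$niche$length_med, pool$niche$optimum,
                method = "spearman"), 0.5)
  expect_true(all(pool$traits$length_min <= pool$traits$length_max))
  expect_true(all(pool$traits$length_min > 0))
  # species median = range midpoint by construction
  expect_equal((pool$traits$length_min + pool$traits$length_max) / 2,
               pool$niche$length_med, tolerance = 1e-12)

  sc0 <- leaf_scenario(n_species = 1000, niche_coupling = 0, seed = 47)
  pool0 <- make_species_pool(sc0, seed = 47)
  expect_lt(abs(cor(log(pool0$niche$length_med), pool0$niche$optimum)), 0.1)

  one <- make_species_pool(leaf_scenario(n_species = 1, seed = 1), seed = 1)
  expect_equal(nrow(one$traits), 1L)
})

test_that("range sampling is seeded, bounded and saturates with breadth", {
  sc <- small_scenario()
  pool <- make_species_pool(sc, seed = 48)
  clim <- make_climate_fields(sc, seed = 48)
  p1 <- make_ranges(pool, clim, sc, seed = 49)
  p2 <- make_ranges(pool, clim, sc, seed = 49)
  expect_identical(p1, p2)
  expect_true(all(colSums(p1) >= 1))             # every species somewhere

  wide <- small_scenario(niche_breadth = 1e9)
  poolw <- make_species_pool(wide, seed = 50)
  pw <- make_ranges(poolw, clim, wide, seed = 50)
  expect_true(all(pw))                           # saturating limit

  # the community trait surface rises with AET (the core assumed structure)
  cells <- community_trait_table(p1, pool$traits, clim)
  ok <- cells$richness >= 20
  expect_gt(cor(cells$mean_length[ok], cells$AET[ok], method = "spearman"),
            0.7)
})

test_that("phylogeny simulation is reproducible with calibrated signal", {
  sc <- small_scenario()
  ph1 <- make_phylogeny(sc, seed = 51, n_tips = 40)
  ph2 <- make_phylogeny(sc, seed = 51, n_tips = 40)
  expect_identical(ape::write.tree(ph1$tree), ape::write.tree(ph2$tree))
  expect_identical(ph1$trait, ph2$trait)
  expect_true(ape::is.ultrametric(ph1$tree, tol = 1e-6))
  expect_error(make_phylogeny(sc, n_tips = 2), "3 taxa")
  expect_error(leaf_scenario(birth = 0.1, death = 0.2), "birth rate")
})

test_that("productivity generation reports noise-induced violations", {
  sc <- leaf_scenario(noise_frac = 0.25, seed = 52)
  x <- runif(500, 2.6, 11.0)
  gen <- make_productivity(data.frame(cell_id = seq_along(x) - 1L,
                                      mean_length = x), sc, seed = 52)
  expect_true(is.numeric(attr(gen, "n_negative")))
  expect_error(validate_cell_table(gen), "productivity invariant")

  sc0 <- leaf_scenario(noise_frac = 0, seed = 53)
  gen0 <- make_productivity(data.frame(cell_id = seq_along(x) - 1L,
                                       mean_length = x), sc0, seed = 53)
  expect_equal(attr(gen0, "n_negative"), 0L)
  expect_true(validate_cell_table(gen0))

  # per-year stacks average back to the annual value in expectation
  gen_y <- make_productivity(data.frame(cell_id = seq_along(x) - 1L,
                                        mean_length = x), sc0, seed = 53,
                             years = TRUE)
  stack <- attr(gen_y, "gpp_years")
  expect_equal(dim(stack), c(500L, 16L))
  expect_equal(mean(rowMeans(stack) - gen_y$GPP), 0, tolerance = 1)
})
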