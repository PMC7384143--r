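make_traits <- function() {
  data.frame(species = c("s1", "s2", "s3", "s4"),
             habit = c("tree", "tree", "shrub", "liana"),
             phenology = c("deciduous", "evergreen", "unknown", "deciduous"),
             length_min = c(4, 8, 0.5, NA), length_max = c(10, 12, 1.5, 6),
             width_min = c(2, 6, 0.2, 1), width_max = c(6, 10, 0.6, 3))
}

test_that("species scalars collapse flora ranges to midpoint or maximum", {
  tr <- make_traits()
  med <- species_trait_scalars(tr, "length", "median")
  expect_equal(med$value[med$species == "s1"], 7)
  expect_equal(attr(med, "n_skipped"), 1L)   # s4 lacks length_min

  mx <- species_trait_scalars(tr, "length", "maximum")
  expect_equal(mx$value[mx$species == "s1"], 10)

  lw <- species_trait_scalars(tr, "lw_product", "median")
  expect_equal(lw$value[lw$species == "s2"], (2 / 3) * 10 * 8)

  bad <- tr; bad$length_min[1] <- 20
  expect_error(species_trait_scalars(bad, "length"), "invalid trait ranges")
})

test_that("leaf area proxy is exact, symmetric and configurable", {
  expect_identical(leaf_area_proxy(9, 4), 24)
  expect_identical(leaf_area_proxy(4, 9), leaf_area_proxy(9, 4))
  expect_identical(leaf_area_proxy(8, 2, factor = 3 / 4), 12)
  expect_error(leaf_area_proxy(-1, 2), "positive")
})

test_that("community means are unweighted and respect life-form filters", {
  tr <- make_traits()
  pm <- matrix(c(TRUE, FALSE, TRUE, FALSE,    # cell 0: s1, s3
                 TRUE, TRUE,  TRUE, FALSE,    # cell 1: s1, s2, s3
                 FALSE, FALSE, FALSE, FALSE), # cell 2: empty
               nrow = 3, byrow = TRUE,
               dimnames = list(c("0", "1", "2"), tr$species))
  class(pm) <- c("presence_matrix", class(pm))
  sc <- species_trait_scalars(tr, "length", "median")  # 7, 10, 1
  cm <- community_mean(pm, sc)
  expect_equal(cm$mean_value, c((7 + 1) / 2, (7 + 10 + 1) / 3, NA))
  expect_equal(cm$n_contributing, c(2L, 3L, 0L))

  trees <- community_mean(pm, sc, traits = tr, habit = "tree")
  expect_equal(trees$mean_value[2], (7 + 10) / 2)

  # single-species cell returns that species' value
  solo <- pm; solo["0", ] <- c(FALSE, TRUE, FALSE, FALSE)
  expect_equal(community_mean(solo, sc)$mean_value[1], 10)

  # cell means bounded by the min/max species value present
  expect_true(all(cm$mean_value >= 1 & cm$mean_value <= 10, na.rm = TRUE))
})

test_that("all-species mean equals the richness-weighted habit-subset mean", {
  set.seed(21)
  sc <- small_scenario()
  pool <- make_species_pool(sc, seed = 7)
  clim <- make_climate_fields(sc, seed = 7)
  pm <- make_ranges(pool, clim, sc, seed = 7)
  scal <- species_trait_scalars(pool$traits, "length", "median")

  all_sp <- community_mean(pm, scal)
  parts <- lapply(c("tree", "shrub", "liana"), function(h)
    community_mean(pm, scal, traits = pool$traits, habit = h))
  num <- Reduce(`+`, lapply(parts, function(p)
    ifelse(p$n_contributing > 0, p$mean_value * p$n_contributing, 0)))
  den <- Reduce(`+`, lapply(parts, function(p) p$n_contributing))
  ok <- all_sp$n_contributing > 0
  expect_equal(num[ok] / den[ok], all_sp$mean_value[ok], tolerance = 1e-12)
})

test_that("length, width and area surfaces are strongly rank-correlated", {
  sc <- small_scenario()
  reg <- leafprod:::simulate_region(sc, sc$seed)
  cells <- filter_richness(reg$cells, 20)
  expect_gt(cor(cells$mean_length, cells$mean_width, method = "spearman"),
            0.8)
  expect_gt(cor(cells$mean_length, cells$mean_lw_product,
                method = "spearman"), 0.8)
})
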