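test_that("Blomberg's K is exactly 1 on a star phylogeny and is affine-invariant", {
  tr <- star_tree(8)
  y <- c(3, 1, 4, 1, 5, 9, 2, 6)
  names(y) <- tr$tip.label
  expect_equal(blomberg_k(tr, y)$K, 1, tolerance = 1e-12)

  set.seed(22)
  bd <- ape::rphylo(40, 0.2, 0.05)
  trait <- ape::rTraitCont(bd)
  k0 <- blomberg_k(bd, trait)$K
  expect_equal(blomberg_k(bd, 5 * trait - 2)$K, k0, tolerance = 1e-10)
  shuffled <- trait[sample(names(trait))]
  expect_equal(blomberg_k(bd, shuffled)$K, k0, tolerance = 1e-10)

  expect_error(blomberg_k(bd, trait[1:2]), "matched taxa")
})

test_that("K agrees with the reference phylogenetics implementation", {
  skip_if_not_installed("phytools")
  set.seed(23)
  for (i in 1:3) {
    tr <- ape::rphylo(60, 0.2, 0.05)
    y <- ape::rTraitCont(tr)
    expect_equal(blomberg_k(tr, y)$K,
                 unname(phytools::phylosig(tr, y, method = "K")[[1]]),
                 tolerance = 1e-6)
  }
})

test_that("Brownian traits centre K near 1 and white noise suppresses it", {
  sc <- small_scenario(signal_weight = 1)
  set.seed(24)
  ks <- replicate(60, {
    ph <- make_phylogeny(sc, seed = sample.int(1e6, 1), n_tips = 80)
    blomberg_k(ph$tree, ph$trait)$K
  })
  expect_gt(mean(ks), 0.7)
  expect_lt(mean(ks), 1.3)

  sc0 <- small_scenario(signal_weight = 0)
  set.seed(25)
  kw <- replicate(40, {
    ph <- make_phylogeny(sc0, seed = sample.int(1e6, 1), n_tips = 80)
    blomberg_k(ph$tree, ph$trait)$K
  })
  expect_lt(median(kw), 0.5)
})

test_that("the permutation test is seeded, calibrated and powered", {
  set.seed(26)
  tr <- ape::rphylo(50, 0.2, 0.05)
  y <- rnorm(50); names(y) <- tr$tip.label
  p1 <- blomberg_k_test(tr, y, n_perm = 199, seed = 99)$p
  p2 <- blomberg_k_test(tr, y, n_perm = 199, seed = 99)$p
  expect_identical(p1, p2)
  expect_warning(blomberg_k_test(tr, y, n_perm = 50, seed = 1), "coarse")

  # strong Brownian signal is detected
  set.seed(27)
  hits <- replicate(20, {
    tr <- ape::rphylo(80, 0.2, 0.05)
    bm <- ape::rTraitCont(tr)
    blomberg_k_test(tr, bm, n_perm = 199, seed = 5)$p <= 0.05
  })
  expect_gte(mean(hits), 0.9)
})

test_that("cell mean clade ages follow the species-level convention", {
  pm <- matrix(c(TRUE, TRUE, FALSE, FALSE, FALSE,
                 FALSE, FALSE, TRUE, TRUE, TRUE,
                 FALSE, FALSE, FALSE, FALSE, FALSE),
               nrow = 3, byrow = TRUE,
               dimnames = list(c("0", "1", "2"), paste0("s", 1:5)))
  class(pm) <- c("presence_matrix", class(pm))
  cmap <- data.frame(species = paste0("s", 1:5),
                     clade = c("famA", "famB", "genC", "genC", "genC"))
  ages <- data.frame(clade = c("famA", "famB", "genC"), age = c(100, 60, 40))
  out <- cell_mean_clade_age(pm, cmap, ages)
  expect_equal(out$mean_clade_age, c(80, 40, NA))
  expect_true(all(out$mean_clade_age >= 40 & out$mean_clade_age <= 100,
                  na.rm = TRUE))
  expect_error(cell_mean_clade_age(pm, cmap,
                                   transform(ages, age = c(-1, 60, 40))),
               "must be > 0")
})

test_that("clade delimitation reads stem ages off the dated tree", {
  sc <- small_scenario()
  ph <- make_phylogeny(sc, seed = 30, n_tips = 50)
  H <- max(ape::node.depth.edgelength(ph$tree))
  cl <- clade_table(ph$tree, cut_age = H / 3)
  expect_setequal(cl$map$species, ph$tree$tip.label)
  expect_true(all(cl$ages$age >= H / 3 - 1e-9))
  expect_true(all(cl$ages$age <= H + 1e-9))
  expect_equal(anyDuplicated(cl$map$species), 0L)
})

test_that("the age x leaf-size interaction regression recovers signs", {
  set.seed(31)
  n <- 1000
  run <- function(beta_int) {
    size <- rnorm(n); age <- rnorm(n)
    y <- 1.0 * size + 0.2 * age + beta_int * size * age + rnorm(n)
    fit <- age_interaction_model(y, size, age)
    fit$coefficients[fit$coefficients$term == "interaction", ]
  }
  null_t <- replicate(30, abs(run(0)$t))
  expect_gte(mean(null_t < 2), 0.85)

  neg_sign <- replicate(30, run(-0.2)$estimate < 0)
  expect_gte(mean(neg_sign), 0.95)

  expect_error(age_interaction_model(rnorm(50), rnorm(50), rep(3, 50)),
               "zero-variance")
})
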