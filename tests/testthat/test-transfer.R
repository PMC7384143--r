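tbl1_gpp_length <- logistic_params(11.602, 1.470, 0.002)

test_that("the inverse-logistic evaluates the printed closed form", {
  p <- tbl1_gpp_length
  m <- structure(list(form = "inv_logistic", params = p),
                 class = "transfer_model")
  # direct high-precision evaluation of (1/r)(alpha - ln(K/x - 1)) at x = 5
  expect_equal(as.numeric(predict_transfer(m, 5)), 596.0326,
               tolerance = 1e-4)
  # closed-form root: x = K/(1 + e^alpha) gives y = 0
  x0 <- p$K / (1 + exp(p$alpha))
  expect_equal(as.numeric(predict_transfer(m, x0)), 0, tolerance = 1e-10)
  # out-of-domain values are NA with a count, never extrapolated
  expect_warning(out <- predict_transfer(m, c(5, 12, -1)))
  expect_equal(is.na(out), c(FALSE, TRUE, TRUE))
  expect_equal(attr(out, "n_out_of_domain"), 2L)
})

test_that("noiseless transfer fits recover the generating parameters", {
  set.seed(14)
  x <- runif(500, 2.5, 11.3)
  p <- tbl1_gpp_length
  y <- (p$alpha - log(p$K / x - 1)) / p$r
  m <- fit_transfer(x, y, trait = "length", productivity = "GPP")
  expect_rel_equal(c(m$params$K, m$params$alpha, m$params$r),
                   c(p$K, p$alpha, p$r), 1e-3)
  expect_gt(m$r2, 1 - 1e-10)

  # forward logistic and inverse transfer are mutual inverses on training x
  yhat <- predict_transfer(m, x)
  expect_lt(max(abs(yhat - y)), 1e-6 * diff(range(y)))

  lin <- fit_transfer(x, 100 + 50 * x, form = "linear")
  expect_equal(unname(lin$params), c(100, 50), tolerance = 1e-9)

  # non-positive trait values are excluded, not fitted
  m0 <- fit_transfer(c(x, 0), c(y, 100))
  expect_equal(m0$n_excluded, 1L)
  expect_equal(m0$n, length(x))
})

test_that("transfer evaluation implements the SE and SE% definitions", {
  ev <- evaluate_transfer(c(1, 9), c(0, 10))
  expect_equal(ev$se, sqrt(2), tolerance = 1e-12)
  expect_equal(ev$se_pct, 100 * sqrt(2) / 10, tolerance = 1e-12)

  y <- c(3, 7, 1, 9, 4)
  perfect <- evaluate_transfer(y, y)
  expect_equal(perfect$se, 0)
  expect_equal(perfect$r2, 1)

  off <- evaluate_transfer(y + 2, y)
  expect_equal(off$se, 2 * sqrt(5 / 4), tolerance = 1e-12)

  # scale covariance: scaling both by c scales SE by c, leaves SE% alone
  sc <- evaluate_transfer(3 * (y + 0.5), 3 * y)
  base <- evaluate_transfer(y + 0.5, y)
  expect_equal(sc$se, 3 * base$se, tolerance = 1e-12)
  expect_equal(sc$se_pct, base$se_pct, tolerance = 1e-12)
})

test_that("models survive a JSON round trip and cross-region application", {
  set.seed(15)
  sc <- leaf_scenario(seed = 15)
  xA <- runif(800, 2.5, 11.3)
  cellsA <- data.frame(cell_id = seq_along(xA) - 1L, mean_length = xA)
  genA <- make_productivity(cellsA, sc, seed = 16)
  m <- fit_transfer(genA$mean_length, genA$GPP, trait = "length",
                    productivity = "GPP", region = "A")

  path <- tempfile(fileext = ".json")
  write_transfer_json(m, path)
  m2 <- read_transfer_json(path)
  expect_equal(m2$params$K, m$params$K)
  expect_equal(m2$trait, "length")

  # self-consistency: region B generated with the same parameters, no noise
  sc0 <- leaf_scenario(noise_frac = 0, seed = 17)
  xB <- runif(400, 2.5, 11.3)
  cellsB <- data.frame(cell_id = seq_along(xB) - 1L, mean_length = xB)
  genB <- make_productivity(cellsB, sc0, seed = 18)
  mB <- fit_transfer(genB$mean_length, genB$GPP)
  cv <- cross_region_validate(mB, genB, "mean_length", "GPP")
  expect_equal(cv$evaluation$slope, 1, tolerance = 1e-6)
  expect_lt(cv$evaluation$se, 1e-6)

  # permuted-trait null: predictions from shuffled traits explain nothing
  set.seed(19)
  genB_null <- genB
  genB_null$mean_length <- sample(genB$mean_length)
  cvn <- cross_region_validate(mB, genB_null, "mean_length", "GPP")
  expect_lt(cvn$evaluation$r2, 0.1)
})

test_that("generated productivity matches the formula and refits cleanly", {
  sc0 <- leaf_scenario(noise_frac = 0, seed = 20)
  cells <- data.frame(cell_id = 0:2, mean_length = c(5, 7, 9))
  gen <- make_productivity(cells, sc0, seed = 20)
  expect_equal(gen$GPP[1], 596.0326, tolerance = 1e-4)

  expect_error(
    make_productivity(data.frame(cell_id = 0:1, mean_length = c(5, 12)),
                      sc0, seed = 20),
    "trait mean >= K")

  # round trip at zero noise: every fitted family recovers its parameters
  set.seed(21)
  x <- runif(300, 2.5, 11.3)
  gen2 <- make_productivity(
    data.frame(cell_id = seq_along(x) - 1L, mean_length = x), sc0, seed = 21)
  for (col in c("GPP", "NPP")) {
    p <- sc0$transfer[[col]]$length
    m <- fit_transfer(x, gen2[[col]])
    expect_rel_equal(c(m$params$K, m$params$alpha, m$params$r),
                     c(p$K, p$alpha, p$r), 1e-3)
  }
})
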