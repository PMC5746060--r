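test_that("clean 4PL data are recovered exactly, including the in vivo case", {
  x <- 10^seq(-1, 3, length.out = 9)          # nM
  y <- 0 + (100 - 0) / (1 + (x / 2.7)^1)      # IC50 2.7 nM, Hill 1
  fit <- fit_ic50(x, y)
  expect_true(fit$converged)
  expect_equal(fit$ic50, 2.7, tolerance = 1e-6)
  expect_equal(fit$hill, 1, tolerance = 1e-6)
  expect_equal(fit$top, 100, tolerance = 1e-5)
  expect_equal(fit$bottom, 0, tolerance = 1e-4)
  # fixed-plateau variant
  fit2 <- fit_ic50(x, y, fix_bottom = 0, fix_top = 100, fix_hill = 1)
  expect_equal(fit2$ic50, 2.7, tolerance = 1e-8)
  # scale invariance: responses in different units give the same IC50
  fit3 <- fit_ic50(x, y * 7.3)
  expect_equal(fit3$ic50, fit$ic50, tolerance = 1e-6)
  expect_equal(fit3$hill, fit$hill, tolerance = 1e-5)
})

test_that("unbracketed transitions are flagged, not extrapolated", {
  x <- 10^seq(-1, 3, length.out = 7)
  high <- fit_ic50(x, rep(100, 7) + c(-1, 1, 0, -2, 1, 0, -1))
  expect_identical(high$out_of_range, "above")
  expect_true(is.na(high$ic50))
  low <- fit_ic50(x, c(2, 1, 3, 2, 1, 2, 1), fix_top = 100)
  expect_identical(low$out_of_range, "below")
})

test_that("steady-state noncompetitive responses yield IC50 = Ki", {
  sc <- scheme_compound11()
  x <- 10^seq(0, 3.5, length.out = 10)
  v0 <- steady_rate(sc, S = 10, I = 0, E0 = 1)
  y <- 100 * steady_rate(sc, S = 10, I = x, E0 = 1) / v0
  fit <- fit_ic50(x, y)
  expect_equal(fit$ic50, 45, tolerance = 0.02 * 45)
  expect_equal(fit$ic50, ic50_from_scheme(sc, S = 10), tolerance = 1e-4)
})

test_that("band conversions normalize to the vehicle lane", {
  # uninhibited conversion ~75%, as in the in vivo knockout-corrected assay
  conv <- c(75, 60, 30, 10, 2) / 100
  bt <- band_table(condition = c("DMSO", "10nM", "30nM", "100nM", "300nM"),
                   inhibitor = c(0, 10, 30, 100, 300),
                   substrate_au = 100 * (1 - conv),
                   product_au = 100 * conv)
  d <- conversion_from_bands(bt)
  expect_equal(d$conversion, conv)
  expect_equal(d$response, c(100, 80, 40, 13 + 1 / 3, 2 + 2 / 3),
               tolerance = 1e-10)
  # degenerate lanes
  expect_equal(conversion_from_bands(
    band_table("DMSO", 0, 50, 50))$conversion, 0.5)
  expect_equal(conversion_from_bands(
    band_table(c("DMSO", "x"), c(0, 10), c(50, 80), c(50, 0)))$conversion,
    c(0.5, 0))
  expect_error(conversion_from_bands(
    band_table("treated", 10, 50, 50)), "vehicle")
  expect_warning(conversion_from_bands(
    band_table(c("DMSO", "bad"), c(0, 10), c(50, 0), c(50, 0))), "zero")
})

test_that("knockout background subtraction clamps at zero and reports", {
  obs <- band_table(c("DMSO", "a", "b"), c(0, 10, 100),
                    substrate_au = c(20, 40, 80),
                    product_au = c(100, 60, 20))
  ko <- band_table(c("DMSO", "a", "b"), c(0, 10, 100),
                   substrate_au = c(0, 0, 0),
                   product_au = c(30, 30, 30))
  expect_warning(corr <- correct_background(obs, ko), "clamped")
  expect_equal(corr$product_au, c(70, 30, 0))
  expect_equal(attr(corr, "correction"), c(30, 30, 30))
  # zero knockout intensity is the identity
  ko0 <- band_table(c("DMSO", "a", "b"), c(0, 10, 100),
                    substrate_au = c(0, 0, 0), product_au = c(0, 0, 0))
  expect_equal(correct_background(obs, ko0)$product_au, obs$product_au)
  # unmatched lanes error, naming the concentration
  expect_error(correct_background(obs, ko[1:2, ]), "100")
})

test_that("probe-competition percent inhibition is the normalized complement", {
  expect_equal(abp_percent_inhibition(100, 100), 0)
  expect_equal(abp_percent_inhibition(0, 100), 100)
  expect_equal(abp_percent_inhibition(25, 100), 75)
  # matrix form for (compound x enzyme) selectivity tables
  m <- matrix(c(25, 50, 100, 150), 2)
  expect_equal(abp_percent_inhibition(m, 100),
               matrix(c(75, 50, 0, 0), 2))
  expect_error(abp_percent_inhibition(10, 0), "> 0")
})
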