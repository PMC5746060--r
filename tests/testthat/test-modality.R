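test_that("every generating modality is re-selected from clean grids", {
  md <- michaelis_design()
  for (mod in c("competitive", "noncompetitive", "uncompetitive", "mixed")) {
    sc <- kinetic_scheme(mod, Ki = 45, koff = 3.9e-3, Km = 5, kcat = 2,
                         alpha = if (mod == "mixed") 4 else 1)
    mg <- simulate_michaelis_grid(sc, sigma_rel = 0)
    res <- suppressWarnings(global_fit_modality(mg))
    expect_identical(res$selected, mod)
    expect_equal(res$Ki_true, 45, tolerance = 1e-5)
    expect_equal(res$Km, 5, tolerance = 1e-5)
    expect_equal(res$Vmax, 2 * 1, tolerance = 1e-5)
    if (mod == "mixed") expect_equal(res$alpha, 4, tolerance = 1e-4)
  }
})

test_that("noncompetitive data leave the apparent Km invariant across [I]", {
  sc <- scheme_compound11()
  md <- michaelis_design()
  # per-concentration Michaelis fits: Km_app spread < 1e-3 relative
  Km_app <- vapply(md$inhibitor_nM, function(I) {
    v <- steady_rate(sc, md$substrate_uM, I, 1)
    fit <- minpack.lm::nlsLM(v ~ Vm * S / (Km + S),
                             data = data.frame(S = md$substrate_uM, v = v),
                             start = list(Vm = max(v) * 1.5, Km = 5))
    coef(fit)[["Km"]]
  }, 0)
  expect_lt(diff(range(Km_app)) / mean(Km_app), 1e-3)
  # competitive data instead show Km_app rising with [I] at constant Vmax
  comp <- kinetic_scheme("competitive", Ki = 45, koff = 3.9e-3,
                         Km = 5, kcat = 2)
  fits <- lapply(md$inhibitor_nM, function(I) {
    v <- steady_rate(comp, md$substrate_uM, I, 1)
    coef(minpack.lm::nlsLM(v ~ Vm * S / (Km + S),
                           data = data.frame(S = md$substrate_uM, v = v),
                           start = list(Vm = max(v) * 1.5, Km = 5)))
  })
  expect_true(all(diff(vapply(fits, `[[`, 0, "Km")) > 0))
  expect_lt(diff(range(vapply(fits, `[[`, 0, "Vm"))) / 2, 1e-3)
})

test_that("grid validation enforces the minimum design", {
  expect_error(michaelis_grid(c(1, 2, 3, 4), rep(10, 4), 1:4),
               "inhibitor levels")
  expect_error(michaelis_grid(rep(c(1, 2), 6), rep(c(0, 10, 20), 4),
                              rep(1, 12)), "substrate levels")
})

test_that("apparent-to-true Ki conversion follows the modality", {
  expect_equal(ki_from_kiapp(123, "noncompetitive"), 123)
  expect_equal(ki_from_kiapp(90, "competitive", S = 5, Km = 5), 45)
  expect_equal(ki_from_kiapp(100, "uncompetitive", S = 5000, Km = 5),
               100, tolerance = 1e-2)
  expect_error(ki_from_kiapp(100, "mixed", S = 5, Km = 5), "alpha")
  expect_error(ki_from_kiapp(100, "competitive"), "requires")
  # round trip through the scheme's own apparent constant is the identity
  for (mod in c("competitive", "noncompetitive", "uncompetitive", "mixed")) {
    sc <- kinetic_scheme(mod, Ki = 45, koff = 3.9e-3, Km = 5, kcat = 2,
                         alpha = if (mod == "mixed") 0.3 else 1)
    S <- 17
    expect_equal(ki_from_kiapp(kiapp_from_scheme(sc, S), mod, S = S,
                               Km = 5, alpha = sc$alpha), 45,
                 tolerance = 1e-10)
  }
})

test_that("steady-state IC50 matches the closed form and the numeric root", {
  ncomp <- kinetic_scheme("noncompetitive", Ki = 45, koff = 3.9e-3,
                          Km = 5, kcat = 2)
  for (S in c(1, 5, 40))
    expect_equal(ic50_from_scheme(ncomp, S), 45)
  comp <- kinetic_scheme("competitive", Ki = 45, koff = 3.9e-3,
                         Km = 5, kcat = 2)
  expect_equal(ic50_from_scheme(comp, S = 5), 90)
  for (sc in list(ncomp, comp))
    expect_equal(ic50_from_scheme(sc, S = 12, numeric = TRUE),
                 ic50_from_scheme(sc, S = 12), tolerance = 1e-8)
})

test_that("modality is recovered from noisy grids at a high rate", {
  sc <- scheme_compound11()
  hits <- 0L
  Ki_hat <- numeric(40)
  for (s in 1:40) {
    mg <- simulate_michaelis_grid(sc, sigma_rel = 0.03, seed = s)
    res <- suppressWarnings(global_fit_modality(mg))
    if (res$selected == "noncompetitive") hits <- hits + 1L
    Ki_hat[s] <- res$Ki_true
  }
  expect_gte(hits / 40, 0.9)
  expect_lt(abs(median(Ki_hat) - 45), 8)
})
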