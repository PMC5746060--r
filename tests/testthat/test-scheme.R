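test_that("scheme construction enforces the parameter invariants", {
  sc <- kinetic_scheme("noncompetitive", Ki = 120, koff = 4.2e-3,
                       Km = 10, kcat = 2)
  expect_equal(sc$kon, 4.2e-3 / 120)
  expect_equal(sc$alpha, 1)                  # forced for noncompetitive
  expect_error(kinetic_scheme("noncompetitive", Ki = -1, koff = 1e-3,
                              Km = 10, kcat = 2), "Ki")
  expect_error(kinetic_scheme("mixed", Ki = 10, koff = 1e-3, alpha = 0,
                              Km = 10, kcat = 2), "alpha")
  expect_error(kinetic_scheme("noncompetitive", Ki = 10, koff = 1e-3,
                              Km = 10, kcat = 2, k5 = 1), "two_step")
  expect_error(kinetic_scheme("noncompetitive", Ki = 10, koff = 1e-3,
                              Km = 10, kcat = 2, two_step = TRUE),
               "requires")
  # explicit kon override (irreversible mimic: koff = 0, kon > 0)
  irr <- kinetic_scheme("noncompetitive", Ki = 120, koff = 0,
                        kon = 3.5e-5, Km = 10, kcat = 2)
  expect_equal(irr$kon, 3.5e-5)
})

test_that("steady-state rate law reproduces its closed-form special cases", {
  sc <- kinetic_scheme("noncompetitive", Ki = 45, koff = 3.9e-3,
                       Km = 5, kcat = 2)
  # half-saturation without inhibitor
  expect_equal(steady_rate(sc, S = 5, I = 0, E0 = 1), 2 * 1 / 2)
  # noncompetitive at I = Ki halves the rate at any substrate level
  for (S in c(0.5, 5, 50))
    expect_equal(steady_rate(sc, S, I = 45, E0 = 1),
                 steady_rate(sc, S, I = 0, E0 = 1) / 2)
  # competitive at I = Ki, S = Km: denominator Km(1+1) + Km = 3 Km
  comp <- kinetic_scheme("competitive", Ki = 45, koff = 3.9e-3,
                         Km = 5, kcat = 2)
  expect_equal(steady_rate(comp, S = 5, I = 45, E0 = 1), 2 * 1 / 3)
  expect_error(steady_rate(sc, S = -1, I = 0, E0 = 1), ">= 0")
  expect_error(steady_rate(sc, S = 1, I = -5, E0 = 1), ">= 0")
})

test_that("steady rate is monotone in inhibitor and substrate", {
  for (mod in c("competitive", "noncompetitive", "uncompetitive", "mixed")) {
    sc <- kinetic_scheme(mod, Ki = 100, koff = 5e-3, Km = 8, kcat = 1.5,
                         alpha = if (mod == "mixed") 3 else 1)
    I <- seq(0, 2000, length.out = 40)
    v <- steady_rate(sc, S = 10, I = I, E0 = 1)
    expect_true(all(diff(v) < 0))
    S <- seq(0.1, 100, length.out = 40)
    v2 <- steady_rate(sc, S = S, I = 50, E0 = 1)
    expect_true(all(diff(v2) > 0))
    expect_true(all(v >= 0) && all(v2 >= 0))
  }
})

test_that("one-step kobs is affine in inhibitor with the published slope", {
  sc <- scheme_compound10()
  expect_equal(kobs_predict(sc, S = 25, I = 0), 4.2e-3)
  # noncompetitive: kon_eff = kon regardless of substrate
  expect_equal(kobs_predict(sc, S = 25, I = 1333),
               4.2e-3 + (4.2e-3 / 123) * 1333)
  expect_equal(kobs_predict(sc, S = 25, I = 1333), 4.972e-2,
               tolerance = 1e-3)
  # at I = Ki, kobs is exactly 2 koff
  expect_equal(kobs_predict(sc, S = 25, I = 123), 2 * 4.2e-3)
  # exact affinity of the law over a grid
  I <- c(0, 10, 50, 250, 1000)
  k <- kobs_predict(sc, S = 25, I = I)
  expect_equal(k, 4.2e-3 + (4.2e-3 / 123) * I)
})

test_that("substrate competition attenuates kon as the modality dictates", {
  args <- list(Ki = 100, koff = 5e-3, Km = 10, kcat = 2)
  comp <- do.call(kinetic_scheme, c(list("competitive"), args))
  unc  <- do.call(kinetic_scheme, c(list("uncompetitive"), args))
  mix  <- do.call(kinetic_scheme, c(list("mixed"), args, alpha = 2))
  S <- 30
  kon <- 5e-3 / 100
  expect_equal(kobs_predict(comp, S, 100) - 5e-3, kon / (1 + S / 10) * 100)
  expect_equal(kobs_predict(unc, S, 100) - 5e-3, kon / (1 + 10 / S) * 100)
  fE <- 10 / 40; fES <- 30 / 40
  expect_equal(kobs_predict(mix, S, 100) - 5e-3,
               kon * (fE + fES / 2) * 100)
  # Kiapp = koff/kon_eff closed forms
  expect_equal(kiapp_from_scheme(comp, S), 100 * (1 + S / 10))
  expect_equal(kiapp_from_scheme(unc, S), 100 * (1 + 10 / S))
})

test_that("two-step kobs saturates hyperbolically", {
  sc <- kinetic_scheme("noncompetitive", Ki = 50, koff = 1e-3, Km = 10,
                       kcat = 2, two_step = TRUE, k5 = 0.05, k6 = 1e-3,
                       Ki1 = 200)
  expect_equal(kobs_predict(sc, S = 25, I = 0), 1e-3)
  expect_equal(kobs_predict(sc, S = 25, I = 1e9), 1e-3 + 0.05,
               tolerance = 1e-6)
  k <- kobs_predict(sc, S = 25, I = c(10, 100, 1000, 1e4))
  expect_true(all(diff(k) > 0))
})
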