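test_that("closed-form curve matches numerical quadrature of the rate law", {
  sc <- scheme_compound10()
  des <- design_progress()
  I <- 444
  curve <- closed_form_curve(sc, des, I)
  # independent oracle: quadrature of dP/dt = vs + (vi - vs) exp(-kobs t)
  vi <- steady_rate(sc, des$S0, 0, des$E0)
  vs <- steady_rate(sc, des$S0, I, des$E0)
  kobs <- kobs_predict(sc, des$S0, I)
  P_quad <- vapply(des$t_grid, function(tt) {
    if (tt == 0) return(0)
    stats::integrate(function(u) vs + (vi - vs) * exp(-kobs * u),
                     0, tt, rel.tol = 1e-12)$value
  }, 0)
  expect_equal(curve$signal_au, des$gain * P_quad / 1000,
               tolerance = 1e-8)
})

test_that("uninhibited closed-form curve is exactly linear", {
  sc <- scheme_compound10()
  des <- design_progress()
  curve <- closed_form_curve(sc, des, 0)
  vi <- steady_rate(sc, des$S0, 0, des$E0)
  expect_equal(curve$signal_au, des$gain * vi * des$t_grid / 1000)
  expect_equal(curve$signal_au[1], des$baseline)
})

test_that("kobs -> 0 limit of the biphasic law recovers the linear curve", {
  # vanishing onset rate: inhibition never develops within the window
  sc <- kinetic_scheme("noncompetitive", Ki = 1e8, koff = 1e-9,
                       Km = 10, kcat = 2)
  des <- design_progress()
  curve <- closed_form_curve(sc, des, 1)   # kobs ~ 1e-9
  vi <- steady_rate(sc, des$S0, 0, des$E0)
  lin <- des$gain * vi * des$t_grid / 1000
  expect_equal(curve$signal_au[-1], lin[-1], tolerance = 1e-4)
})

test_that("ODE and closed-form simulations agree under low conversion", {
  sc <- scheme_compound10()
  des <- design_progress()
  for (I in c(0, 49.4, 1333)) {
    c_cf <- closed_form_curve(sc, des, I)
    c_ode <- ode_curve(sc, des, I)
    dev <- max(abs(c_cf$signal_au - c_ode$signal_au)) /
      max(c_ode$signal_au)
    expect_lt(dev, 0.01)
    expect_lt(attr(c_ode, "mass_violation"), 1e-6)
  }
})

test_that("uninhibited ODE trajectory is linear at low conversion", {
  sc <- scheme_compound10()
  des <- design_progress()
  curve <- ode_curve(sc, des, 0)
  v0 <- steady_rate(sc, des$S0, 0, des$E0)        # nM/min
  conversion <- max(curve$signal_au) / des$gain / des$S0
  expect_lt(conversion, 0.05)
  expect_equal(curve$signal_au[-1],
               (des$gain * v0 / 1000) * des$t_grid[-1],
               tolerance = 0.01)
})

test_that("two-step ODE with k5 = 0 and Ki1 = Ki collapses to one-step", {
  one <- kinetic_scheme("noncompetitive", Ki = 120, koff = 4.2e-3,
                        Km = 10, kcat = 2)
  # with k5 = 0 the EI* branch is dead and the first step has
  # koff1 = kon * Ki1 = koff when Ki1 = Ki
  two <- kinetic_scheme("noncompetitive", Ki = 120, koff = 4.2e-3,
                        Km = 10, kcat = 2, two_step = TRUE,
                        k5 = 0, k6 = 1e-3, Ki1 = 120)
  des <- design_progress()
  c1 <- ode_curve(one, des, 400)
  c2 <- ode_curve(two, des, 400)
  expect_equal(c1$signal_au, c2$signal_au, tolerance = 1e-8)
})

test_that("noise model is unbiased, seeded and reproducible", {
  sc <- scheme_compound10()
  des <- design_progress()
  curve <- closed_form_curve(sc, des, 148)
  # zero noise is the identity
  expect_identical(add_noise(curve, noise_model(0, 0, 1)), curve)
  # fixed seed: bit-identical repeats; different id: different stream
  nm <- noise_model(sigma_rel = 0.02, sigma_abs = 0.5, seed = 42)
  n1 <- add_noise(curve, nm)
  n2 <- add_noise(curve, nm)
  expect_identical(n1$signal_au, n2$signal_au)
  curve_b <- curve; curve_b$curve_id <- "other"
  expect_false(identical(add_noise(curve_b, nm)$signal_au, n1$signal_au))
  # absolute-noise SD check over 1e4 points
  t_long <- seq(0, 9999)
  big <- progress_curve(t_long, rep(100, length(t_long)), 0, 25, 0.5,
                        "sd_check")
  noisy <- add_noise(big, noise_model(sigma_rel = 0, sigma_abs = 1,
                                      seed = 7))
  sd_hat <- sd(noisy$signal_au - big$signal_au)
  expect_gt(sd_hat, 0.95); expect_lt(sd_hat, 1.05)
})

test_that("add_noise does not disturb the caller's RNG stream", {
  sc <- scheme_compound10()
  curve <- closed_form_curve(sc, design_progress(), 148)
  set.seed(123); before <- rnorm(3)
  set.seed(123); invisible(add_noise(curve, noise_model(0.01, 0, 5)))
  expect_identical(rnorm(3), before)
})

test_that("simulated families are complete, monotone and reproducible", {
  sc <- scheme_compound10()
  des <- design_progress()
  fam <- simulate_experiment(sc, des)
  expect_length(fam, length(des$I_grid))
  expect_identical(attr(fam, "simulator"), "closed_form")
  finals <- vapply(fam, function(cu) cu$signal_au[length(cu$signal_au)], 0)
  I <- vapply(fam, `[[`, 0, "inhibitor_nM")
  expect_true(all(diff(finals[order(I)]) < 0))
  # closed-form and ODE families agree within 1%
  fam_ode <- simulate_experiment(sc, des, simulator = "ode")
  for (id in names(fam))
    expect_lt(max(abs(fam[[id]]$signal_au - fam_ode[[id]]$signal_au)) /
                max(fam_ode[[id]]$signal_au), 0.01)
  # whole-experiment determinism under a fixed master seed
  nm <- noise_model(sigma_rel = 0.02, seed = 11)
  f1 <- simulate_experiment(sc, des, noise = nm)
  f2 <- simulate_experiment(sc, des, noise = nm)
  expect_identical(f1, f2)
})

test_that("single-concentration design yields one linear control curve", {
  sc <- scheme_compound10()
  des <- assay_design(E0 = 0.5, S0 = 25, I_grid = 0,
                      t_grid = seq(0, 60, 2))
  fam <- simulate_experiment(sc, des)
  expect_length(fam, 1L)
  expect_equal(diff(fam[[1]]$signal_au),
               rep(diff(fam[[1]]$signal_au)[1], 30), tolerance = 1e-10)
})

test_that("jump dilution relaxes to the steady rate at the diluted [I]", {
  sc <- kinetic_scheme("noncompetitive", Ki = 120, koff = 4.2e-3,
                       Km = 10, kcat = 2)
  post <- assay_design(E0 = 4, S0 = 10, I_grid = 0,
                       t_grid = seq(0, 120, 2))
  cu <- simulate_dilution(sc, pre_E0 = 400, pre_I = 1000,
                          pre_minutes = 60, dilution_factor = 100,
                          post_design = post)
  expect_equal(attr(cu, "I_diluted_nM"), 10)
  expect_gt(attr(cu, "bound_fraction_at_dilution"), 0.5)
  # late slope approaches vs(I = 10): within the window the approach is
  # incomplete (kobs ~ 4.6e-3/min), so compare against the Eq.1 expectation
  v0 <- steady_rate(sc, 10, 0, 4) * post$gain / 1000
  vs_frac <- 120 / (120 + 10)
  n <- length(cu$time_min)
  late <- (n - 5):n
  slope <- coef(lm(cu$signal_au[late] ~ cu$time_min[late]))[2]
  # mechanical bound: late slope has risen above the inhibited rate but
  # cannot exceed the steady rate at the diluted concentration
  expect_gt(slope, 0.1 * v0); expect_lt(slope, vs_frac * v0 * 1.02)
  expect_error(simulate_dilution(sc, 400, 1000, 60, 1, post),
               "dilution_factor")
})

test_that("irreversible and topped-up dilutions show no recovery", {
  post <- assay_design(E0 = 4, S0 = 10, I_grid = 0,
                       t_grid = seq(0, 120, 2))
  irr <- kinetic_scheme("noncompetitive", Ki = 120, koff = 0,
                        kon = 4.2e-3 / 120, Km = 10, kcat = 2)
  cu <- simulate_dilution(irr, 400, 1000, 60, 100, post)
  b0 <- attr(cu, "bound_fraction_at_dilution")
  # pseudo-first-order binding at kon * I_free ~ 0.028/min for 60 min
  expect_gt(b0, 0.75)
  # rate stays at the inhibited value: final slope ~ (1 - b0) * v0
  v0 <- steady_rate(irr, 10, 0, 4) * post$gain / 1000
  n <- length(cu$time_min); late <- (n - 5):n
  slope <- coef(lm(cu$signal_au[late] ~ cu$time_min[late]))[2]
  expect_lt(slope, (1 - b0) * v0 * 1.1)
  # reversible compound, dilution into inhibitor-topped-up buffer
  rev <- kinetic_scheme("noncompetitive", Ki = 120, koff = 4.2e-3,
                        Km = 10, kcat = 2)
  cu2 <- simulate_dilution(rev, 400, 1000, 60, 100, post,
                           topped_up_nM = 990)
  expect_equal(attr(cu2, "I_diluted_nM"), 1000)
  slope2 <- coef(lm(cu2$signal_au[late] ~ cu2$time_min[late]))[2]
  v0r <- steady_rate(rev, 10, 0, 4) * post$gain / 1000
  expect_lt(slope2 / v0r, 120 / (120 + 1000) * 1.1)
})

test_that("per-curve sub-seeding is a pure function of seed and id", {
  expect_identical(curve_seed(1, "I_0"), curve_seed(1, "I_0"))
  expect_false(curve_seed(1, "I_0") == curve_seed(2, "I_0"))
  expect_false(curve_seed(1, "I_0") == curve_seed(1, "I_1"))
  s <- vapply(1:200, function(i) curve_seed(i, "x"), 1L)
  expect_true(all(s >= 1) && all(s <= 2147483647))
  expect_equal(length(unique(s)), 200L)
})
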