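test_that("aspiration force follows the pressure and errors without one", {
  expect_equal(signif(aspiration_force(27, 700), 3), 1.60e-6)
  expect_error(aspiration_force(27, 500, 500), "exceed")
  # linear in the net pressure
  expect_equal(aspiration_force(27, 500, 100),
               0.8 * aspiration_force(27, 500, 0))
})

test_that("elastic modulus matches worked examples and scalings", {
  expect_equal(elastic_modulus(90, 27, 700), 210)
  expect_equal(round(elastic_modulus(70, 27, 500), 1), 192.9)
  expect_equal(elastic_modulus(180, 27, 700),
               elastic_modulus(90, 27, 700) / 2)
  expect_error(elastic_modulus(0, 27, 700), "positive")
})

test_that("viscosity matches the worked example and scalings", {
  expect_equal(signif(tissue_viscosity(0.167, 27, 700), 3), 1.20e4)
  expect_equal(tissue_viscosity(0.334, 27, 700),
               tissue_viscosity(0.167, 27, 700) / 2)
  expect_equal(tissue_viscosity(0.167, 27, 350),
               tissue_viscosity(0.167, 27, 700) / 2)
  expect_error(tissue_viscosity(0, 27, 700), "positive")
})

test_that("modulus-deformation identity holds and tau is pressure-free", {
  set.seed(4)
  for (k in 1:10) {
    r <- runif(1, 10, 50)
    dp <- runif(1, 300, 2000)
    dpc <- runif(1, 0, 200)
    delta <- runif(1, 20, 150)
    e <- elastic_modulus(delta, r, dp, dpc)
    expect_equal(e * delta, r * (dp - dpc))
  }
  # delta and l_dot_inf proportional to net pressure leave tau unchanged
  tau_at <- function(dp) {
    scale <- dp / 700
    e <- elastic_modulus(90 * scale, 27, dp)
    eta <- tissue_viscosity(0.167 * scale, 27, dp)
    eta / e
  }
  expect_equal(tau_at(500), tau_at(700))
  expect_equal(tau_at(1500), tau_at(700))
})

test_that("critical pressure shifts the modulus by delta_p_c / delta_p", {
  e0 <- elastic_modulus(70, 27, 500, 0)
  e50 <- elastic_modulus(70, 27, 500, 50)
  e150 <- elastic_modulus(70, 27, 500, 150)
  expect_equal((e0 - e50) / e0, 50 / 500)
  expect_equal((e0 - e150) / e0, 150 / 500)
})

noiseless_fit <- function() {
  curve <- simulate_creep(90, 0.6, 10, 0.167)
  fit_modified_maxwell(curve)
}

test_that("uncertainty propagation honours its limiting cases", {
  fit <- noiseless_fit()
  geom <- channel_geometry()
  # all error sources off: propagated SEs vanish
  m0 <- propagate_uncertainty(fit, geom,
                              aspiration_conditions(700, delta_p_error = 0,
                                                    dimension_error_um = 0))
  expect_lt(m0$se_e_pa / m0$e_pa, 1e-6)
  expect_lt(m0$se_eta_pa_s / m0$eta_pa_s, 1e-6)
  expect_equal(m0$tau_s, m0$eta_pa_s / m0$e_pa, tolerance = 1e-12)
  # only the pressure-reading error: relative SE equals se_dP / net dP
  mp <- propagate_uncertainty(fit, geom,
                              aspiration_conditions(700, delta_p_error = 20,
                                                    dimension_error_um = 0))
  expect_equal(mp$se_e_pa / mp$e_pa, 20 / 700, tolerance = 1e-6)
})

test_that("propagated errors match a Monte-Carlo resampling oracle", {
  curve <- simulate_creep(90, 0.6, 10, 0.167, noise_sd = 2, seed = 42)
  fit <- fit_modified_maxwell(curve)
  geom <- channel_geometry()
  cond <- aspiration_conditions(700)
  mech <- propagate_uncertainty(fit, geom, cond)

  se <- sqrt(diag(fit$vcov))
  set.seed(99)
  n_mc <- 1e4
  d_mc <- rnorm(n_mc, fit$params[["delta"]], se[["delta"]])
  v_mc <- rnorm(n_mc, fit$params[["l_dot_inf"]], se[["l_dot_inf"]])
  dp_mc <- rnorm(n_mc, 700, 20)
  w_mc <- rnorm(n_mc, 50, 5)
  h_mc <- rnorm(n_mc, 50, 5)
  r_mc <- effective_radius(w_mc, h_mc)
  e_mc <- r_mc * dp_mc / d_mc
  eta_mc <- r_mc * dp_mc / (3 * pi * v_mc)
  expect_equal(mech$se_e_pa, sd(e_mc), tolerance = 0.05)
  expect_equal(mech$se_eta_pa_s, sd(eta_mc), tolerance = 0.05)
})

test_that("propagation refuses a fit without covariance", {
  fit <- noiseless_fit()
  fit$converged <- FALSE
  expect_error(propagate_uncertainty(fit, channel_geometry(),
                                     aspiration_conditions(700)),
               "covariance")
})

test_that("derive_mechanics maps over a cohort and skips excluded rows", {
  cohort <- generate_cohort("HEK293T", n_spheroids = 4, seed = 5)
  fits <- fit_cohort(cohort)
  fits$excluded[2] <- TRUE
  mech <- derive_mechanics(fits, channel_geometry(),
                           aspiration_conditions(700))
  expect_true(is.na(mech$e_pa[2]))
  expect_true(all(is.finite(mech$e_pa[-2])))
  expect_equal(mech$tau_s[-2], mech$eta_pa_s[-2] / mech$e_pa[-2],
               tolerance = 1e-12)
})
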