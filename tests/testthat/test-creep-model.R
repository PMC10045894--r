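test_that("creep law evaluates its limiting cases and worked example", {
  expect_equal(creep_length(0, 90, 0.6, 10, 0.167), 90 * (1 - 0.6))
  expect_equal(round(creep_length(300, 90, 0.6, 10, 0.167), 1), 140.1)
  # long-time slope tends to the flow velocity, intercept to delta
  t_far <- c(5000, 5100)
  slope <- diff(creep_length(t_far, 90, 0.6, 10, 0.167)) / 100
  expect_equal(slope, 0.167, tolerance = 1e-9)
  intercept <- creep_length(5000, 90, 0.6, 10, 0.167) - 0.167 * 5000
  expect_equal(intercept, 90, tolerance = 1e-9)
  expect_error(creep_length(-1, 90, 0.6, 10, 0.167), "non-negative")
})

test_that("creep length increases strictly in time for positive parameters", {
  set.seed(8)
  tt <- seq(0, 300, by = 5)
  for (k in 1:15) {
    l <- creep_length(tt, runif(1, 10, 150), runif(1, 0.05, 0.95),
                      runif(1, 2, 60), runif(1, 0.01, 0.5))
    expect_true(all(diff(l) > 0))
  }
})

test_that("noiseless curves are recovered to near machine precision", {
  truth <- c(delta = 90, beta = 0.6, tau_c = 10, l_dot_inf = 0.167)
  curve <- simulate_creep(90, 0.6, 10, 0.167)
  fit <- fit_modified_maxwell(curve)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$params / truth - 1)), 1e-6)
  expect_gt(fit$r_squared, 1 - 1e-12)
})

test_that("a noisy fixed-seed curve recovers delta within 5 um", {
  curve <- simulate_creep(90, 0.6, 10, 0.167, noise_sd = 2, seed = 42)
  fit <- fit_modified_maxwell(curve)
  expect_true(fit$converged)
  expect_lt(abs(fit$params[["delta"]] - 90), 5)
  expect_true(fit$params[["beta"]] >= 0 && fit$params[["beta"]] <= 1)
})

test_that("fitting is deterministic given the curve", {
  curve <- simulate_creep(50, 0.4, 20, 0.06, noise_sd = 2, seed = 3)
  f1 <- fit_modified_maxwell(curve)
  f2 <- fit_modified_maxwell(curve)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$vcov, f2$vcov)
})

test_that("onset detection re-zeroes records that start before the step", {
  curve <- simulate_creep(90, 0.6, 10, 0.167, n_pre = 8, noise_sd = 1,
                          seed = 6)
  onset <- detect_onset(curve$length_um)
  expect_equal(onset, 9L)
  fit <- fit_modified_maxwell(curve, onset = "detect")
  expect_true(fit$converged)
  expect_lt(abs(fit$params[["delta"]] - 90), 5)
  expect_equal(fit$data$time_s[1], 0)
})

test_that("too-short records are rejected", {
  short <- simulate_creep(90, 0.6, 10, 0.167, n_points = 9)
  expect_error(fit_modified_maxwell(short), "At least 10")
})

test_that("tidy, glance and augment expose the fit in broom style", {
  fit <- fit_modified_maxwell(simulate_creep(90, 0.6, 10, 0.167,
                                             noise_sd = 2, seed = 1))
  td <- tidy(fit)
  expect_equal(td$term, c("delta", "beta", "tau_c", "l_dot_inf"))
  expect_true(all(td$std.error > 0))
  gl <- glance(fit)
  expect_equal(gl$nobs, 61L)
  expect_true(gl$r.squared > 0.99 && gl$r.squared <= 1)
  aug <- augment(fit)
  expect_equal(aug$.resid, aug$length_um - aug$.fitted)
})

test_that("the full model attains the best goodness of fit among nested models", {
  for (seed in c(1, 2, 3)) {
    curve <- simulate_creep(90, 0.6, 10, 0.167, noise_sd = 2, seed = seed)
    tab <- fit_nested_models(curve)
    expect_setequal(tab$model,
                    c("maxwell", "kelvin_voigt", "sls", "modified_maxwell"))
    r2_mm <- tab$r_squared[tab$model == "modified_maxwell"]
    expect_true(all(r2_mm >= tab$r_squared - 1e-9))
  }
})

test_that("data from a nested sub-model never beats the full model", {
  # pure Maxwell truth (no exponential rise)
  tt <- seq(0, 300, by = 5)
  mx <- tibble::tibble(time_s = tt,
                       length_um = 40 + 0.1 * tt + rnorm(61, 0, 1) * 0)
  tab <- fit_nested_models(mx)
  expect_gte(tab$r_squared[tab$model == "modified_maxwell"],
             tab$r_squared[tab$model == "maxwell"] - 1e-9)
  # Kelvin-Voigt truth, noiseless: the KV fit is exact
  kv <- tibble::tibble(time_s = tt, length_um = 80 * (1 - exp(-tt / 15)))
  tab_kv <- fit_nested_models(kv)
  expect_gt(tab_kv$r_squared[tab_kv$model == "kelvin_voigt"], 1 - 1e-9)
})

test_that("simulated curves are reproducible and carry calibrated noise", {
  a <- simulate_creep(90, 0.6, 10, 0.167, noise_sd = 2, seed = 10)
  b <- simulate_creep(90, 0.6, 10, 0.167, noise_sd = 2, seed = 10)
  expect_identical(a, b)
  clean <- simulate_creep(90, 0.6, 10, 0.167)
  expect_equal(clean$length_um,
               creep_length(clean$time_s, 90, 0.6, 10, 0.167))
  resid_sd <- sd(a$length_um - clean$length_um)
  expect_lt(abs(resid_sd / 2 - 1), 0.3)
})
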