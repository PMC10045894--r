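test_that("cohort ground truth inverts the modulus relation exactly", {
  # with the conventionally quoted radius of 27 um, the HEK preset at
  # 700 Pa gives delta = 27 * 700 / 210 = 90 um for every spheroid
  geom <- channel_geometry(r_eff_um = 27)
  cohort <- generate_cohort("HEK293T", n_spheroids = 5, geometry = geom,
                            cv = 0, noise_sd = 0, seed = 1)
  expect_equal(cohort$delta_true_um, rep(90, 5))
  expect_equal(cohort$l_dot_inf_true_um_s,
               rep(27 * 700 / (3 * pi * 12e3), 5))
  expect_equal(cohort$e_true_pa, rep(210, 5))
})

test_that("cohort generation is deterministic and handles edge sizes", {
  a <- generate_cohort("HEK293T", n_spheroids = 6, seed = 7)
  b <- generate_cohort("HEK293T", n_spheroids = 6, seed = 7)
  expect_identical(a, b)
  empty <- generate_cohort("HEK293T", n_spheroids = 0)
  expect_equal(nrow(empty), 0)
  expect_error(generate_cohort("HeLa"), "Unknown preset")
})

test_that("per-spheroid draws preserve the preset means and radii range", {
  cohort <- generate_cohort("NIH3T3", n_spheroids = 400, seed = 2)
  expect_equal(mean(cohort$e_true_pa), 780, tolerance = 0.05)
  expect_equal(mean(cohort$eta_true_pa_s), 67e3, tolerance = 0.05)
  expect_equal(sd(cohort$e_true_pa) / mean(cohort$e_true_pa), 0.2,
               tolerance = 0.15)
  expect_true(all(cohort$r0_um >= 60 & cohort$r0_um <= 125))
})

test_that("simulate-fit round trip recovers the cohort ground truth", {
  cohort <- generate_cohort("HEK293T", n_spheroids = 30, seed = 21)
  fits <- fit_cohort(cohort)
  expect_true(all(fits$converged))
  expect_equal(mean(fits$delta_um), mean(cohort$delta_true_um),
               tolerance = 0.05)
  expect_equal(mean(fits$l_dot_inf_um_s), mean(cohort$l_dot_inf_true_um_s),
               tolerance = 0.05)
  # bias vanishes with the noise
  clean <- generate_cohort("HEK293T", n_spheroids = 10, noise_sd = 0,
                           seed = 21)
  cf <- fit_cohort(clean)
  expect_lt(max(abs(cf$delta_um / clean$delta_true_um - 1)), 1e-6)
})

test_that("derived mechanics are independent of spheroid radius", {
  cohort <- generate_cohort("HEK293T", n_spheroids = 50, seed = 31)
  fits <- fit_cohort(cohort)
  mech <- derive_mechanics(fits, channel_geometry(),
                           aspiration_conditions(700))
  chk <- size_independence_check(mech, n_perm = 2000, seed = 1)
  expect_false(any(chk$independence_rejected))
})

test_that("rendered stacks honour trivial tongue configurations", {
  # zero-length tongues: the whole stack is background
  truth0 <- tibble::tibble(delta_true_um = 1e-9, beta_true = 0,
                           tau_c_true_s = 10, l_dot_inf_true_um_s = 0)
  st0 <- render_stack(truth0, n_frames = 5)
  expect_equal(sum(st0$frames), 0)
  # constant tongue length: front row fixed at height - round(L / px) + 1
  truth1 <- tibble::tibble(delta_true_um = 100, beta_true = 0,
                           tau_c_true_s = 10, l_dot_inf_true_um_s = 0)
  st1 <- render_stack(truth1, n_frames = 5, pixel_size_um = 1.3)
  h <- dim(st1$frames)[1]
  expected_row <- h - round(100 / 1.3) + 1L
  expect_equal(unique(st1$truth$front_row), expected_row)
  for (k in 1:5) {
    expect_equal(find_front(st1$frames[, , k], st1$centerlines[1]),
                 expected_row)
  }
})

test_that("stack rendering rejects more spheroids than channels", {
  cohort <- generate_cohort("HEK293T", n_spheroids = 9, seed = 1)
  expect_error(render_stack(cohort), "At most 8")
})

test_that("break-off artifacts are flagged on exactly the injected channels", {
  cohort <- generate_cohort("HEK293T", n_spheroids = 5, seed = 12)
  cohort$artifact <- c(NA, "break_off", NA, "break_off", NA)
  st <- render_stack(cohort, n_frames = 31)
  tracked <- creep_from_stack(st)
  flags <- dplyr::distinct(tracked, pocket, excluded)
  expect_equal(flags$excluded, c(FALSE, TRUE, FALSE, TRUE, FALSE))
})

test_that("mask artifact modes trip the matching exclusion rules", {
  expect_false(check_spheroid_shape(render_spheroid_masks(90))$excluded)
  non_round <- check_spheroid_shape(render_spheroid_masks(90,
                                                          mode = "non_round"))
  expect_equal(non_round$reason, "non_round")
  shrink <- check_spheroid_shape(render_spheroid_masks(90,
                                                       mode = "shrinking"))
  expect_equal(shrink$reason, "volume_drift")
})

test_that("creep tables round-trip through CSV", {
  curves <- simulate_creep(90, 0.6, 10, 0.167, noise_sd = 2, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_creep_curves(curves, path)
  back <- read_creep_curves(path)
  expect_equal(as.data.frame(back), as.data.frame(curves))
})
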