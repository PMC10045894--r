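mech_tbl <- function(e, eta = e * 60, delta = 27 * 700 / e) {
  tibble::tibble(e_pa = e, eta_pa_s = eta, delta_um = delta)
}

test_that("group summaries compute means and SEMs over non-excluded fits", {
  two <- mech_tbl(c(210, 210))
  s <- summarize_group(two, "pair")
  expect_equal(s$sem_e_pa, 0)
  s2 <- summarize_group(mech_tbl(c(200, 220)), "pair")
  expect_equal(s2$mean_e_pa, 210)
  expect_equal(s2$sem_e_pa, 10)
  expect_error(summarize_group(mech_tbl(210)), "At least 2")
  with_flag <- mech_tbl(c(200, 220, 900))
  with_flag$excluded <- c(FALSE, FALSE, TRUE)
  s3 <- summarize_group(with_flag, "flagged")
  expect_equal(s3$n, 2)
  expect_equal(s3$mean_e_pa, 210)
})

test_that("cohort summaries land near the preset with SEM at the printed scale", {
  res <- run_scenario(list(preset = "HEK293T", seed = 17))
  expect_equal(res$summary$n, 80)
  expect_equal(res$summary$mean_e_pa, 210, tolerance = 0.05)
  expect_gt(res$summary$sem_e_pa, 1)
  expect_lt(res$summary$sem_e_pa, 15)
})

test_that("the two-sample t-test matches pooled-variance arithmetic", {
  res <- two_sample_t_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(round(res$t, 3), -3.674)
  expect_equal(res$df, 4)
  expect_true(res$significant)
  # closed form: pooled sd = 1, t = -3 / sqrt(2/3)
  expect_equal(res$t, -3 / sqrt(2 / 3), tolerance = 1e-12)
  # welch variant reproduces stats::t.test
  w <- two_sample_t_test(c(1, 2, 3, 7), c(4, 5, 6), variant = "welch")
  ref <- t.test(c(1, 2, 3, 7), c(4, 5, 6))
  expect_equal(w$p, ref$p.value)
})

test_that("degenerate zero-variance groups follow the p = 1 convention", {
  res <- two_sample_t_test(c(2, 2), c(2, 2))
  expect_equal(res$p, 1)
  expect_true(res$degenerate)
  expect_false(res$significant)
  res2 <- two_sample_t_test(c(2, 2), c(3, 3))
  expect_equal(res2$p, 0)
  expect_true(res2$degenerate)
})

test_that("size-independence check distinguishes null from induced trends", {
  set.seed(23)
  r0 <- runif(50, 60, 125)
  null_tbl <- tibble::tibble(r0_um = r0, e_pa = rnorm(50, 210, 40),
                             eta_pa_s = rnorm(50, 12e3, 2e3))
  chk <- size_independence_check(null_tbl, n_perm = 4000, seed = 5)
  expect_false(any(chk$independence_rejected))
  # permutation p agrees with the analytic approximation
  expect_lt(max(abs(chk$p_permutation - chk$p_analytic)), 0.02)
  # a linear dependence on radius is detected
  dep_tbl <- tibble::tibble(r0_um = r0, e_pa = 2 * r0 + rnorm(50, 0, 5),
                            eta_pa_s = rnorm(50, 12e3, 2e3))
  chk2 <- size_independence_check(dep_tbl, values = "e_pa", n_perm = 4000,
                                  seed = 5)
  expect_true(chk2$independence_rejected)
  expect_gt(chk2$pearson_r, 0)
  expect_error(size_independence_check(tibble::tibble(r0_um = rep(90, 12),
                                                      e_pa = rnorm(12))),
               "constant")
  expect_error(size_independence_check(null_tbl[1:5, ]), "At least 10")
})

test_that("scenarios are reproducible from config plus seed", {
  cfg <- list(preset = "HEK293T", n_spheroids = 6, seed = 4)
  a <- run_scenario(cfg)
  b <- run_scenario(cfg)
  expect_equal(a$summary, b$summary)
  expect_identical(a$cohort$delta_um, b$cohort$delta_um)
  # config can come from a YAML file
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, path)
  c3 <- run_scenario(path)
  expect_equal(c3$summary, a$summary)
})

test_that("scenarios can route curves through rendering and tracking", {
  res <- run_scenario(list(preset = "HEK293T", n_spheroids = 4,
                           noise_sd = 0, seed = 4, render = TRUE))
  expect_equal(res$summary$n, 4)
  expect_equal(res$summary$mean_e_pa, mean(res$cohort$e_true_pa),
               tolerance = 0.05)
})

test_that("results tables serialize to JSON records", {
  cohort <- fit_cohort(generate_cohort("HEK293T", n_spheroids = 3, seed = 2))
  mech <- derive_mechanics(cohort, channel_geometry(),
                           aspiration_conditions(700))
  path <- withr::local_tempfile(fileext = ".json")
  write_results_json(mech, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(nrow(back), 3)
  expect_equal(back$e_pa, mech$e_pa, tolerance = 1e-9)
})
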