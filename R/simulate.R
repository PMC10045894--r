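#' Cell-line presets for synthetic cohorts
#'
#' Mean elastic modulus and viscosity of the three spheroid models used as
#' ground truth by the synthetic-data generator, together with the pressure
#' step each line was measured at and the published cohort size.
#'
#' @return A tibble with columns `cell_line`, `e_pa`, `eta_pa_s`,
#'   `delta_p`, `n`.
#' @export
#' @examples
#' cell_line_presets()
cell_line_presets <- function() {
  tibble(
    cell_line = c("HEK293T", "NIH3T3", "MCF10A"),
    e_pa = c(210, 780, 770),
    eta_pa_s = c(12e3, 67e3, 67e3),
    delta_p = c(700, 1500, 1500),
    n = c(80L, 75L, 34L)
  )
}

#' Simulate one creep curve
#'
#' Evaluates the modified Maxwell law [creep_length()] on a regular time
#' grid and adds i.i.d. Gaussian measurement noise. Optionally prepends
#' baseline frames before the pressure step (length 0 plus noise), as in a
#' recording started before the outlet reservoir is lowered.
#'
#' @inheritParams creep_length
#' @param n_points Number of post-onset frames (default 61: 5 minutes at
#'   5 s intervals, including \eqn{t=0}).
#' @param dt Frame interval in seconds (default 5).
#' @param noise_sd Gaussian noise standard deviation in micrometres
#'   (default 0).
#' @param n_pre Number of pre-onset baseline frames (default 0).
#' @param seed Optional integer seed; when supplied the curve is
#'   reproducible and the caller's RNG state is left untouched.
#' @param spheroid_id,pocket Identifier columns copied into the output.
#'
#' @return A tibble with columns `time_s`, `length_um`, `spheroid_id`,
#'   `pocket`, `excluded`, `reason`.
#' @export
#' @examples
#' simulate_creep(delta = 90, beta = 0.6, tau_c = 10, l_dot_inf = 0.167,
#'                noise_sd = 2, seed = 1)
simulate_creep <- function(delta, beta, tau_c, l_dot_inf,
                           n_points = 61, dt = 5, noise_sd = 0, n_pre = 0,
                           seed = NULL, spheroid_id = "sim-1", pocket = 1L) {
  if (dt <= 0) abort("`dt` must be positive.")
  if (noise_sd < 0) abort("`noise_sd` must be non-negative.")
  if (n_points < 1) abort("`n_points` must be at least 1.")
  gen <- function() {
    t_post <- (seq_len(n_points) - 1) * dt
    l_post <- creep_length(t_post, delta, beta, tau_c, l_dot_inf)
    l <- c(rep(0, n_pre), l_post)
    if (noise_sd > 0) l <- l + rnorm(length(l), 0, noise_sd)
    tibble(
      time_s = (seq_along(l) - 1) * dt,
      length_um = pmax(l, 0),
      spheroid_id = spheroid_id,
      pocket = as.integer(pocket),
      excluded = FALSE,
      reason = NA_character_
    )
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Generate a synthetic aspiration cohort
#'
#' Draws per-spheroid ground-truth mechanical parameters around a cell-line
#' preset (or custom means), inverts the modulus and viscosity relations to
#' obtain the creep parameters
#' \eqn{\delta_i = R_{\mathrm{eff}} \Delta P / E_i} and
#' \eqn{\dot L_{\infty,i} = R_{\mathrm{eff}} \Delta P / (3\pi\eta_i)},
#' and simulates one noisy creep curve per spheroid. Between-spheroid
#' variability is lognormal with the requested coefficient of variation,
#' parameterized to preserve the arithmetic mean. Spheroid radii are drawn
#' uniformly in 60--125 um and do not enter the creep law (mechanics are
#' size-independent by construction). All randomness flows through `seed`.
#'
#' @param preset Cell line name (see [cell_line_presets()]) or `NULL` when
#'   `e_pa`/`eta_pa_s` are given directly.
#' @param delta_p Applied pressure step in Pa; defaults to the preset's.
#' @param n_spheroids Cohort size; defaults to the preset's published n.
#' @param e_pa,eta_pa_s Custom preset means (override the cell line's).
#' @param geometry A [channel_geometry()] record.
#' @param beta,tau_c Shared creep-shape parameters (defaults 0.6 and 10 s;
#'   the published tables do not report them, and recovery of modulus and
#'   viscosity does not depend on their exact values).
#' @param cv Between-spheroid coefficient of variation of `E` and `eta`
#'   (default 0.2).
#' @param noise_sd Measurement noise per frame in micrometres (default 2).
#' @param n_points,dt Time grid passed to [simulate_creep()].
#' @param n_pre Pre-onset baseline frames per curve (default 0).
#' @param seed Integer seed (required for reproducibility; default 1).
#'
#' @return A tibble with one row per spheroid: identifiers, sampled radius
#'   `r0_um`, ground-truth columns (`e_true_pa`, `eta_true_pa_s`,
#'   `delta_true_um`, `l_dot_inf_true_um_s`, `beta_true`, `tau_c_true_s`),
#'   and a `data` list-column holding each simulated curve.
#' @export
#' @examples
#' cohort <- generate_cohort("HEK293T", n_spheroids = 5, seed = 1)
#' cohort
generate_cohort <- function(preset = "HEK293T", delta_p = NULL,
                            n_spheroids = NULL, e_pa = NULL, eta_pa_s = NULL,
                            geometry = channel_geometry(),
                            beta = 0.6, tau_c = 10, cv = 0.2, noise_sd = 2,
                            n_points = 61, dt = 5, n_pre = 0, seed = 1) {
  if (!is.null(preset)) {
    pr <- cell_line_presets()
    row <- pr[pr$cell_line == preset, ]
    if (nrow(row) == 0) {
      abort(paste0("Unknown preset '", preset, "'. Available: ",
                   paste(pr$cell_line, collapse = ", "), "."))
    }
    e_pa <- e_pa %||% row$e_pa
    eta_pa_s <- eta_pa_s %||% row$eta_pa_s
    delta_p <- delta_p %||% row$delta_p
    n_spheroids <- n_spheroids %||% row$n
  }
  if (is.null(e_pa) || is.null(eta_pa_s) || is.null(delta_p) ||
      is.null(n_spheroids)) {
    abort("Provide `preset`, or all of `e_pa`, `eta_pa_s`, `delta_p`, `n_spheroids`.")
  }
  if (cv < 0) abort("`cv` must be non-negative.")
  if (n_spheroids == 0) {
    return(tibble(
      spheroid_id = character(), pocket = integer(), r0_um = numeric(),
      e_true_pa = numeric(), eta_true_pa_s = numeric(),
      delta_true_um = numeric(), l_dot_inf_true_um_s = numeric(),
      beta_true = numeric(), tau_c_true_s = numeric(), data = list()
    ))
  }
  r_eff <- geometry$r_eff_um
  withr::with_seed(seed, {
    # mean-preserving lognormal draws
    draw <- function(m, n) {
      if (cv == 0) return(rep(m, n))
      sdlog <- sqrt(log(1 + cv^2))
      rlnorm(n, meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
    }
    e_i <- draw(e_pa, n_spheroids)
    eta_i <- draw(eta_pa_s, n_spheroids)
    r0 <- runif(n_spheroids, 60, 125)
    delta_i <- r_eff * delta_p / e_i
    ldot_i <- r_eff * delta_p / (3 * pi * eta_i)
    curves <- purrr::pmap(
      list(delta_i, ldot_i, seq_len(n_spheroids)),
      function(d, v, k) {
        simulate_creep(d, beta, tau_c, v, n_points = n_points, dt = dt,
                       noise_sd = noise_sd, n_pre = n_pre,
                       spheroid_id = sprintf("sph-%03d", k),
                       pocket = ((k - 1L) %% 8L) + 1L)
      })
    tibble(
      spheroid_id = sprintf("sph-%03d", seq_len(n_spheroids)),
      pocket = ((seq_len(n_spheroids) - 1L) %% 8L) + 1L,
      r0_um = r0,
      e_true_pa = e_i, eta_true_pa_s = eta_i,
      delta_true_um = delta_i, l_dot_inf_true_um_s = ldot_i,
      beta_true = beta, tau_c_true_s = tau_c,
      data = curves
    )
  })
}

#' Fit every curve of a cohort
#'
#' Maps [fit_modified_maxwell()] over the `data` list-column of a cohort
#' table (as produced by [generate_cohort()] or assembled from tracked
#' stacks) and appends the tidy parameter estimates. Rows flagged `excluded`
#' are kept but not fitted.
#'
#' @param cohort A data frame with a `data` list-column of creep curves.
#' @param onset Passed to [fit_modified_maxwell()].
#'
#' @return The cohort with columns `fit` (list of `creep_fit` objects),
#'   `delta_um`, `beta`, `tau_c_s`, `l_dot_inf_um_s`, `se_delta_um`,
#'   `se_l_dot_inf_um_s`, `r_squared`, `n_points`, `converged` appended.
#' @export
#' @examples
#' cohort <- generate_cohort("HEK293T", n_spheroids = 3, seed = 1)
#' fits <- fit_cohort(cohort)
#' fits$delta_um
fit_cohort <- function(cohort, onset = "none") {
  stopifnot(is.data.frame(cohort), "data" %in% names(cohort))
  excl <- if ("excluded" %in% names(cohort)) cohort$excluded else
    purrr::map_lgl(cohort$data, ~ isTRUE(.x$excluded[1]))
  fits <- purrr::map2(cohort$data, excl, function(d, ex) {
    if (isTRUE(ex)) NULL else fit_modified_maxwell(d, onset = onset)
  })
  rows <- purrr::map(fits, function(f) {
    if (is.null(f)) {
      creep_fit_row(new_creep_fit(
        params = setNames(rep(NA_real_, 4),
                          c("delta", "beta", "tau_c", "l_dot_inf")),
        vcov = matrix(NA_real_, 4, 4,
                      dimnames = list(c("delta", "beta", "tau_c",
                                        "l_dot_inf"),
                                      c("delta", "beta", "tau_c",
                                        "l_dot_inf"))),
        r_squared = NA_real_, data = tibble(), fitted = numeric(),
        converged = FALSE, onset = 1L, message = "excluded"))
    } else {
      creep_fit_row(f)
    }
  })
  out <- dplyr::bind_cols(as_tibble(cohort), dplyr::bind_rows(rows))
  out$fit <- fits
  out$excluded <- excl
  out
}

#' Read and write creep-curve tables
#'
#' Thin CSV wrappers for the creep-curve exchange schema: columns `time_s`,
#' `length_um`, `spheroid_id`, `pocket`, `excluded`, `reason`.
#'
#' @param path File path.
#' @param curves A data frame of creep curves (long format).
#' @return `read_creep_curves()` returns a tibble; `write_creep_curves()`
#'   returns `curves` invisibly.
#' @export
read_creep_curves <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    time_s = readr::col_double(),
                    length_um = readr::col_double(),
                    spheroid_id = readr::col_character(),
                    pocket = readr::col_integer(),
                    excluded = readr::col_logical(),
                    reason = readr::col_character()
                  ))
}

#' @rdname read_creep_curves
#' @export
write_creep_curves <- function(curves, path) {
  readr::write_csv(curves, path)
  invisible(curves)
}

#' Write a results table as JSON records
#'
#' Serializes a tibble of fit or mechanics records to a JSON array of
#' objects (one per row), dropping list-columns.
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_results_json <- function(x, path) {
  flat <- x[, !purrr::map_lgl(x, is.list), drop = FALSE]
  jsonlite::write_json(flat, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(x)
}
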