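#' Summarize a cohort of fitted spheroids
#'
#' Means and standard errors of the mean (SEM = sample SD / sqrt(n)) of
#' elastic modulus, viscosity and elastic deformation over the
#' non-excluded, converged records of a mechanics table (see
#' [derive_mechanics()]).
#'
#' @param records Data frame with columns `e_pa`, `eta_pa_s` and
#'   `delta_um` (optionally `excluded`).
#' @param label Group label for the summary row.
#'
#' @return One-row tibble of class `"group_summary"`: `label`, `n`,
#'   `mean_e_pa`, `sem_e_pa`, `mean_eta_kpa_s`, `sem_eta_kpa_s`,
#'   `mean_delta_um`, `sem_delta_um`. Viscosity is reported in kPa s, the
#'   scale of the published tables.
#' @export
summarize_group <- function(records, label = "group") {
  stopifnot(is.data.frame(records))
  if ("excluded" %in% names(records)) {
    records <- records[!records$excluded %in% TRUE, , drop = FALSE]
  }
  keep <- stats::complete.cases(records[, c("e_pa", "eta_pa_s", "delta_um")])
  records <- records[keep, , drop = FALSE]
  n <- nrow(records)
  if (n < 2) abort("At least 2 non-excluded records are required.")
  sem <- function(x) sd(x) / sqrt(length(x))
  out <- tibble(
    label = label, n = n,
    mean_e_pa = mean(records$e_pa), sem_e_pa = sem(records$e_pa),
    mean_eta_kpa_s = mean(records$eta_pa_s) / 1e3,
    sem_eta_kpa_s = sem(records$eta_pa_s) / 1e3,
    mean_delta_um = mean(records$delta_um),
    sem_delta_um = sem(records$delta_um)
  )
  class(out) <- c("group_summary", class(out))
  out
}

#' Two-sample Student t-test
#'
#' Two-tailed two-sample t-test between two groups of measurements, in the
#' classical equal-variance form by default (with a Welch option).
#' Zero-variance identical groups are degenerate for the t statistic and
#' are reported with the convention p = 1 (and p = 0 for zero-variance
#' groups with different means), flagged via `degenerate`.
#'
#' @param a,b Numeric vectors (each of length >= 2).
#' @param variant `"equal_variance"` (classical Student, default) or
#'   `"welch"`.
#' @param alpha Significance level for the `significant` flag (default
#'   0.05).
#'
#' @return One-row tibble: `t`, `df`, `p`, `significant`, `variant`,
#'   `degenerate`.
#' @export
#' @examples
#' two_sample_t_test(c(1, 2, 3), c(4, 5, 6))
two_sample_t_test <- function(a, b,
                              variant = c("equal_variance", "welch"),
                              alpha = 0.05) {
  variant <- match.arg(variant)
  if (length(a) < 2 || length(b) < 2) {
    abort("Each group needs at least 2 values.")
  }
  if (var(a) == 0 && var(b) == 0) {
    same <- isTRUE(all.equal(mean(a), mean(b)))
    return(tibble(
      t = if (same) 0 else Inf * sign(mean(a) - mean(b)),
      df = NA_real_, p = if (same) 1 else 0,
      significant = !same, variant = variant, degenerate = TRUE
    ))
  }
  tt <- t.test(a, b, var.equal = (variant == "equal_variance"),
               alternative = "two.sided")
  tibble(
    t = unname(tt$statistic), df = unname(tt$parameter),
    p = tt$p.value, significant = tt$p.value < alpha,
    variant = variant, degenerate = FALSE
  )
}

#' Size-independence check of derived mechanics
#'
#' Tests whether elastic modulus and viscosity correlate with spheroid
#' radius. Reports the Pearson correlation with both a permutation p-value
#' (radii shuffled, two-sided on |r|) and the analytic t-approximation, and
#' flags whether independence is rejected at `alpha`.
#'
#' @param records Data frame with columns `r0_um` plus the `values`
#'   columns.
#' @param values Character vector of value columns to test (default
#'   `c("e_pa", "eta_pa_s")`).
#' @param n_perm Number of permutations (default 10000).
#' @param alpha Significance level (default 0.05).
#' @param seed Optional seed for the permutation draw.
#'
#' @return A tibble with one row per tested column: `parameter`, `n`,
#'   `pearson_r`, `p_permutation`, `p_analytic`, `independence_rejected`.
#' @export
size_independence_check <- function(records,
                                    values = c("e_pa", "eta_pa_s"),
                                    n_perm = 10000, alpha = 0.05,
                                    seed = NULL) {
  stopifnot(is.data.frame(records), "r0_um" %in% names(records))
  if ("excluded" %in% names(records)) {
    records <- records[!records$excluded %in% TRUE, , drop = FALSE]
  }
  r0 <- records$r0_um
  if (length(r0) < 10) abort("At least 10 records with radii are required.")
  if (sd(r0) == 0) abort("Radii are constant; correlation is undefined.")
  run <- function() {
    purrr::map_dfr(values, function(vn) {
      x <- records[[vn]]
      ok <- is.finite(x) & is.finite(r0)
      x <- x[ok]
      rr <- r0[ok]
      r_obs <- cor(rr, x)
      perm <- vapply(seq_len(n_perm),
                     function(i) cor(sample(rr), x), numeric(1))
      p_perm <- (1 + sum(abs(perm) >= abs(r_obs))) / (n_perm + 1)
      p_an <- cor.test(rr, x)$p.value
      tibble(parameter = vn, n = length(x), pearson_r = r_obs,
             p_permutation = p_perm, p_analytic = p_an,
             independence_rejected = p_perm < alpha)
    })
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Run a full synthetic scenario
#'
#' Chains the pipeline stages -- cohort simulation, optional rendering and
#' tracking, model fitting, mechanics derivation and group summary -- from
#' a single configuration list (or a YAML/JSON file path with the same
#' fields). All randomness flows through `config$seed`.
#'
#' Recognised fields (all optional, with the package defaults):
#' `preset`, `delta_p`, `n_spheroids`, `cv`, `noise_sd`, `beta`, `tau_c`,
#' `seed`, `label`, `geometry` (list: `width_um`, `height_um`, `length_um`),
#' `conditions` (list: `delta_p_c`, `delta_p_error`, `dimension_error_um`),
#' `render` (logical: route the curves through the image renderer and
#' tracker instead of fitting the simulated curves directly; rendered
#' stacks hold at most 8 spheroids, so this is only allowed for
#' `n_spheroids <= 8`).
#'
#' @param config A named list, or a path to a YAML or JSON file.
#' @param verbose Emit per-stage progress messages (default `FALSE`).
#'
#' @return A list with elements `cohort` (fits + mechanics tibble),
#'   `summary` (one-row [summarize_group()] table), `geometry`,
#'   `conditions`, `config`.
#' @export
#' @examples
#' res <- run_scenario(list(preset = "HEK293T", n_spheroids = 6, seed = 2))
#' res$summary
run_scenario <- function(config = list(), verbose = FALSE) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  stopifnot(is.list(config))
  say <- function(...) if (verbose) inform(paste0(...))
  g <- config$geometry %||% list()
  geometry <- channel_geometry(
    width_um = g$width_um %||% 50, height_um = g$height_um %||% 50,
    length_um = g$length_um %||% 300, r_eff_um = g$r_eff_um
  )
  preset <- config$preset %||% "HEK293T"
  pr <- cell_line_presets()
  pr <- pr[pr$cell_line == preset, ]
  delta_p <- config$delta_p %||% pr$delta_p
  cc <- config$conditions %||% list()
  conditions <- aspiration_conditions(
    delta_p = delta_p, delta_p_c = cc$delta_p_c %||% 0,
    delta_p_error = cc$delta_p_error %||% 20,
    dimension_error_um = cc$dimension_error_um %||% 5
  )
  seed <- config$seed %||% 1
  say("simulate: preset ", preset, ", delta_p ", delta_p, " Pa, seed ", seed)
  cohort <- generate_cohort(
    preset = preset, delta_p = delta_p,
    n_spheroids = config$n_spheroids, geometry = geometry,
    beta = config$beta %||% 0.6, tau_c = config$tau_c %||% 10,
    cv = config$cv %||% 0.2, noise_sd = config$noise_sd %||% 2,
    seed = seed
  )
  if (isTRUE(config$render)) {
    if (nrow(cohort) > 8) {
      abort("`render = TRUE` supports at most 8 spheroids (one stack).")
    }
    say("render + track: ", nrow(cohort), " channels")
    stack <- render_stack(cohort)
    tracked <- creep_from_stack(stack)
    cohort$data <- purrr::map(seq_len(nrow(cohort)), function(i) {
      dplyr::filter(tracked, .data$pocket == i)
    })
  }
  say("fit: ", nrow(cohort), " curves")
  fits <- fit_cohort(cohort)
  say("mechanics + summary")
  mech <- derive_mechanics(fits, geometry, conditions)
  summary <- summarize_group(mech, label = config$label %||% preset)
  list(cohort = mech, summary = summary, geometry = geometry,
       conditions = conditions, config = config)
}
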