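#' Modified Maxwell creep law
#'
#' Creep length of an aspirated tissue tongue under a constant pressure step,
#' for the four-element spring-dashpot network consisting of a dashpot
#' \eqn{\xi_t} in series with a spring \eqn{k_1} in parallel with a
#' \eqn{k_2}--\eqn{\xi_c} branch:
#' \deqn{L(t) = \delta\,\big(1 - \beta e^{-t/\tau_c}\big) + \dot L_\infty t,}
#' with \eqn{\delta = f/k_1} the elastic deformation (the intercept of the
#' long-time linear flow extrapolated to \eqn{t=0}),
#' \eqn{\beta = k_2/(k_1+k_2)} governing the initial jump
#' \eqn{L(0) = \delta(1-\beta)}, \eqn{\tau_c} the rising time of the elastic
#' deformation, and \eqn{\dot L_\infty = f/\xi_t} the long-time flow
#' velocity.
#'
#' @param t Time in seconds since the pressure step (non-negative vector).
#' @param delta Elastic deformation in micrometres (> 0).
#' @param beta Dimensionless jump ratio in \[0, 1\].
#' @param tau_c Rising time in seconds (> 0).
#' @param l_dot_inf Long-time flow velocity in micrometres per second
#'   (>= 0).
#'
#' @return Creep length in micrometres.
#' @export
#' @examples
#' creep_length(c(0, 30, 300), delta = 90, beta = 0.6, tau_c = 10,
#'              l_dot_inf = 0.167)
creep_length <- function(t, delta, beta, tau_c, l_dot_inf) {
  if (any(t < 0)) abort("`t` must be non-negative.")
  if (delta <= 0) abort("`delta` must be positive.")
  if (beta < 0 || beta > 1) abort("`beta` must lie in [0, 1].")
  if (tau_c <= 0) abort("`tau_c` must be positive.")
  if (l_dot_inf < 0) abort("`l_dot_inf` must be non-negative.")
  delta * (1 - beta * exp(-t / tau_c)) + l_dot_inf * t
}

#' Detect the aspiration onset in a creep record
#'
#' Image acquisition starts before the outlet reservoir is lowered, so the
#' first frames of a record sit at baseline. The onset is taken as the first
#' frame whose length exceeds the running pre-onset mean by `k` pre-onset
#' standard deviations (with a small floor so a noiseless baseline still
#' triggers). A single outlier frame cannot trigger the onset: the
#' following frame must exceed the threshold too, which the genuine elastic
#' jump always does.
#'
#' @param lengths_um Numeric vector of creep lengths per frame.
#' @param k Number of baseline standard deviations (default 3).
#' @param min_baseline Minimum number of frames used for the baseline
#'   estimate before a jump may be declared (default 3).
#' @param sd_floor Lower bound on the baseline standard deviation, in
#'   micrometres, so that a strictly constant baseline still yields a finite
#'   threshold (default 1e-6).
#'
#' @return Integer index of the onset frame (1 if no pre-onset baseline is
#'   detected, so the record is treated as already post-onset).
#' @export
detect_onset <- function(lengths_um, k = 3, min_baseline = 3,
                         sd_floor = 1e-6) {
  n <- length(lengths_um)
  if (n <= min_baseline) return(1L)
  for (i in (min_baseline + 1):n) {
    base <- lengths_um[1:(i - 1)]
    thr <- mean(base) + k * max(sd(base), sd_floor)
    if (lengths_um[i] > thr &&
        (i == n || lengths_um[i + 1] > thr)) {
      return(as.integer(i))
    }
  }
  1L
}

creep_xy <- function(data, onset) {
  stopifnot(is.data.frame(data),
            all(c("time_s", "length_um") %in% names(data)))
  tt <- data$time_s
  ll <- data$length_um
  if (anyNA(tt) || anyNA(ll) || any(!is.finite(tt)) || any(!is.finite(ll))) {
    abort("`time_s` and `length_um` must be finite and non-missing.")
  }
  if (any(diff(tt) <= 0)) abort("`time_s` must be strictly increasing.")
  if (any(ll < 0)) abort("`length_um` must be non-negative.")
  if (identical(onset, "detect")) onset <- detect_onset(ll)
  if (identical(onset, "none")) onset <- 1L
  onset <- as.integer(onset)
  if (onset < 1L || onset > length(tt)) abort("`onset` is out of range.")
  list(t = tt[onset:length(tt)] - tt[onset], l = ll[onset:length(ll)],
       onset = onset)
}

mm_start <- function(t, l) {
  # straight line through the final third: slope -> l_dot_inf, intercept ->
  # delta (the graphical definition of the elastic deformation)
  i <- which(t >= t[1] + 2 / 3 * (max(t) - t[1]))
  if (length(i) < 3) i <- seq_along(t)
  cf <- coef(lm(l[i] ~ t[i]))
  d0 <- max(cf[[1]], 1e-3)
  v0 <- max(cf[[2]], 0)
  b0 <- min(max(1 - l[1] / d0, 0.05), 0.95)
  dt <- stats::median(diff(t))
  list(delta = d0, beta = b0, tau_c = 5 * dt, l_dot_inf = v0)
}

mm_bounds <- list(lower = c(delta = 1e-9, beta = 0, tau_c = 1e-9,
                            l_dot_inf = 0),
                  upper = c(delta = Inf, beta = 1, tau_c = Inf,
                            l_dot_inf = Inf))

fit_mm_once <- function(t, l, start) {
  df <- data.frame(.t = t, .l = l)
  tryCatch(
    suppressWarnings(
      nls(.l ~ delta * (1 - beta * exp(-.t / tau_c)) + l_dot_inf * .t,
          data = df, start = start, algorithm = "port",
          lower = mm_bounds$lower, upper = mm_bounds$upper,
          control = nls.control(maxiter = 500, warnOnly = TRUE))
    ),
    error = function(e) NULL
  )
}

new_creep_fit <- function(params, vcov, r_squared, data, fitted, converged,
                          onset, message = NA_character_) {
  structure(
    list(params = params, vcov = vcov, r_squared = r_squared,
         n_points = length(fitted), data = data, fitted = fitted,
         converged = converged, onset = onset, message = message),
    class = "creep_fit"
  )
}

#' Fit the modified Maxwell model to a creep curve
#'
#' Bounded nonlinear least squares (Gauss-Newton with box constraints) of
#' the four-parameter creep law [creep_length()] to a measured curve.
#' Parameters are constrained to \eqn{\delta > 0}, \eqn{\beta \in [0,1]},
#' \eqn{\tau_c > 0}, \eqn{\dot L_\infty \ge 0}. Starting values come from a
#' straight-line fit to the final third of the record (slope and intercept),
#' mirroring the graphical reading of \eqn{\delta} as the linear-tail
#' intercept. The loss is plain (unweighted) least squares and the fit is
#' deterministic given the data.
#'
#' @param data Data frame with columns `time_s` and `length_um` (the
#'   creep-curve CSV schema; extra columns are ignored).
#' @param onset Either `"none"` (default: the record starts at the pressure
#'   step, \eqn{t=0} is the first row), `"detect"` (baseline jump detection
#'   via [detect_onset()]), or an integer frame index. Times are re-zeroed
#'   at the onset.
#' @param extra_starts Optional list of additional named starting-value
#'   lists; the fit with the lowest residual sum of squares wins. Used by
#'   [fit_nested_models()] to guarantee the nested-model ordering of
#'   goodness of fit.
#'
#' @return An object of class `"creep_fit"`: a list with elements `params`
#'   (named vector `delta`, `beta`, `tau_c`, `l_dot_inf`), `vcov` (4x4
#'   covariance of the estimates), `r_squared`, `n_points`, `data` (the
#'   post-onset series actually fitted), `fitted`, `converged`, `onset`.
#'   Supports [tidy()], [glance()], [augment()] and [autoplot()].
#' @export
#' @examples
#' curve <- simulate_creep(delta = 90, beta = 0.6, tau_c = 10,
#'                         l_dot_inf = 0.167, noise_sd = 2, seed = 7)
#' fit <- fit_modified_maxwell(curve)
#' tidy(fit)
#' glance(fit)
fit_modified_maxwell <- function(data, onset = "none", extra_starts = NULL) {
  xy <- creep_xy(data, onset)
  t <- xy$t
  l <- xy$l
  if (length(t) < 10L) {
    abort("At least 10 post-onset points are required to fit 4 parameters.")
  }
  starts <- c(list(mm_start(t, l)), extra_starts %||% list())
  fits <- purrr::compact(purrr::map(starts, ~ fit_mm_once(t, l, .x)))
  post <- tibble(time_s = t, length_um = l)
  if (length(fits) == 0) {
    return(new_creep_fit(
      params = setNames(rep(NA_real_, 4),
                        c("delta", "beta", "tau_c", "l_dot_inf")),
      vcov = matrix(NA_real_, 4, 4), r_squared = NA_real_, data = post,
      fitted = rep(NA_real_, length(t)), converged = FALSE, onset = xy$onset,
      message = "all starting points failed"
    ))
  }
  rss <- vapply(fits, function(f) sum(stats::resid(f)^2), numeric(1))
  best <- fits[[which.min(rss)]]
  conv <- isTRUE(best$convInfo$isConv)
  params <- coef(best)[c("delta", "beta", "tau_c", "l_dot_inf")]
  vc <- tryCatch(vcov(best), error = function(e) matrix(NA_real_, 4, 4))
  dimnames(vc) <- list(names(params), names(params))
  fitted_l <- as.numeric(stats::fitted(best))
  sst <- sum((l - mean(l))^2)
  r2 <- if (sst > 0) 1 - min(rss) / sst else NA_real_
  new_creep_fit(params, vc, r2, post, fitted_l, conv, xy$onset,
                message = if (conv) NA_character_ else
                  "solver did not report convergence")
}

#' @export
print.creep_fit <- function(x, ...) {
  cat("Modified Maxwell creep fit (", x$n_points, " points)\n", sep = "")
  if (isTRUE(x$converged)) {
    p <- x$params
    cat(sprintf(
      "  delta = %.3g um, beta = %.3g, tau_c = %.3g s, l_dot_inf = %.3g um/s\n",
      p[["delta"]], p[["beta"]], p[["tau_c"]], p[["l_dot_inf"]]))
    cat(sprintf("  R-squared = %.5f\n", x$r_squared))
  } else {
    cat("  NOT CONVERGED: ", x$message, "\n", sep = "")
  }
  invisible(x)
}

#' @rdname fit_modified_maxwell
#' @param x A `creep_fit` object.
#' @param ... Unused.
#' @export
tidy.creep_fit <- function(x, ...) {
  se <- sqrt(pmax(diag(x$vcov), 0))
  tibble(
    term = names(x$params),
    estimate = as.numeric(x$params),
    std.error = as.numeric(se)
  )
}

#' @rdname fit_modified_maxwell
#' @export
glance.creep_fit <- function(x, ...) {
  tibble(r.squared = x$r_squared, nobs = x$n_points,
         converged = x$converged, onset = x$onset)
}

#' @rdname fit_modified_maxwell
#' @export
augment.creep_fit <- function(x, ...) {
  dplyr::mutate(x$data, .fitted = x$fitted,
                .resid = .data$length_um - x$fitted)
}

# wide one-row parameter table used by fit_cohort()
creep_fit_row <- function(fit) {
  se <- sqrt(pmax(diag(fit$vcov), 0))
  tibble(
    delta_um = fit$params[["delta"]], beta = fit$params[["beta"]],
    tau_c_s = fit$params[["tau_c"]],
    l_dot_inf_um_s = fit$params[["l_dot_inf"]],
    se_delta_um = se[["delta"]], se_l_dot_inf_um_s = se[["l_dot_inf"]],
    r_squared = fit$r_squared, n_points = fit$n_points,
    converged = fit$converged
  )
}

#' Compare nested spring-dashpot creep models
#'
#' Fits four nested models to one creep curve and reports their coefficients
#' of determination:
#' \describe{
#'   \item{maxwell}{\eqn{L = \delta + \dot L_\infty t} (spring and dashpot in
#'     series; linear fit).}
#'   \item{kelvin_voigt}{\eqn{L = \delta (1 - e^{-t/\tau_c})} (saturating
#'     rise, no flow).}
#'   \item{sls}{\eqn{L = \delta (1 - \beta e^{-t/\tau_c})} (standard linear
#'     solid, no flow).}
#'   \item{modified_maxwell}{the full four-parameter law [creep_length()].}
#' }
#' The full model nests the other three, so its residual sum of squares can
#' never be worse; to guarantee that ordering numerically, the sub-model
#' solutions are also supplied as starting points for the full fit.
#'
#' @inheritParams fit_modified_maxwell
#'
#' @return A tibble with one row per model: `model`, `n_params`,
#'   `r_squared`, `params` (list-column of named estimates).
#' @export
#' @examples
#' curve <- simulate_creep(90, 0.6, 10, 0.167, noise_sd = 2, seed = 1)
#' fit_nested_models(curve)
fit_nested_models <- function(data, onset = "none") {
  xy <- creep_xy(data, onset)
  t <- xy$t
  l <- xy$l
  if (length(t) < 10L) {
    abort("At least 10 post-onset points are required.")
  }
  df <- data.frame(.t = t, .l = l)
  sst <- sum((l - mean(l))^2)
  r2_of <- function(rss) if (sst > 0) 1 - rss / sst else NA_real_

  # (a) pure Maxwell: linear
  lm_fit <- lm(.l ~ .t, data = df)
  p_a <- c(delta = unname(coef(lm_fit)[1]), l_dot_inf = unname(coef(lm_fit)[2]))
  rss_a <- sum(stats::resid(lm_fit)^2)

  # (b) Kelvin-Voigt: delta (1 - exp(-t/tau))
  st <- mm_start(t, l)
  kv <- tryCatch(
    suppressWarnings(nls(.l ~ delta * (1 - exp(-.t / tau_c)), data = df,
        start = list(delta = max(l[length(l)], 1e-3), tau_c = st$tau_c),
        algorithm = "port", lower = c(1e-9, 1e-9),
        control = nls.control(maxiter = 500, warnOnly = TRUE))),
    error = function(e) NULL)

  # (c) standard linear solid: delta (1 - beta exp(-t/tau))
  sls <- tryCatch(
    suppressWarnings(nls(.l ~ delta * (1 - beta * exp(-.t / tau_c)), data = df,
        start = list(delta = max(l[length(l)], 1e-3), beta = st$beta,
                     tau_c = st$tau_c),
        algorithm = "port", lower = c(1e-9, 0, 1e-9), upper = c(Inf, 1, Inf),
        control = nls.control(maxiter = 500, warnOnly = TRUE))),
    error = function(e) NULL)

  # (d) full model, additionally seeded from the sub-model optima
  extra <- list(
    list(delta = max(p_a[["delta"]], 1e-3), beta = 0.001, tau_c = st$tau_c,
         l_dot_inf = max(p_a[["l_dot_inf"]], 0))
  )
  if (!is.null(kv)) {
    ck <- coef(kv)
    extra <- c(extra, list(list(delta = ck[["delta"]], beta = 0.999,
                                tau_c = ck[["tau_c"]], l_dot_inf = 1e-9)))
  }
  if (!is.null(sls)) {
    cs <- coef(sls)
    extra <- c(extra, list(list(delta = cs[["delta"]], beta = cs[["beta"]],
                                tau_c = cs[["tau_c"]], l_dot_inf = 1e-9)))
  }
  mm <- fit_modified_maxwell(tibble(time_s = t, length_um = l),
                             extra_starts = extra)

  rows <- list(
    tibble(model = "maxwell", n_params = 2L, r_squared = r2_of(rss_a),
           params = list(p_a)),
    if (!is.null(kv)) {
      tibble(model = "kelvin_voigt", n_params = 2L,
             r_squared = r2_of(sum(stats::resid(kv)^2)),
             params = list(coef(kv)))
    },
    if (!is.null(sls)) {
      tibble(model = "sls", n_params = 3L,
             r_squared = r2_of(sum(stats::resid(sls)^2)),
             params = list(coef(sls)))
    },
    tibble(model = "modified_maxwell", n_params = 4L,
           r_squared = mm$r_squared, params = list(mm$params))
  )
  dplyr::bind_rows(purrr::compact(rows))
}
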