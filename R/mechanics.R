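#' Aspiration force on a spheroid tongue
#'
#' Force exerted on the tongue by the net aspiration pressure, assuming
#' volume conservation of the spheroid:
#' \eqn{f = \pi R_{\mathrm{eff}}^2 (\Delta P - \Delta P_c)}.
#'
#' @param r_eff_um Effective channel radius in micrometres.
#' @param delta_p Applied pressure step in Pa.
#' @param delta_p_c Critical aspiration pressure in Pa (default 0).
#'
#' @return Force in newtons.
#' @export
#' @examples
#' aspiration_force(27, 700)  # about 1.6e-6 N
aspiration_force <- function(r_eff_um, delta_p, delta_p_c = 0) {
  if (any(r_eff_um <= 0)) abort("`r_eff_um` must be positive.")
  if (any(delta_p <= delta_p_c)) {
    abort("`delta_p` must exceed `delta_p_c`: no aspiration occurs otherwise.")
  }
  pi * (r_eff_um * 1e-6)^2 * (delta_p - delta_p_c)
}

#' Elastic modulus from the fitted elastic deformation
#'
#' Converts the fitted instantaneous-plus-rising elastic deformation
#' \eqn{\delta} (the intercept of the long-time linear flow extrapolated to
#' \eqn{t = 0}) into an elastic modulus. With spring constant
#' \eqn{k_1 = \pi R_{\mathrm{eff}} E} and \eqn{\delta = f / k_1},
#' \deqn{E = \frac{f}{\pi R_{\mathrm{eff}} \delta}
#'         = \frac{R_{\mathrm{eff}} (\Delta P - \Delta P_c)}{\delta}.}
#'
#' @param delta_um Elastic deformation \eqn{\delta} in micrometres.
#' @param r_eff_um Effective channel radius in micrometres.
#' @param delta_p,delta_p_c Applied and critical pressure in Pa.
#'
#' @return Elastic modulus in Pa.
#' @export
#' @examples
#' elastic_modulus(90, 27, 700)  # 210 Pa
elastic_modulus <- function(delta_um, r_eff_um, delta_p, delta_p_c = 0) {
  if (any(delta_um <= 0)) abort("`delta_um` must be positive.")
  if (any(r_eff_um <= 0)) abort("`r_eff_um` must be positive.")
  if (any(delta_p <= delta_p_c)) {
    abort("`delta_p` must exceed `delta_p_c`.")
  }
  r_eff_um * (delta_p - delta_p_c) / delta_um
}

#' Tissue viscosity from the long-time flow velocity
#'
#' Converts the fitted long-time tongue velocity \eqn{\dot L_\infty} into a
#' viscosity. With the tongue friction coefficient
#' \eqn{\xi_t = 3 \pi^2 \eta R_{\mathrm{eff}}} and
#' \eqn{\dot L_\infty = f / \xi_t},
#' \deqn{\eta = \frac{f}{3\pi^2 R_{\mathrm{eff}} \dot L_\infty}
#'            = \frac{R_{\mathrm{eff}} (\Delta P - \Delta P_c)}
#'                   {3\pi \dot L_\infty}.}
#'
#' @param l_dot_inf_um_s Long-time flow velocity in micrometres per second.
#' @param r_eff_um Effective channel radius in micrometres.
#' @param delta_p,delta_p_c Applied and critical pressure in Pa.
#'
#' @return Viscosity in Pa s.
#' @export
#' @examples
#' tissue_viscosity(0.167, 27, 700)  # about 1.2e4 Pa s (12 kPa s)
tissue_viscosity <- function(l_dot_inf_um_s, r_eff_um, delta_p, delta_p_c = 0) {
  if (any(l_dot_inf_um_s <= 0)) abort("`l_dot_inf_um_s` must be positive.")
  if (any(r_eff_um <= 0)) abort("`r_eff_um` must be positive.")
  if (any(delta_p <= delta_p_c)) {
    abort("`delta_p` must exceed `delta_p_c`.")
  }
  r_eff_um * (delta_p - delta_p_c) / (3 * pi * l_dot_inf_um_s)
}

# 1-sigma of R_eff induced by independent errors on W and H (delta method,
# central differences).
r_eff_sigma <- function(geometry, dim_error_um) {
  if (dim_error_um == 0) return(0)
  w <- geometry$width_um
  h <- geometry$height_um
  step <- 1e-3 * min(w, h)
  dw <- (effective_radius(w + step, h) - effective_radius(w - step, h)) /
    (2 * step)
  dh <- (effective_radius(w, h + step) - effective_radius(w, h - step)) /
    (2 * step)
  sqrt((dw * dim_error_um)^2 + (dh * dim_error_um)^2)
}

#' Mechanical parameters with propagated uncertainties
#'
#' Converts a fitted creep model into aspiration force, elastic modulus,
#' viscosity and relaxation time \eqn{\tau = \eta / E}, propagating to first
#' order (delta method, independent sources combined in quadrature):
#' the fit standard errors of \eqn{\delta} and \eqn{\dot L_\infty}, the
#' pressure-reading error, and the channel-dimension error (through
#' \eqn{R_{\mathrm{eff}}}).
#'
#' Since \eqn{E} and \eqn{\eta} are products/ratios of the inputs, relative
#' variances add:
#' \deqn{\Big(\frac{s_E}{E}\Big)^2 =
#'   \Big(\frac{s_R}{R_{\mathrm{eff}}}\Big)^2 +
#'   \Big(\frac{s_{\Delta P}}{\Delta P - \Delta P_c}\Big)^2 +
#'   \Big(\frac{s_\delta}{\delta}\Big)^2,}
#' and likewise for \eqn{\eta} with \eqn{s_{\dot L_\infty}}.
#'
#' @param fit A `creep_fit` object from [fit_modified_maxwell()], with a
#'   finite parameter covariance (converged fit).
#' @param geometry A [channel_geometry()] record.
#' @param conditions An [aspiration_conditions()] record.
#'
#' @return A one-row tibble with columns `f_n`, `e_pa`, `se_e_pa`,
#'   `eta_pa_s`, `se_eta_pa_s`, `eta_kpa_s`, `tau_s`.
#' @export
propagate_uncertainty <- function(fit, geometry, conditions) {
  stopifnot(inherits(fit, "creep_fit"))
  if (!isTRUE(fit$converged) || anyNA(fit$vcov)) {
    abort("Fit covariance unavailable: the fit did not converge.")
  }
  p <- fit$params
  if (p[["l_dot_inf"]] <= 0) {
    abort("Fitted `l_dot_inf` is not positive; viscosity is undefined.")
  }
  r <- geometry$r_eff_um
  net <- conditions$delta_p - conditions$delta_p_c
  se <- sqrt(pmax(diag(fit$vcov), 0))
  e <- elastic_modulus(p[["delta"]], r, conditions$delta_p,
                       conditions$delta_p_c)
  eta <- tissue_viscosity(p[["l_dot_inf"]], r, conditions$delta_p,
                          conditions$delta_p_c)
  s_r <- r_eff_sigma(geometry, conditions$dimension_error_um)
  rel2 <- (s_r / r)^2 + (conditions$delta_p_error / net)^2
  se_e <- e * sqrt(rel2 + (se[["delta"]] / p[["delta"]])^2)
  se_eta <- eta * sqrt(rel2 + (se[["l_dot_inf"]] / p[["l_dot_inf"]])^2)
  tibble(
    f_n = aspiration_force(r, conditions$delta_p, conditions$delta_p_c),
    e_pa = e, se_e_pa = se_e,
    eta_pa_s = eta, se_eta_pa_s = se_eta,
    eta_kpa_s = eta / 1e3,
    tau_s = eta / e
  )
}

#' Derive mechanics for a table of fitted curves
#'
#' Data-frame verb that appends mechanical parameters (and their propagated
#' standard errors) to a cohort table carrying a `fit` list-column of
#' `creep_fit` objects, as produced by [fit_cohort()]. Rows whose fit did
#' not converge (or that are flagged `excluded`) get `NA` mechanics.
#'
#' @param fits A data frame with a `fit` list-column.
#' @param geometry A [channel_geometry()] record.
#' @param conditions An [aspiration_conditions()] record.
#'
#' @return The input tibble with columns `f_n`, `e_pa`, `se_e_pa`,
#'   `eta_pa_s`, `se_eta_pa_s`, `eta_kpa_s`, `tau_s` appended.
#' @export
derive_mechanics <- function(fits, geometry, conditions) {
  stopifnot(is.data.frame(fits), "fit" %in% names(fits))
  na_row <- tibble(
    f_n = NA_real_, e_pa = NA_real_, se_e_pa = NA_real_,
    eta_pa_s = NA_real_, se_eta_pa_s = NA_real_, eta_kpa_s = NA_real_,
    tau_s = NA_real_
  )
  excl <- if ("excluded" %in% names(fits)) fits$excluded else
    rep(FALSE, nrow(fits))
  mech <- purrr::map2(fits$fit, excl, function(f, ex) {
    if (ex || is.null(f) || !isTRUE(f$converged)) return(na_row)
    propagate_uncertainty(f, geometry, conditions)
  })
  dplyr::bind_cols(as_tibble(fits), dplyr::bind_rows(mech))
}
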