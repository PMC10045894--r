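#' Aspect-ratio factor for laminar flow in a rectangular duct
#'
#' Computes the dimensionless correction factor \eqn{f^*(a)} appearing in the
#' series solution for fully developed laminar flow through a rectangular
#' duct of cross-section \eqn{W \times H} (aspect ratio \eqn{a = H/W} with
#' \eqn{H \le W}):
#' \deqn{f^*(a) = 1 - \frac{192}{\pi^5}\, a \sum_{n\ \mathrm{odd}}
#'   \frac{\tanh\!\big(n\pi/(2a)\big)}{n^5}.}
#' The volumetric conductance of the duct per unit length and unit pressure
#' gradient is \eqn{W H^3 f^*(H/W) / (12\mu)}. In the infinite-slit limit
#' \eqn{a \to 0} the factor tends to 1; for a square duct
#' \eqn{f^*(1) \approx 0.4217}.
#'
#' @param aspect_ratio Numeric vector in \eqn{(0, 1]}: the ratio of the
#'   smaller to the larger cross-sectional dimension, \eqn{\min(W,H)/\max(W,H)}.
#' @param tol Series truncation tolerance; summation stops once a term falls
#'   below `tol`. Terms are bounded by \eqn{1/n^5}, so the default reaches
#'   machine-level accuracy.
#'
#' @return Numeric vector of factors in \eqn{(0, 1)}.
#' @seealso [effective_radius()], [rect_resistance()]
#' @export
#' @examples
#' son_aspect_factor(1)     # square duct
#' son_aspect_factor(0.5)   # 2:1 duct
son_aspect_factor <- function(aspect_ratio, tol = 1e-12) {
  if (!is.numeric(aspect_ratio) || length(aspect_ratio) == 0) {
    abort("`aspect_ratio` must be a non-empty numeric vector.")
  }
  if (any(!is.finite(aspect_ratio)) ||
      any(aspect_ratio <= 0) || any(aspect_ratio > 1)) {
    abort("`aspect_ratio` must lie in (0, 1]: pass min(W, H) / max(W, H).")
  }
  vapply(aspect_ratio, function(a) {
    s <- 0
    n <- 1
    repeat {
      term <- tanh(n * pi / (2 * a)) / n^5
      s <- s + term
      if (term < tol) break
      n <- n + 2
    }
    1 - (192 / pi^5) * a * s
  }, numeric(1))
}

#' Effective radius of a rectangular aspiration channel
#'
#' Radius of the circular duct with the same Poiseuille conductance per unit
#' length as a rectangular duct of width `width_um` and height `height_um`.
#' Equating \eqn{\pi R_{\mathrm{eff}}^4 / 8} with
#' \eqn{W_{\max} H_{\min}^3 f^*(H_{\min}/W_{\max}) / 12} gives
#' \deqn{R_{\mathrm{eff}} = \Big(\tfrac{2}{3\pi}\, f^* \,
#'   W_{\max} H_{\min}^3\Big)^{1/4}.}
#' This effective radius stands in for the pipette radius when converting
#' creep parameters measured in square microfluidic channels into elastic
#' modulus and viscosity. For the 50 um square channel it evaluates to
#' approximately 27 um.
#'
#' @param width_um,height_um Cross-sectional dimensions in micrometres.
#'   Vectors are recycled to a common length. The result is symmetric in the
#'   two arguments.
#'
#' @return Effective radius in micrometres.
#' @export
#' @examples
#' effective_radius(50, 50)
#' round(effective_radius(50, 50))  # the printed channel radius, 27 um
effective_radius <- function(width_um, height_um) {
  if (any(!is.finite(width_um)) || any(!is.finite(height_um)) ||
      any(width_um <= 0) || any(height_um <= 0)) {
    abort("Channel dimensions must be finite and strictly positive.")
  }
  w <- pmax(width_um, height_um)
  h <- pmin(width_um, height_um)
  fs <- son_aspect_factor(h / w)
  (2 * fs * w * h^3 / (3 * pi))^(1 / 4)
}

#' Channel geometry record
#'
#' Bundles the physical dimensions of an aspiration channel with its derived
#' effective radius into a one-row tibble used by the mechanics and network
#' functions.
#'
#' @param width_um Channel width in micrometres (default 50, the chip's
#'   aspiration-channel width).
#' @param height_um Channel height in micrometres (default 50).
#' @param length_um Channel length in micrometres; only the hydraulic network
#'   uses it. Default 300, chosen so that with all eight pockets open the
#'   per-channel pressure drop is a few tens of pascal for a 700 Pa step
#'   (see [chip_network()]).
#' @param r_eff_um Effective radius in micrometres. Defaults to
#'   [effective_radius()] of the cross-section at full precision; pass an
#'   explicit value (for instance the conventionally quoted rounded 27 um)
#'   to reproduce derivations that use a rounded radius.
#'
#' @return A tibble of class `"channel_geometry"` with columns `width_um`,
#'   `height_um`, `length_um`, `r_eff_um`.
#' @export
#' @examples
#' channel_geometry()
#' channel_geometry(50, 50, r_eff_um = 27)
channel_geometry <- function(width_um = 50, height_um = 50, length_um = 300,
                             r_eff_um = NULL) {
  if (any(c(width_um, height_um, length_um) <= 0) ||
      any(!is.finite(c(width_um, height_um, length_um)))) {
    abort("Channel dimensions must be finite and strictly positive.")
  }
  r <- r_eff_um %||% effective_radius(width_um, height_um)
  if (r <= 0 || r >= max(width_um, height_um)) {
    abort("`r_eff_um` must be positive and smaller than the larger duct side.")
  }
  out <- tibble(
    width_um = width_um, height_um = height_um,
    length_um = length_um, r_eff_um = r
  )
  class(out) <- c("channel_geometry", class(out))
  out
}

#' Aspiration pressure conditions
#'
#' Applied hydrostatic step pressure, optional critical aspiration pressure,
#' and instrument uncertainties used for error propagation.
#'
#' The critical pressure `delta_p_c` is the threshold below which tissue
#' surface tension prevents any tongue from entering the channel; the net
#' aspiration pressure is `delta_p - delta_p_c`. It defaults to 0 because the
#' chip cannot measure the retraction curves needed to determine it; glass
#' micropipette measurements place it in the 50--150 Pa range, which shifts
#' derived moduli by 10--30% at a 500 Pa step.
#'
#' @param delta_p Applied pressure step in Pa.
#' @param delta_p_c Critical aspiration pressure in Pa (default 0).
#' @param delta_p_error 1-sigma uncertainty of the pressure reading in Pa.
#'   Default 20 Pa, the reading error of a ruler graduated in 0.2 cmH2O.
#' @param dimension_error_um 1-sigma uncertainty of each channel
#'   cross-section dimension in micrometres (default 5, profilometer scale).
#'
#' @return A tibble of class `"aspiration_conditions"`.
#' @export
#' @examples
#' aspiration_conditions(700)
#' aspiration_conditions(500, delta_p_c = 100)
aspiration_conditions <- function(delta_p = 700, delta_p_c = 0,
                                  delta_p_error = 20,
                                  dimension_error_um = 5) {
  if (!is.finite(delta_p) || !is.finite(delta_p_c)) {
    abort("Pressures must be finite.")
  }
  if (delta_p_c < 0) abort("`delta_p_c` must be non-negative.")
  if (delta_p <= delta_p_c) {
    abort("`delta_p` must exceed `delta_p_c`: no aspiration occurs otherwise.")
  }
  if (delta_p_error < 0 || dimension_error_um < 0) {
    abort("Uncertainties must be non-negative.")
  }
  out <- tibble(
    delta_p = delta_p, delta_p_c = delta_p_c,
    delta_p_error = delta_p_error, dimension_error_um = dimension_error_um
  )
  class(out) <- c("aspiration_conditions", class(out))
  out
}
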