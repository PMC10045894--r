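#' Hydraulic resistance of a rectangular duct
#'
#' Lumped Poiseuille resistance of a rectangular channel in laminar flow,
#' \deqn{R = \frac{12 \mu L}{W_{\max} H_{\min}^3 f^*(H_{\min}/W_{\max})},}
#' with the aspect-ratio series factor [son_aspect_factor()]. By the
#' definition of the effective radius this equals
#' \eqn{8 \mu L / (\pi R_{\mathrm{eff}}^4)}, the resistance of the
#' hydraulically equivalent circular duct.
#'
#' @param width_um,height_um Cross-section in micrometres.
#' @param length_um Duct length in micrometres.
#' @param mu_pa_s Dynamic viscosity of the medium in Pa s (default 7e-4,
#'   water-like culture medium at 37 C).
#'
#' @return Resistance in Pa s per cubic metre.
#' @export
#' @examples
#' rect_resistance(300, 300, 6e5)  # the 60 cm outlet tube
rect_resistance <- function(width_um, height_um, length_um,
                            mu_pa_s = 7e-4) {
  if (any(c(width_um, height_um, length_um, mu_pa_s) <= 0)) {
    abort("All duct dimensions and the viscosity must be positive.")
  }
  w <- pmax(width_um, height_um) * 1e-6
  h <- pmin(width_um, height_um) * 1e-6
  fs <- son_aspect_factor(h / w)
  12 * mu_pa_s * (length_um * 1e-6) / (w * h^3 * fs)
}

#' Lumped hydraulic network of the aspiration chip
#'
#' One-dimensional resistor-network abstraction of the chip: an inlet
#' resistance in series with `n_pockets` parallel branches (each a pocket
#' plus its aspiration channel) and the long outlet tube. A clogged pocket
#' (one holding a spheroid) carries no flow; its channel then sees the
#' static pressure difference between the two manifolds. Once every pocket
#' is clogged no flow remains anywhere and the full hydrostatic step
#' appears across every channel -- the condition under which measurements
#' are valid.
#'
#' @param n_pockets Number of parallel pockets (default 8).
#' @param channel_geometry A [channel_geometry()] record for the aspiration
#'   channels (default 50 x 50 um cross-section, 300 um long).
#' @param pocket_width_um,pocket_height_um,pocket_length_um Pocket duct
#'   dimensions (defaults 250 x 325 um cross-section, 250 um long).
#' @param outlet_width_um,outlet_height_um,outlet_length_um Outlet tube
#'   modelled as a rectangular duct (defaults 300 x 300 um by 60 cm).
#' @param inlet_resistance Hydraulic resistance of the loading bay in
#'   Pa s m^-3 (default 0: a wide bay with negligible drop).
#' @param mu_pa_s Medium viscosity in Pa s (default 7e-4).
#' @param clogged Logical vector of length `n_pockets` (default all open).
#'
#' @return An object of class `"chip_network"`.
#' @export
#' @examples
#' chip <- chip_network(clogged = rep(c(TRUE, FALSE), each = 4))
#' solve_network(chip, 700)
chip_network <- function(n_pockets = 8,
                         channel_geometry = spheromech::channel_geometry(),
                         pocket_width_um = 250, pocket_height_um = 325,
                         pocket_length_um = 250,
                         outlet_width_um = 300, outlet_height_um = 300,
                         outlet_length_um = 6e5,
                         inlet_resistance = 0, mu_pa_s = 7e-4,
                         clogged = rep(FALSE, n_pockets)) {
  if (n_pockets < 1) abort("`n_pockets` must be at least 1.")
  clogged <- rep_len(as.logical(clogged), n_pockets)
  r_channel <- rect_resistance(channel_geometry$width_um,
                               channel_geometry$height_um,
                               channel_geometry$length_um, mu_pa_s)
  r_pocket <- rect_resistance(pocket_width_um, pocket_height_um,
                              pocket_length_um, mu_pa_s)
  r_outlet <- rect_resistance(outlet_width_um, outlet_height_um,
                              outlet_length_um, mu_pa_s)
  if (inlet_resistance < 0) abort("`inlet_resistance` must be >= 0.")
  structure(
    list(n_pockets = n_pockets, r_channel = r_channel, r_pocket = r_pocket,
         r_outlet = r_outlet, r_inlet = inlet_resistance,
         clogged = clogged),
    class = "chip_network"
  )
}

#' @export
print.chip_network <- function(x, ...) {
  cat(sprintf("Chip network: %d pockets (%d clogged)\n", x$n_pockets,
              sum(x$clogged)))
  cat(sprintf("  R_channel %.3g, R_pocket %.3g, R_outlet %.3g Pa s/m^3\n",
              x$r_channel, x$r_pocket, x$r_outlet))
  invisible(x)
}

#' Solve the chip's hydraulic network
#'
#' Solves the linear resistor network for the manifold pressures by flow
#' conservation (Kirchhoff's current law at the two internal nodes), then
#' reports per-pocket flows and the pressure drop across each aspiration
#' channel. Open branches drop `flow * R_channel` across the channel;
#' clogged branches carry no flow, so their channel drop is the static
#' manifold difference -- the pressure felt by the spheroid blocking it.
#'
#' @param chip A [chip_network()].
#' @param delta_p_total Total hydrostatic step between inlet reservoir and
#'   outlet vial, in Pa.
#'
#' @return A tibble with one row per pocket: `pocket`, `clogged`,
#'   `flow_m3_s`, `channel_drop_pa`. Attributes `node_pressures` (named
#'   vector: inlet, manifold_a, manifold_b, outlet) and
#'   `conservation_residual` (largest relative node imbalance) are
#'   attached.
#' @export
solve_network <- function(chip, delta_p_total) {
  stopifnot(inherits(chip, "chip_network"))
  if (!is.finite(delta_p_total) || delta_p_total < 0) {
    abort("`delta_p_total` must be a non-negative pressure in Pa.")
  }
  r_branch <- chip$r_pocket + chip$r_channel
  g_branch <- ifelse(chip$clogged, 0, 1 / r_branch)
  g_sum <- sum(g_branch)
  g_out <- 1 / chip$r_outlet

  if (chip$r_inlet > 0) {
    g_in <- 1 / chip$r_inlet
    # unknown node pressures p = (P_A, P_B); Laplacian solve
    a_mat <- matrix(c(g_in + g_sum, -g_sum,
                      -g_sum, g_sum + g_out), 2, 2, byrow = TRUE)
    b_vec <- c(g_in * delta_p_total, 0)
    p <- solve(a_mat, b_vec)
    p_a <- p[1]
    p_b <- p[2]
  } else {
    p_a <- delta_p_total
    p_b <- if (g_sum + g_out > 0) delta_p_total * g_sum / (g_sum + g_out)
           else 0
  }

  flows <- g_branch * (p_a - p_b)
  drop <- ifelse(chip$clogged, p_a - p_b, flows * chip$r_channel)
  q_out <- g_out * p_b
  scale <- max(abs(c(flows, q_out)), .Machine$double.eps)
  residual <- max(abs(sum(flows) - q_out),
                  if (chip$r_inlet > 0) {
                    abs((delta_p_total - p_a) / chip$r_inlet - sum(flows))
                  } else 0) / scale

  out <- tibble(
    pocket = seq_len(chip$n_pockets),
    clogged = chip$clogged,
    flow_m3_s = flows,
    channel_drop_pa = drop
  )
  attr(out, "node_pressures") <- c(inlet = delta_p_total, manifold_a = p_a,
                                   manifold_b = p_b, outlet = 0)
  attr(out, "conservation_residual") <- residual
  out
}

#' Channel pressure drop as pockets clog
#'
#' Convenience sweep over the number of clogged pockets, reporting the drop
#' across a still-open channel (and across clogged ones) at each stage.
#' Demonstrates the redistribution effect: the drop over the remaining open
#' channels grows monotonically as pockets fill, and jumps to the full step
#' pressure when the last pocket clogs.
#'
#' @param chip A [chip_network()]; its `clogged` state is ignored.
#' @param delta_p_total Total step pressure in Pa.
#' @param n_clogged Integer vector of clogging stages (default
#'   `0:n_pockets`).
#'
#' @return A tibble: `n_clogged`, `open_drop_pa` (`NA` when none open),
#'   `clogged_drop_pa` (`NA` when none clogged).
#' @export
sweep_clogging <- function(chip, delta_p_total,
                           n_clogged = 0:chip$n_pockets) {
  purrr::map_dfr(n_clogged, function(k) {
    cl <- rep(FALSE, chip$n_pockets)
    if (k > 0) cl[seq_len(k)] <- TRUE
    chip$clogged <- cl
    sol <- solve_network(chip, delta_p_total)
    tibble(
      n_clogged = k,
      open_drop_pa = if (any(!sol$clogged))
        sol$channel_drop_pa[!sol$clogged][1] else NA_real_,
      clogged_drop_pa = if (any(sol$clogged))
        sol$channel_drop_pa[sol$clogged][1] else NA_real_
    )
  })
}
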