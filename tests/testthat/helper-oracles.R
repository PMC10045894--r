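# Independent numerical oracles used across the suite.

# Brute-force evaluation of the rectangular-duct aspect-ratio series with a
# fixed number of odd terms (no early truncation); kept separate from the
# package implementation on purpose.
fstar_oracle <- function(a, n_terms = 25) {
  n <- seq(1, by = 2, length.out = n_terms)
  1 - (192 / pi^5) * a * sum(tanh(n * pi / (2 * a)) / n^5)
}

# Finite-difference Poisseuille conductance of a rectangular duct:
# solves -laplacian(u) = 1 with u = 0 on the wall (5-point stencil, dense
# solve) and integrates u. Units: returns integral of u over the
# cross-section for a duct W x H (same length units as the inputs), i.e.
# Q * mu * (length / pressure-drop).
fd_duct_conductance <- function(w, h, nx = 40) {
  ny <- max(10, round(nx * h / w))
  hx <- w / (nx + 1)
  hy <- h / (ny + 1)
  n_tot <- nx * ny
  idx <- function(i, j) (j - 1) * nx + i
  a_mat <- matrix(0, n_tot, n_tot)
  for (j in 1:ny) {
    for (i in 1:nx) {
      k <- idx(i, j)
      a_mat[k, k] <- 2 / hx^2 + 2 / hy^2
      if (i > 1) a_mat[k, idx(i - 1, j)] <- -1 / hx^2
      if (i < nx) a_mat[k, idx(i + 1, j)] <- -1 / hx^2
      if (j > 1) a_mat[k, idx(i, j - 1)] <- -1 / hy^2
      if (j < ny) a_mat[k, idx(i, j + 1)] <- -1 / hy^2
    }
  }
  u <- solve(a_mat, rep(1, n_tot))
  sum(u) * hx * hy
}

# Effective radius implied by the finite-difference conductance: the
# circular duct with conductance pi R^4 / 8 matching the rectangle's.
fd_effective_radius <- function(w, h, nx = 40) {
  (8 * fd_duct_conductance(w, h, nx) / pi)^(1 / 4)
}
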