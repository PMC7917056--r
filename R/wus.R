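#' Repressor input of the WUS activation function
#'
#' Affine map `u = h_w + T_wy * y` from the local repressor level to the input
#' of the activation nonlinearity. With the defaults (`h_w = 2`,
#' `T_wy = -30`) WUS is derepressed (`u = 2`) where y is absent and strongly
#' repressed (`u = -28`) where y is at its boundary level of 1.
#'
#' @param y repressor concentration vector.
#' @param wp a [wus_params()].
#' @return dimensionless input vector.
#' @export
repressor_input <- function(y, wp) {
  wp$h_w + wp$T_wy * y
}

#' WUS activation nonlinearity
#'
#' `"mjolsness"` is the saturating sigmoid `g(u) = (1 + u/sqrt(1+u^2))/2`,
#' bounded in (0, 1) with `g(0) = 1/2`; the two `"literal_*"` variants are
#' alternative readings of the printed production bracket
#' (`(1+u)/(1+u^2)` and `1 + u/(1+u^2)`), kept for comparison although they
#' are not sigmoidal and cannot yield the required on/off contrast.
#'
#' @param u dimensionless input (vectorised).
#' @param variant one of `"mjolsness"`, `"literal_ratio"`, `"literal_sum"`.
#' @return activation value(s).
#' @examples
#' activation_sigmoid(0)    # 0.5
#' activation_sigmoid(2)    # ~0.947
#' @export
activation_sigmoid <- function(u, variant = c("mjolsness", "literal_ratio",
                                              "literal_sum")) {
  variant <- match.arg(variant)
  if (any(!is.finite(u))) stop("u must be finite")
  switch(variant,
         mjolsness = 0.5 * (1 + u / sqrt(1 + u^2)),
         literal_ratio = (1 + u) / (1 + u^2),
         literal_sum = 1 + u / (1 + u^2))
}

#' Rate of change of WUS
#'
#' Production `k17_eff * g(h_w + T_wy * y)` against decay `d_w * wus`, scaled
#' from repressor-subsystem time units to seconds by `1/time_scale`. Under the
#' normalized amplitude convention `k17_eff = d_w`, so the derepressed steady
#' level equals `g` (order 1).
#'
#' @param state a [field_state()].
#' @param wp a [wus_params()].
#' @return rate vector (uM/s).
#' @export
wus_rate <- function(state, wp) {
  g <- activation_sigmoid(repressor_input(state$y, wp), wp$sigmoid_variant)
  (k17_effective(wp) * g - wp$d_w * state$wus) / wp$time_scale
}

#' Rate of change of the repressor signal y
#'
#' Production `k_y * L` driven by the boundary signal, decay `d_y * y`, and
#' no-flux lattice diffusion with coefficient `D_y`; scaled to seconds by
#' `1/time_scale`.
#'
#' @param state a [field_state()].
#' @param L binary boundary signal vector.
#' @param wp a [wus_params()].
#' @return rate vector (uM/s).
#' @export
y_rate <- function(state, L, wp) {
  if (length(L) != length(state$y)) stop("L length must match the grid")
  (wp$k_y * L - wp$d_y * state$y + wp$D_y * noflux_laplacian(state$y)) /
    wp$time_scale
}

#' Steady profiles of the repressor subsystem by direct linear solve
#'
#' The y equation is linear, so its steady state solves
#' `(d_y I - D_y Lap) y = k_y L` exactly, with `Lap` the no-flux lattice
#' Laplacian; the steady WUS profile follows pointwise as
#' `k17_eff * g(h_w + T_wy * y) / d_w`. This is an independent oracle for the
#' time-stepped subsystem (it never touches the integrator).
#'
#' @param wp a [wus_params()].
#' @param bc a [boundary_config()].
#' @param grid a [grid_spec()].
#' @return list with components `y_ss` and `wus_ss` (uM vectors).
#' @export
wus_steady_profile <- function(wp, bc = boundary_config("wide", grid),
                               grid = grid_spec()) {
  n <- grid$n_cells
  if (length(bc$L) != n) stop("boundary_config does not match the grid")
  if (wp$d_y <= 0) stop("d_y must be > 0 for a steady state to exist")
  lapm <- matrix(0, n, n)
  for (j in seq_len(n)) {
    lapm[j, j] <- if (j == 1L || j == n) -1 else -2
    if (j > 1L) lapm[j, j - 1L] <- 1
    if (j < n) lapm[j, j + 1L] <- 1
  }
  y_ss <- solve(diag(wp$d_y, n) - wp$D_y * lapm, wp$k_y * bc$L)
  g <- activation_sigmoid(repressor_input(y_ss, wp), wp$sigmoid_variant)
  list(y_ss = as.numeric(y_ss),
       wus_ss = as.numeric(k17_effective(wp) * g / wp$d_w))
}
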