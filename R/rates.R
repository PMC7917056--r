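#' AG-excluded effective AP1 profile
#'
#' AP1 itself neither moves nor is degraded by AG in the model; instead the AG
#' field masks AP1 activity in the cells it occupies. The effective profile is
#' `ap1 * (1 - ag/(ag + beta1))`, i.e. AP1 scaled by a saturating exclusion
#' factor, so `0 <= ap1_T <= ap1` cell-wise and exclusion is half-maximal where
#' `ag = beta1`.
#'
#' @param ap1 AP1 concentration vector (uM).
#' @param ag driving concentration vector (uM), same length.
#' @param beta1 saturation constant (uM), > 0.
#' @return effective AP1 concentration vector.
#' @examples
#' effective_ap1(c(2, 2), c(0, 0.05), beta1 = 0.05)  # 2, 1
#' @export
effective_ap1 <- function(ap1, ag, beta1) {
  if (length(ap1) != length(ag)) stop("ap1 and ag must have the same length")
  if (!is.finite(beta1) || beta1 <= 0) stop("beta1 must be > 0")
  ap1 * (1 - ag / (ag + beta1))
}

#' Unit step gate for AG production
#'
#' AG production is silenced until `gate_time`, standing in for upstream
#' flowering-time regulation that is not modelled mechanistically. The gate is
#' right-continuous: it equals 1 at exactly `t = gate_time`.
#'
#' @param t time (s), >= 0.
#' @param gate_time opening time (s).
#' @return 0 or 1 (vectorised over `t`).
#' @export
heaviside_gate <- function(t, gate_time = 18000) {
  if (any(t < 0)) stop("t must be >= 0")
  as.numeric(t >= gate_time)
}

#' No-flux discrete Laplacian
#'
#' Second difference on the cell lattice with mirrored ghost cells at the two
#' ends, so nothing flows out of the meristem: the output always sums to
#' exactly zero.
#'
#' @param v concentration vector, length >= 3.
#' @return per-cell second difference.
#' @examples
#' noflux_laplacian(c(0, 1, 0))  # 1 -2 1
#' @export
noflux_laplacian <- function(v) {
  n <- length(v)
  if (n < 3) stop("need at least 3 cells")
  c(v[2] - v[1],
    v[seq(3, n)] - 2 * v[seq(2, n - 1)] + v[seq(1, n - 2)],
    v[n - 1] - v[n])
}

## ap1 level seen by the other equations under the chosen feedback reading
.ap1_input <- function(state, opts) {
  if (opts$ap1_feedback == "raw") state$ap1 else state$ap1_T
}

#' Rate of change of LFY
#'
#' Balance of basal activation (k1), activation by AP1 (k2), inactivation by
#' TFL1 (k3), first-order decay (k4), and diffusive coupling to the
#' neighbouring cells with coefficient `epsilon`.
#'
#' @param state a [field_state()].
#' @param p a [kinetic_params()].
#' @param opts a [model_options()].
#' @return rate vector (uM/s).
#' @export
lfy_rate <- function(state, p, opts = model_options()) {
  p$k1 + p$k2 * .ap1_input(state, opts) - p$k3 * state$tfl1 -
    p$k4 * state$lfy + p$epsilon * noflux_laplacian(state$lfy)
}

#' Rate of change of AP1
#'
#' Basal activation (k5), activation by LFY (k6), inactivation by TFL1 (k7)
#' and first-order decay (k8). The AP1 state variable evolves independently of
#' AG; exclusion acts only through the derived `ap1_T` profile.
#'
#' @inheritParams lfy_rate
#' @return rate vector (uM/s).
#' @export
ap1_rate <- function(state, p) {
  p$k5 + p$k6 * state$lfy - p$k7 * state$tfl1 - p$k8 * state$ap1
}

#' Rate of change of AG
#'
#' Production is activated by WUS (k9) and LFY (k10), inhibited
#' noncompetitively by AP1 through the `(beta2 + beta3 * ap1)` denominator,
#' and gated by the unit step that opens at `p$gate_time`; AG is inactivated
#' by TFL1 (k11) and decays at k12. `opts` selects the gate and denominator
#' scope (see [model_options()]).
#'
#' @inheritParams lfy_rate
#' @return rate vector (uM/s).
#' @export
ag_rate <- function(state, p, opts = model_options()) {
  gate <- heaviside_gate(state$t, p$gate_time)
  denom <- p$beta2 + p$beta3 * .ap1_input(state, opts)
  if (any(denom <= 0)) stop("nonpositive inhibition denominator")
  prod <- if (opts$denominator_scope == "shared") {
    if (opts$gate_scope == "all_production") {
      gate * (p$k9 * state$wus + p$k10 * state$lfy) / denom
    } else {
      (gate * p$k9 * state$wus + p$k10 * state$lfy) / denom
    }
  } else {
    if (opts$gate_scope == "all_production") {
      gate * (p$k9 * state$wus + p$k10 * state$lfy / denom)
    } else {
      gate * p$k9 * state$wus + p$k10 * state$lfy / denom
    }
  }
  prod - p$k11 * state$tfl1 - p$k12 * state$ag
}

#' Rate of change of TFL1
#'
#' Basal activation (k13) against inactivation by LFY (k14) and AP1 (k15) and
#' first-order decay (k16). LFY and AP1 keep TFL1 low but do not exclude it.
#'
#' @inheritParams lfy_rate
#' @return rate vector (uM/s).
#' @export
tfl1_rate <- function(state, p, opts = model_options()) {
  p$k13 - p$k14 * state$lfy - p$k15 * .ap1_input(state, opts) -
    p$k16 * state$tfl1
}

#' Uniform fixed point of the AG-free subsystem
#'
#' Before the AG gate opens (and with the WUS subsystem silent) the LFY, AP1
#' and TFL1 equations form a linear 3x3 system whose spatially uniform fixed
#' point has a closed form. If the unconstrained solution has a negative
#' component, the system is re-solved with that variable pinned at zero
#' (matching the clipped dynamics).
#'
#' @param p a [kinetic_params()].
#' @return named numeric vector `c(lfy, ap1, tfl1)` (uM).
#' @examples
#' uniform_fixed_point(kinetic_params())
#' @export
uniform_fixed_point <- function(p) {
  ## rows: lfy', ap1', tfl1' = 0; unknowns (lfy, ap1, tfl1)
  A <- rbind(c(-p$k4, p$k2, -p$k3),
             c(p$k6, -p$k8, -p$k7),
             c(-p$k14, -p$k15, -p$k16))
  b <- -c(p$k1, p$k5, p$k13)
  nm <- c("lfy", "ap1", "tfl1")
  solve_clipped <- function(active) {
    x <- setNames(numeric(3), nm)
    if (any(active)) {
      Ai <- A[active, active, drop = FALSE]
      if (abs(det(Ai)) < .Machine$double.eps) stop("singular rate system")
      x[active] <- solve(Ai, b[active])
    }
    x
  }
  active <- rep(TRUE, 3)
  repeat {
    x <- solve_clipped(active)
    neg <- active & (x < 0)
    if (!any(neg)) return(x)
    active[neg] <- FALSE
  }
}

#' Full right-hand side of the coupled model
#'
#' Reference (pure R) evaluation of the time derivatives of all six fields,
#' mirroring the compiled integrator kernel; used for unit testing and for the
#' reference integration engine.
#'
#' @param state a [field_state()].
#' @param p a [kinetic_params()].
#' @param wp a [wus_params()].
#' @param bc a [boundary_config()].
#' @param opts a [model_options()].
#' @return named list of rate vectors (uM/s) for lfy, ap1, ag, tfl1, wus, y.
#' @export
model_rhs <- function(state, p, wp, bc, opts = model_options()) {
  list(lfy = lfy_rate(state, p, opts),
       ap1 = ap1_rate(state, p),
       ag = ag_rate(state, p, opts),
       tfl1 = tfl1_rate(state, p, opts),
       wus = wus_rate(state, wp),
       y = y_rate(state, bc$L, wp))
}
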