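#' Lattice geometry of the L1 transect
#'
#' The meristem is modelled as a line of equally sized L1 cells spanning the
#' diameter of the four whorls. With the defaults (15 cells of 4.4 um) the
#' transect is 66 um across, and the centre of the lattice is cell 8.
#'
#' @param n_cells number of cells (>= 3).
#' @param cell_length cell diameter in micrometres.
#' @return an object of class `grid_spec` with fields `n_cells`, `cell_length`
#'   and the derived `diameter` (um).
#' @examples
#' grid_spec()$diameter  # 66
#' @export
grid_spec <- function(n_cells = 15L, cell_length = 4.4) {
  n_cells <- as.integer(n_cells)
  if (is.na(n_cells) || n_cells < 3L) stop("n_cells must be >= 3")
  if (!is.finite(cell_length) || cell_length <= 0) {
    stop("cell_length must be > 0")
  }
  structure(
    list(n_cells = n_cells, cell_length = cell_length,
         diameter = n_cells * cell_length),
    class = "grid_spec")
}

## default rate constants of the five-gene kinetic model; units: k1, k5, k13
## in uM/s, the remaining k's in 1/s, beta1 and beta2 in uM, beta3 unitless
.default_kinetics <- list(
  k1 = 0.03, k2 = 0.02, k3 = 0.02, k4 = 0.04,
  k5 = 0.09, k6 = 0.05, k7 = 0.02, k8 = 0.05,
  k9 = 0.08, k10 = 0.025, k11 = 0.03, k12 = 0.05,
  k13 = 0.9, k14 = 0.08, k15 = 0.03, k16 = 0.55,
  beta1 = 0.05, beta2 = 1, beta3 = 0.55)

#' Stability intervals of the rate constants
#'
#' Each rate constant of the kinetic model comes with an interval inside which
#' the emergent zone pattern was found to be stable. The published k5 interval
#' (`[0.9, 1.5]`) does not contain the k5 working value (0.09) and destroys the
#' pattern when used literally; by default it is returned decimally rescaled to
#' `[0.09, 0.15]`, consistent with the working value. Set `corrected = FALSE`
#' to obtain the interval exactly as printed.
#'
#' @param corrected replace the inconsistent k5 interval by `[0.09, 0.15]`.
#' @return named list of length-2 numeric vectors (lower, upper), one per
#'   rate constant k1..k16.
#' @export
param_intervals <- function(corrected = TRUE) {
  ints <- list(
    k1 = c(0.03, 0.035), k2 = c(0.02, 0.023), k3 = c(0.015, 0.02),
    k4 = c(0.035, 0.04), k5 = c(0.9, 1.5), k6 = c(0.05, 0.07),
    k7 = c(0.01, 0.02), k8 = c(0.04, 0.05), k9 = c(0.08, 0.5),
    k10 = c(0.025, 0.05), k11 = c(0.01, 0.03), k12 = c(0.01, 0.05),
    k13 = c(0.7, 0.9), k14 = c(0.07, 0.08), k15 = c(0.03, 0.08),
    k16 = c(0.55, 0.75))
  if (corrected) ints$k5 <- c(0.09, 0.15)
  ints
}

#' Kinetic parameters of the five-gene patterning model
#'
#' Rate constants for the LFY / AP1 / AG / TFL1 equations, the AG-exclusion
#' saturation constant `beta1`, the noncompetitive-inhibition constants
#' `beta2`/`beta3`, the opening time of the AG gate, and the LFY coupling
#' coefficient `epsilon` (the discretised diffusion rate between neighbouring
#' cells).
#'
#' @param ... named overrides of the default rate constants (k1..k16, beta1,
#'   beta2, beta3).
#' @param gate_time time (s) at which the AG gate opens; default 5 h.
#' @param epsilon LFY coupling coefficient (1/s) between adjacent cells.
#' @param check_intervals if `TRUE`, warn for any rate constant lying outside
#'   its stability interval (k5 is exempt: its published interval is
#'   inconsistent with its working value, see [param_intervals()]).
#' @return object of class `kinetic_params`.
#' @examples
#' p <- kinetic_params(k9 = 0.5)
#' p$k9
#' @export
kinetic_params <- function(..., gate_time = 18000, epsilon = 5,
                           check_intervals = FALSE) {
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(.default_kinetics))
    if (length(bad) || is.null(names(over)) || any(names(over) == "")) {
      stop("unknown kinetic parameter(s): ",
           paste(if (length(bad)) bad else "<unnamed>", collapse = ", "))
    }
  }
  p <- modifyList(.default_kinetics, over)
  vals <- unlist(p)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("all rate constants must be finite and >= 0; offending: ",
         paste(names(vals)[!is.finite(vals) | vals < 0], collapse = ", "))
  }
  if (p$beta1 <= 0 || p$beta2 <= 0) stop("beta1 and beta2 must be > 0")
  if (!is.finite(gate_time) || gate_time < 0) stop("gate_time must be >= 0")
  if (!is.finite(epsilon) || epsilon < 0) stop("epsilon must be >= 0")
  p$gate_time <- gate_time
  p$epsilon <- epsilon
  if (check_intervals) {
    ints <- param_intervals()
    for (nm in setdiff(names(ints), "k5")) {
      v <- p[[nm]]
      if (v < ints[[nm]][1] || v > ints[[nm]][2]) {
        warning(sprintf("%s = %g lies outside its stability interval [%g, %g]",
                        nm, v, ints[[nm]][1], ints[[nm]][2]))
      }
    }
  }
  structure(p, class = "kinetic_params")
}

#' Parameters of the WUS repressor subsystem
#'
#' The WUS pre-pattern is generated by an adapted repressor model: a boundary
#' signal L induces a diffusible repressor y whose level sets the input
#' `u = h_w + T_wy * y` of a saturating activation function `g(u)`; WUS is
#' produced at `k17 * g(u)` and degraded at `d_w * wus`. These rates are per
#' `time_scale` seconds (default: per hour), reflecting the slower timescale of
#' the repressor subsystem relative to the per-second kinetic model.
#'
#' `sigmoid_variant` selects the activation nonlinearity: `"mjolsness"`
#' (default) is the classic saturating sigmoid `g(u) = (1 + u/sqrt(1+u^2))/2`
#' of the source repressor model; `"literal_ratio"` (`(1+u)/(1+u^2)`) and
#' `"literal_sum"` (`1 + u/(1+u^2)`) are alternative readings of the printed
#' bracket, retained for fidelity experiments -- neither produces a usable
#' on/off contrast with the default `h_w`/`T_wy`.
#'
#' Under `amplitude_mode = "normalized"` (default) the production constant is
#' set to `d_w` so the derepressed steady WUS level is `g_max`, of order 1 and
#' commensurate with the unit initial WUS level; `"literal"` uses `k17` as
#' given (steady level `k17/d_w * g`, about 0.03 uM).
#'
#' @param k17 WUS production rate (uM per time unit).
#' @param d_w WUS decay rate (per time unit).
#' @param h_w activation-input offset (dimensionless).
#' @param T_wy repressor weight on the activation input (dimensionless,
#'   negative for repression).
#' @param k_y y production rate per unit boundary signal (per time unit).
#' @param d_y y decay rate (per time unit).
#' @param D_y y lattice coupling coefficient (per time unit).
#' @param time_scale seconds per repressor-subsystem time unit.
#' @param sigmoid_variant activation nonlinearity, see Details.
#' @param amplitude_mode `"normalized"` or `"literal"`, see Details.
#' @return object of class `wus_params`.
#' @export
wus_params <- function(k17 = 0.05, d_w = 1.75, h_w = 2, T_wy = -30,
                       k_y = 0.2, d_y = 2, D_y = 0.1, time_scale = 3600,
                       sigmoid_variant = c("mjolsness", "literal_ratio",
                                           "literal_sum"),
                       amplitude_mode = c("normalized", "literal")) {
  sigmoid_variant <- match.arg(sigmoid_variant)
  amplitude_mode <- match.arg(amplitude_mode)
  for (nm in c("k17", "d_w", "k_y", "d_y", "D_y")) {
    v <- get(nm)
    if (!is.finite(v) || v < 0) stop(nm, " must be finite and >= 0")
  }
  if (!is.finite(time_scale) || time_scale <= 0) {
    stop("time_scale must be > 0")
  }
  structure(
    list(k17 = k17, d_w = d_w, h_w = h_w, T_wy = T_wy, k_y = k_y, d_y = d_y,
         D_y = D_y, time_scale = time_scale, sigmoid_variant = sigmoid_variant,
         amplitude_mode = amplitude_mode),
    class = "wus_params")
}

## effective WUS production constant under the chosen amplitude convention
k17_effective <- function(wp) {
  if (wp$amplitude_mode == "normalized") wp$d_w else wp$k17
}

#' Structural options of the kinetic model
#'
#' The AG equation admits several readings; these flags make each explicit.
#' `gate_scope` decides whether the AG time gate multiplies all AG production
#' (`"all_production"`, default -- without it the AG pattern would emerge
#' within a few integration steps) or only the WUS term. `denominator_scope`
#' decides whether the noncompetitive AP1 inhibition `(beta2 + beta3 * ap1)`
#' divides the combined activation (`"shared"`, default) or only the LFY term.
#' `ap1_feedback` decides whether "AP1" in the LFY, AG and TFL1 equations means
#' the raw AP1 state variable (`"raw"`, default -- this makes the coupling
#' invariance of the pattern exact) or the AG-excluded effective level
#' `ap1_T`. `exclusion_driver` selects which field drives the AP1 exclusion
#' transform (AG by default; WUS is the variant explored in the discussion of
#' the model). `clip_negative` clips every field at zero after each corrector
#' step, keeping concentrations physical.
#'
#' @param gate_scope `"all_production"` or `"wus_term_only"`.
#' @param denominator_scope `"shared"` or `"lfy_term_only"`.
#' @param ap1_feedback `"raw"` or `"effective"`.
#' @param exclusion_driver `"AG"` or `"WUS"`.
#' @param clip_negative logical.
#' @return object of class `model_options`.
#' @export
model_options <- function(gate_scope = c("all_production", "wus_term_only"),
                          denominator_scope = c("shared", "lfy_term_only"),
                          ap1_feedback = c("raw", "effective"),
                          exclusion_driver = c("AG", "WUS"),
                          clip_negative = TRUE) {
  structure(
    list(gate_scope = match.arg(gate_scope),
         denominator_scope = match.arg(denominator_scope),
         ap1_feedback = match.arg(ap1_feedback),
         exclusion_driver = match.arg(exclusion_driver),
         clip_negative = isTRUE(clip_negative)),
    class = "model_options")
}

#' Boundary signal configuration
#'
#' The repressor subsystem is driven by a binary boundary signal L fixed in
#' time, and the repressor y starts from a matching initial profile. The
#' `"wide"` configuration applies the signal to the three outermost cells of
#' each end (cells 1-3 and 13-15 of 15); `"narrow"` confines it to the two
#' extreme cells (1 and 15). `"custom"` takes `L` and `y0` verbatim.
#'
#' @param name `"wide"`, `"narrow"` or `"custom"`.
#' @param grid a [grid_spec()].
#' @param L binary vector of length `n_cells` (custom only).
#' @param y0 initial y profile (defaults to `L`).
#' @return object of class `boundary_config` with fields `name`, `L`, `y0`.
#' @export
boundary_config <- function(name = c("wide", "narrow", "custom"),
                            grid = grid_spec(), L = NULL, y0 = NULL) {
  name <- match.arg(name)
  n <- grid$n_cells
  if (name == "wide") {
    edge <- min(3L, n %/% 2L)
    L <- as.numeric(seq_len(n) %in% c(seq_len(edge), n - edge + seq_len(edge)))
  } else if (name == "narrow") {
    L <- as.numeric(seq_len(n) %in% c(1L, n))
  } else if (is.null(L)) {
    stop("custom boundary_config requires L")
  }
  L <- as.numeric(L)
  if (length(L) != n) stop("L must have length n_cells")
  if (any(!L %in% c(0, 1))) stop("L must be binary")
  if (is.null(y0)) y0 <- L
  y0 <- as.numeric(y0)
  if (length(y0) != n) stop("y0 must have length n_cells")
  if (any(!is.finite(y0)) || any(y0 < 0)) stop("y0 must be finite and >= 0")
  structure(list(name = name, L = L, y0 = y0), class = "boundary_config")
}

#' Per-cell concentration state at one time point
#'
#' Bundles the six concentration fields at a time `t` together with the derived
#' AG-excluded AP1 profile `ap1_T = ap1 * (1 - x/(x + beta1))`, where `x` is
#' the driving field (AG by default).
#'
#' @param t time (s).
#' @param lfy,ap1,ag,tfl1,wus,y concentration vectors (uM), equal length.
#' @param beta1 exclusion saturation constant (uM).
#' @param exclusion_driver `"AG"` or `"WUS"`.
#' @return object of class `field_state`; element `ap1_T` holds the derived
#'   profile.
#' @export
field_state <- function(t, lfy, ap1, ag, tfl1, wus, y, beta1 = 0.05,
                        exclusion_driver = c("AG", "WUS")) {
  exclusion_driver <- match.arg(exclusion_driver)
  n <- length(lfy)
  fields <- list(lfy = lfy, ap1 = ap1, ag = ag, tfl1 = tfl1, wus = wus, y = y)
  for (nm in names(fields)) {
    v <- fields[[nm]]
    if (!is.numeric(v) || length(v) != n) {
      stop("field ", nm, " must be numeric of length ", n)
    }
    if (any(!is.finite(v))) stop("field ", nm, " contains non-finite values")
  }
  driver <- if (exclusion_driver == "AG") ag else wus
  st <- c(list(t = t), fields,
          list(ap1_T = effective_ap1(ap1, driver, beta1),
               exclusion_driver = exclusion_driver, beta1 = beta1))
  structure(st, class = "field_state")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("L1 transect: %d cells x %.2f um = %.1f um\n",
              x$n_cells, x$cell_length, x$diameter))
  invisible(x)
}

#' @export
print.field_state <- function(x, ...) {
  cat(sprintf("field_state at t = %.1f s (%.3f h), %d cells\n",
              x$t, x$t / 3600, length(x$lfy)))
  m <- rbind(lfy = x$lfy, ap1 = x$ap1, ap1_T = x$ap1_T, ag = x$ag,
             tfl1 = x$tfl1, wus = x$wus, y = x$y)
  colnames(m) <- paste0("c", seq_len(ncol(m)))
  print(signif(m, 4))
  invisible(x)
}
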