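#' Assemble a complete run configuration
#'
#' Bundles lattice, kinetic parameters, repressor-subsystem parameters,
#' boundary configuration, structural options and integrator settings. The
#' defaults are the reference study conditions: 15 cells, coupling
#' `epsilon = 5`, wide boundary signal, 1,200,000 Heun steps of 0.05 s
#' (16.6 simulated hours), sampling every 2,000 steps (100 s), and the
#' homogeneous initial state `lfy = 1`, `ap1 = 0`, `ag = 0`, `tfl1 = 0.1`,
#' `wus = 1` with y set from the boundary configuration.
#'
#' `epsilon_schedule` optionally replaces the constant coupling of
#' `kinetics$epsilon`: a list with `values` (a numeric vector of one epoch per
#' element, or a matrix with one column per cell) and `every_s` (epoch length
#' in seconds; the last epoch persists). Used by the random-coupling
#' experiments.
#'
#' @param grid a [grid_spec()].
#' @param kinetics a [kinetic_params()].
#' @param wus a [wus_params()].
#' @param boundary a [boundary_config()] (built on `grid` by default).
#' @param options a [model_options()].
#' @param dt integrator step (s).
#' @param n_steps number of steps (>= 1).
#' @param sample_every sampling stride in steps.
#' @param seed integer seed recorded for stochastic experiment wrappers.
#' @param initial_state a [field_state()] at t = 0, or NULL for the default.
#' @param epsilon_schedule optional time/space-varying coupling, see Details.
#' @return object of class `run_config`.
#' @export
run_config <- function(grid = grid_spec(), kinetics = kinetic_params(),
                       wus = wus_params(),
                       boundary = boundary_config("wide", grid),
                       options = model_options(), dt = 0.05,
                       n_steps = 1200000L, sample_every = 2000L,
                       seed = NULL, initial_state = NULL,
                       epsilon_schedule = NULL) {
  stopifnot(inherits(grid, "grid_spec"), inherits(kinetics, "kinetic_params"),
            inherits(wus, "wus_params"),
            inherits(boundary, "boundary_config"),
            inherits(options, "model_options"))
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0")
  n_steps <- as.integer(n_steps)
  if (is.na(n_steps) || n_steps < 1L) stop("n_steps must be >= 1")
  sample_every <- as.integer(sample_every)
  if (is.na(sample_every) || sample_every < 1L) {
    stop("sample_every must be >= 1")
  }
  n <- grid$n_cells
  if (length(boundary$L) != n) stop("boundary does not match the grid")
  if (is.null(initial_state)) {
    initial_state <- field_state(
      t = 0, lfy = rep(1, n), ap1 = rep(0, n), ag = rep(0, n),
      tfl1 = rep(0.1, n), wus = rep(1, n), y = boundary$y0,
      beta1 = kinetics$beta1, exclusion_driver = options$exclusion_driver)
  }
  stopifnot(inherits(initial_state, "field_state"))
  if (length(initial_state$lfy) != n) {
    stop("initial_state does not match the grid")
  }
  if (!is.null(epsilon_schedule)) {
    v <- epsilon_schedule$values
    if (is.null(dim(v))) v <- matrix(v, ncol = 1L)
    if (!ncol(v) %in% c(1L, n)) {
      stop("epsilon_schedule$values must have 1 or n_cells columns")
    }
    if (any(!is.finite(v)) || any(v < 0)) {
      stop("epsilon values must be finite and >= 0")
    }
    ev <- epsilon_schedule$every_s
    if (nrow(v) > 1L && (!is.finite(ev) || ev <= 0)) {
      stop("epsilon_schedule$every_s must be > 0 for multi-epoch schedules")
    }
    epsilon_schedule <- list(values = v,
                             every_s = if (nrow(v) > 1L) ev else 0)
  }
  structure(
    list(grid = grid, kinetics = kinetics, wus = wus, boundary = boundary,
         options = options, dt = dt, n_steps = n_steps,
         sample_every = sample_every, seed = seed,
         initial_state = initial_state,
         epsilon_schedule = epsilon_schedule),
    class = "run_config")
}

## epoch matrix + stride handed to the compiled kernel
.epsilon_args <- function(config) {
  if (is.null(config$epsilon_schedule)) {
    list(eps = matrix(config$kinetics$epsilon, 1L, 1L), every_steps = 0L)
  } else {
    sch <- config$epsilon_schedule
    list(eps = sch$values,
         every_steps = if (sch$every_s > 0) {
           max(1L, as.integer(round(sch$every_s / config$dt)))
         } else 0L)
  }
}

#' One Heun (Euler predictor-corrector) step
#'
#' Forward-Euler predictor followed by a trapezoidal corrector:
#' `x' = x + dt/2 * (f(t, x) + f(t + dt, x + dt f(t, x)))`, optionally clipped
#' at zero afterwards. Operates on any numeric state vector and rate function;
#' the integration engines apply the same update to the stacked fields.
#'
#' @param x numeric state vector.
#' @param t current time.
#' @param dt step size, > 0.
#' @param rhs function of `(t, x)` returning dx/dt.
#' @param clip_negative clip the corrected state at 0.
#' @return updated state vector.
#' @examples
#' heun_step(1, 0, 0.1, function(t, x) -x)  # 0.905
#' @export
heun_step <- function(x, t, dt, rhs, clip_negative = FALSE) {
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0")
  f1 <- rhs(t, x)
  pred <- x + dt * f1
  out <- x + dt / 2 * (f1 + rhs(t + dt, pred))
  if (any(!is.finite(out))) {
    stop("non-finite state after Heun step: integration unstable")
  }
  if (clip_negative) out <- pmax(out, 0)
  out
}

#' Integrate the full coupled system
#'
#' Runs the fixed-step Heun scheme on all six fields jointly and records the
#' state every `sample_every` steps (plus the final state). The default engine
#' is the compiled kernel; `engine = "reference"` runs the same scheme in pure
#' R on top of [model_rhs()] and is used to validate the kernel on short runs.
#' Deterministic given the configuration: no randomness enters the default
#' run.
#'
#' @param config a [run_config()].
#' @param engine `"compiled"` or `"reference"`.
#' @param method `"heun"` (default) or `"euler"` (plain forward Euler, kept
#'   for fidelity comparisons).
#' @return object of class `abc_trajectory`: sampled `times` (s), one
#'   samples-by-cells matrix per field (`lfy`, `ap1`, `ap1_T`, `ag`, `tfl1`,
#'   `wus`, `y`), per-field clip counts, and the configuration.
#' @export
simulate_abc <- function(config = run_config(),
                         engine = c("compiled", "reference"),
                         method = c("heun", "euler")) {
  stopifnot(inherits(config, "run_config"))
  engine <- match.arg(engine)
  method <- match.arg(method)
  p <- config$kinetics
  wp <- config$wus
  opts <- config$options
  st0 <- config$initial_state
  eps <- .epsilon_args(config)
  gate_step <- as.integer(round(p$gate_time / config$dt))

  if (engine == "compiled") {
    kin <- c(p$k1, p$k2, p$k3, p$k4, p$k5, p$k6, p$k7, p$k8, p$k9, p$k10,
             p$k11, p$k12, p$k13, p$k14, p$k15, p$k16,
             p$beta1, p$beta2, p$beta3)
    wpv <- c(k17_effective(wp), wp$d_w, wp$h_w, wp$T_wy, wp$k_y, wp$d_y,
             wp$D_y, 1 / wp$time_scale)
    res <- .sim_core(
      st0$lfy, st0$ap1, st0$ag, st0$tfl1, st0$wus, st0$y,
      config$boundary$L, kin, eps$eps, eps$every_steps, wpv,
      match(wp$sigmoid_variant,
            c("mjolsness", "literal_ratio", "literal_sum")) - 1L,
      gate_step,
      match(opts$gate_scope, c("all_production", "wus_term_only")) - 1L,
      match(opts$denominator_scope, c("shared", "lfy_term_only")) - 1L,
      match(opts$ap1_feedback, c("raw", "effective")) - 1L,
      match(opts$exclusion_driver, c("AG", "WUS")) - 1L,
      opts$clip_negative, method == "euler",
      config$dt, config$n_steps, config$sample_every)
    fields <- res[c("lfy", "ap1", "ag", "tfl1", "wus", "y")]
    times <- res$times
    clips <- setNames(res$clip_counts,
                      c("lfy", "ap1", "ag", "tfl1", "wus", "y"))
  } else {
    out <- .simulate_reference(config, method, eps, gate_step)
    fields <- out$fields
    times <- out$times
    clips <- out$clips
  }
  n <- config$grid$n_cells
  for (nm in names(fields)) {
    dimnames(fields[[nm]]) <- list(NULL, paste0("c", seq_len(n)))
  }
  driver <- if (opts$exclusion_driver == "AG") fields$ag else fields$wus
  fields$ap1_T <- fields$ap1 * (1 - driver / (driver + p$beta1))
  structure(
    list(times = times, hours = times / 3600,
         fields = fields[c("lfy", "ap1", "ap1_T", "ag", "tfl1", "wus", "y")],
         clip_counts = clips, config = config, engine = engine,
         method = method),
    class = "abc_trajectory")
}

## pure-R engine: same scheme on the stacked state vector
.simulate_reference <- function(config, method, eps, gate_step) {
  n <- config$grid$n_cells
  p <- config$kinetics
  wp <- config$wus
  bc <- config$boundary
  opts <- config$options
  dt <- config$dt
  nm <- c("lfy", "ap1", "ag", "tfl1", "wus", "y")
  st <- lapply(config$initial_state[nm], as.numeric)
  every_steps <- eps$every_steps
  eps_m <- eps$eps
  n_epochs <- nrow(eps_m)

  rhs_at <- function(step, s) {
    epoch <- if (every_steps > 0) min(step %/% every_steps, n_epochs - 1L)
             else 0L
    erow <- eps_m[epoch + 1L, ]
    ## state time drives the gate; products of step * dt agree with the
    ## step-indexed gate of the compiled kernel (dt rounds upward)
    fs <- field_state(step * dt, s$lfy, s$ap1, s$ag, s$tfl1, s$wus, s$y,
                      beta1 = p$beta1,
                      exclusion_driver = opts$exclusion_driver)
    p_loc <- p
    p_loc$epsilon <- 0 # coupling re-applied below to honour per-cell values
    d <- model_rhs(fs, p_loc, wp, bc, opts)
    d$lfy <- d$lfy + erow * noflux_laplacian(s$lfy)
    d
  }

  n_samples <- config$n_steps %/% config$sample_every +
    (if (config$n_steps %% config$sample_every) 2L else 1L)
  times <- numeric(n_samples)
  fields <- setNames(
    lapply(nm, function(x) matrix(NA_real_, n_samples, n)), nm)
  clips <- setNames(integer(6), nm)
  row <- 1L
  for (f in nm) fields[[f]][row, ] <- st[[f]]
  times[row] <- 0
  for (s in seq_len(config$n_steps) - 1L) {
    f1 <- rhs_at(s, st)
    if (method == "euler") {
      new <- Map(function(x, d) x + dt * d, st, f1)
    } else {
      pred <- Map(function(x, d) x + dt * d, st, f1)
      f2 <- rhs_at(s + 1L, pred)
      new <- Map(function(x, d1, d2) x + dt / 2 * (d1 + d2), st, f1, f2)
    }
    if (opts$clip_negative) {
      for (f in nm) {
        neg <- new[[f]] < 0
        clips[[f]] <- clips[[f]] + sum(neg)
        new[[f]][neg] <- 0
      }
    }
    st <- new
    if ((s + 1L) %% config$sample_every == 0L || s + 1L == config$n_steps) {
      if (any(!vapply(st, function(v) all(is.finite(v)), logical(1)))) {
        stop("integration unstable: non-finite state at step ", s + 1L)
      }
      row <- row + 1L
      for (f in nm) fields[[f]][row, ] <- st[[f]]
      times[row] <- (s + 1L) * dt
    }
  }
  list(times = times[seq_len(row)],
       fields = lapply(fields, function(m) m[seq_len(row), , drop = FALSE]),
       clips = clips)
}

#' Time at which a trajectory settles
#'
#' Scans consecutive samples and reports the first sample time after which
#' every field's maximum relative change per simulated hour stays below `tol`
#' through the end of the run. Relative change between samples is the maximum
#' absolute per-cell change divided by the field's amplitude (its maximum
#' absolute level over the whole trajectory, floored at 1e-8 uM to guard
#' all-zero fields), so for a decaying transient of amplitude A and time
#' constant tau the settling time is close to `tau * log(A / (tol * tau * A))`
#' = `tau * log(1 / (tol * tau))` with tau in hours.
#'
#' @param traj an [simulate_abc()] trajectory with at least 2 samples.
#' @param tol relative rate threshold per hour.
#' @return list with `time` (s), `hours`, and logical `reached` (`FALSE` if
#'   the criterion still fails at the final sample, in which case `time` is
#'   the end time).
#' @export
steady_state_time <- function(traj, tol = 1e-3) {
  stopifnot(inherits(traj, "abc_trajectory"))
  m <- length(traj$times)
  if (m < 2L) stop("need at least 2 samples")
  nm <- c("lfy", "ap1", "ag", "tfl1", "wus", "y")
  dt_h <- diff(traj$times) / 3600
  worst <- rep(0, m - 1L)
  for (f in nm) {
    x <- traj$fields[[f]]
    dx <- abs(x[-1L, , drop = FALSE] - x[-m, , drop = FALSE])
    scale <- max(abs(x), 1e-8)
    worst <- pmax(worst, apply(dx, 1L, max) / scale / dt_h)
  }
  bad <- which(worst >= tol)
  if (length(bad) == 0L) {
    list(time = traj$times[1L], hours = traj$times[1L] / 3600, reached = TRUE)
  } else if (max(bad) == m - 1L) {
    list(time = traj$times[m], hours = traj$times[m] / 3600, reached = FALSE)
  } else {
    t0 <- traj$times[max(bad) + 1L]
    list(time = t0, hours = t0 / 3600, reached = TRUE)
  }
}

#' Extract one sampled state from a trajectory
#'
#' @param traj an `abc_trajectory`.
#' @param sample sample index (default: last).
#' @return a [field_state()].
#' @export
get_state <- function(traj, sample = length(traj$times)) {
  stopifnot(inherits(traj, "abc_trajectory"))
  i <- as.integer(sample)
  if (is.na(i) || i < 1L || i > length(traj$times)) stop("bad sample index")
  f <- traj$fields
  field_state(traj$times[i], f$lfy[i, ], f$ap1[i, ], f$ag[i, ], f$tfl1[i, ],
              f$wus[i, ], f$y[i, ], beta1 = traj$config$kinetics$beta1,
              exclusion_driver = traj$config$options$exclusion_driver)
}

#' @rdname get_state
#' @export
final_state <- function(traj) get_state(traj)

#' @export
print.abc_trajectory <- function(x, ...) {
  cat(sprintf(
    "abc_trajectory: %d cells, %d samples over %.2f h (dt = %g s, %s/%s)\n",
    x$config$grid$n_cells, length(x$times), max(x$hours), x$config$dt,
    x$engine, x$method))
  fin <- final_state(x)
  cat(sprintf("final AG peak at cell %d; clip events: %s\n",
              peak_cell(fin$ag),
              paste(names(x$clip_counts), x$clip_counts, sep = "=",
                    collapse = " ")))
  invisible(x)
}

#' @export
summary.abc_trajectory <- function(object, ...) {
  s <- pattern_summary(object)
  print(s)
  invisible(s)
}

#' Plot sampled profiles or time courses
#'
#' `what = "profiles"` draws the spatial profiles of the fields at one sampled
#' time (default: final); `what = "timecourse"` draws each field at one cell
#' against time.
#'
#' @param x an `abc_trajectory`.
#' @param what `"profiles"` or `"timecourse"`.
#' @param sample sample index for profiles (default: last).
#' @param cell cell index for time courses (default: centre cell).
#' @param fields which fields to draw.
#' @param ... passed to [graphics::matplot()].
#' @return invisibly, the matrix plotted.
#' @export
plot.abc_trajectory <- function(x, what = c("profiles", "timecourse"),
                                sample = length(x$times),
                                cell = (x$config$grid$n_cells + 1L) %/% 2L,
                                fields = c("lfy", "ap1_T", "ag", "tfl1",
                                           "wus"),
                                ...) {
  what <- match.arg(what)
  fields <- match.arg(fields, names(x$fields), several.ok = TRUE)
  cols <- hcl.colors(length(fields), "Dark 3")
  if (what == "profiles") {
    m <- vapply(fields, function(f) x$fields[[f]][sample, ],
                numeric(x$config$grid$n_cells))
    matplot(seq_len(nrow(m)), m, type = "b", pch = 16, lty = 1, col = cols,
            xlab = "cell", ylab = "concentration (uM)",
            main = sprintf("t = %.2f h", x$hours[sample]), ...)
  } else {
    m <- vapply(fields, function(f) x$fields[[f]][, cell],
                numeric(length(x$times)))
    matplot(x$hours, m, type = "l", lty = 1, col = cols,
            xlab = "time (h)", ylab = "concentration (uM)",
            main = sprintf("cell %d", cell), ...)
  }
  legend("topright", legend = fields, col = cols, lty = 1, bty = "n")
  invisible(m)
}
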