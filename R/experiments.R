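## Scripted reproductions of the in-silico experiments: each returns an
## `abc_experiment` whose verdicts are all traceable to named metrics in
## `comparisons` or rows of `tables`.

.experiment_report <- function(name, configs, summaries, comparisons,
                               verdicts, tables = NULL) {
  structure(list(name = name, configs = configs, summaries = summaries,
                 comparisons = comparisons, verdicts = verdicts,
                 tables = tables),
            class = "abc_experiment")
}

## centre cell of an odd lattice
.centre_cell <- function(config) (config$grid$n_cells + 1L) %/% 2L

## labels must read periphery-A, centre-C, with any B cells between the two;
## the B zone is residual and may be empty
.zone_ordering_ok <- function(labels, centre) {
  if (anyNA(labels)) return(FALSE)
  runs <- rle(labels)$values
  ok <- identical(runs, c("A", "C", "A")) ||
    identical(runs, c("A", "B", "C", "B", "A"))
  ok && labels[centre] == "C"
}

#' Wild-type patterning run
#'
#' Full default run (wide boundary signal, constant coupling): reports the
#' zone labels, the AG peak cell, the duration of the pre-gate AG silence and
#' the settling time, with verdicts for central AG, pre-gate silence and the
#' periphery-A / centre-C zone layout.
#'
#' @param config base [run_config()]; the defaults are the reference study
#'   conditions.
#' @param half_fraction zone threshold, see [zone_classify()].
#' @return an `abc_experiment`.
#' @export
run_wildtype <- function(config = run_config(), half_fraction = 0.5) {
  traj <- simulate_abc(config)
  s <- pattern_summary(traj, half_fraction)
  centre <- .centre_cell(config)
  gate <- config$kinetics$gate_time
  ag_zero <- apply(traj$fields$ag, 1L, function(v) all(v == 0))
  pre <- traj$times < gate
  silence_end <- if (any(!ag_zero)) traj$times[which(!ag_zero)[1L]] else
    max(traj$times)
  comparisons <- c(
    ag_peak_cell = s$ag_peak_cell,
    ag_silence_end_h = silence_end / 3600,
    max_pre_gate_ag = max(traj$fields$ag[pre, ]),
    final_center_ag = unname(final_state(traj)$ag[centre]),
    steady_time_h = s$steady_time / 3600,
    zones_stable_from_h = s$classification_stable_from / 3600)
  verdicts <- c(
    ag_peak_at_centre = s$ag_peak_cell == centre,
    ag_silent_before_gate = all(traj$fields$ag[pre, ] == 0),
    ag_positive_after_gate = all(!ag_zero[traj$times >= gate + 100]),
    zones_well_ordered = .zone_ordering_ok(as.character(s$zone_labels),
                                           centre))
  .experiment_report("wildtype", list(wildtype = config), list(wildtype = s),
                     comparisons, verdicts)
}

#' Narrow-boundary run
#'
#' Confines the boundary signal (and initial repressor) to the two extreme
#' cells and compares the AG domain to the wild-type run: the domain broadens
#' while the qualitative layout is conserved. The profile stays mirror
#' symmetric: symmetric equations with symmetric initial conditions cannot
#' break symmetry, so any reported asymmetry of this configuration is flagged
#' rather than reproduced.
#'
#' @inheritParams run_wildtype
#' @return an `abc_experiment`.
#' @export
run_narrow_boundary <- function(config = run_config(),
                                half_fraction = 0.5) {
  narrow_bc <- boundary_config("narrow", config$grid)
  narrow_cfg <- run_config(
    grid = config$grid, kinetics = config$kinetics, wus = config$wus,
    boundary = narrow_bc, options = config$options, dt = config$dt,
    n_steps = config$n_steps, sample_every = config$sample_every,
    seed = config$seed)
  wide <- simulate_abc(config)
  narrow <- simulate_abc(narrow_cfg)
  s_w <- pattern_summary(wide, half_fraction)
  s_n <- pattern_summary(narrow, half_fraction)
  centre <- .centre_cell(config)
  comparisons <- c(
    ag_width_wide = s_w$ag_halfmax_width,
    ag_width_narrow = s_n$ag_halfmax_width,
    symmetry_error_narrow = s_n$symmetry_error,
    ag_peak_cell_narrow = s_n$ag_peak_cell)
  verdicts <- c(
    broader_than_wide = s_n$ag_halfmax_width > s_w$ag_halfmax_width,
    qualitative_form_conserved =
      .zone_ordering_ok(as.character(s_n$zone_labels), centre) &&
      s_n$ag_peak_cell == centre,
    mirror_symmetric = s_n$symmetry_error < 1e-10)
  .experiment_report("narrow_boundary",
                     list(wide = config, narrow = narrow_cfg),
                     list(wide = s_w, narrow = s_n), comparisons, verdicts)
}

#' Coupling-coefficient experiments
#'
#' Three modes probing the role of LFY movement between cells: a sweep over
#' fixed coupling values, a run in which the coupling is redrawn uniformly
#' from `[0, 10]` every 50 s of simulated time, and a run with an independent
#' random coupling per cell (constant in time). Each final state is compared
#' to the reference run (constant `epsilon = 5`) by [profile_distance()];
#' under the default options the invariance is exact, so the distances are
#' required to vanish to within 1e-10.
#'
#' @param values coupling values for the sweep mode.
#' @param random_mode also run the two randomised variants.
#' @param seed integer seed for the random draws.
#' @inheritParams run_wildtype
#' @return an `abc_experiment`; `tables$distances` lists one row per variant.
#' @export
run_epsilon_experiments <- function(values = c(0, 5, 10), random_mode = TRUE,
                                    seed = 1L, config = run_config()) {
  if (any(values < 0)) stop("epsilon values must be >= 0")
  with_eps <- function(e = NULL, schedule = NULL) {
    kin <- config$kinetics
    if (!is.null(e)) kin$epsilon <- e
    run_config(grid = config$grid, kinetics = kin, wus = config$wus,
               boundary = config$boundary, options = config$options,
               dt = config$dt, n_steps = config$n_steps,
               sample_every = config$sample_every, seed = seed,
               epsilon_schedule = schedule)
  }
  ref_cfg <- with_eps(5)
  ref <- final_state(simulate_abc(ref_cfg))
  configs <- list(reference = ref_cfg)
  dist <- c()
  for (e in values) {
    cfg <- with_eps(e)
    configs[[paste0("eps_", e)]] <- cfg
    dist[paste0("eps_", e)] <- profile_distance(
      final_state(simulate_abc(cfg)), ref)
  }
  if (random_mode) {
    set.seed(seed)
    total_s <- config$n_steps * config$dt
    n_epochs <- max(1L, ceiling(total_s / 50))
    cfg_t <- with_eps(schedule = list(values = runif(n_epochs, 0, 10),
                                      every_s = 50))
    cfg_c <- with_eps(schedule = list(
      values = matrix(runif(config$grid$n_cells, 0, 10), nrow = 1L),
      every_s = 0))
    configs$random_time <- cfg_t
    configs$random_per_cell <- cfg_c
    dist["random_time"] <- profile_distance(final_state(simulate_abc(cfg_t)),
                                            ref)
    dist["random_per_cell"] <- profile_distance(
      final_state(simulate_abc(cfg_c)), ref)
  }
  verdicts <- setNames(dist < 1e-10, paste0(names(dist), "_invariant"))
  .experiment_report(
    "epsilon", configs, list(reference = pattern_summary(simulate_abc(ref_cfg))),
    c(max_distance = max(dist), dist), verdicts,
    tables = list(distances = data.frame(variant = names(dist),
                                         distance = unname(dist))))
}

#' TFL1 knockout
#'
#' Sets the intrinsic TFL1 activation rate to zero and starts TFL1 at zero,
#' then compares the final pattern to wild type: without the TFL1 brake AG
#' accumulates in excess at the centre and the effective AP1 at the extreme
#' cells collapses. Also checks that wild-type TFL1 is kept low but never
#' excluded (all final values positive).
#'
#' @inheritParams run_wildtype
#' @return an `abc_experiment`.
#' @export
run_tfl1_knockout <- function(config = run_config()) {
  n <- config$grid$n_cells
  kin <- config$kinetics
  kin$k13 <- 0
  ko_init <- field_state(
    t = 0, lfy = rep(1, n), ap1 = rep(0, n), ag = rep(0, n),
    tfl1 = rep(0, n), wus = rep(1, n), y = config$boundary$y0,
    beta1 = kin$beta1, exclusion_driver = config$options$exclusion_driver)
  ko_cfg <- run_config(grid = config$grid, kinetics = kin, wus = config$wus,
                       boundary = config$boundary, options = config$options,
                       dt = config$dt, n_steps = config$n_steps,
                       sample_every = config$sample_every,
                       initial_state = ko_init)
  wt <- final_state(simulate_abc(config))
  ko <- final_state(simulate_abc(ko_cfg))
  centre <- .centre_cell(config)
  edges <- c(1L, n)
  comparisons <- c(
    wt_center_ag = unname(wt$ag[centre]),
    ko_center_ag = unname(ko$ag[centre]),
    wt_edge_ap1T = min(wt$ap1_T[edges]), ko_edge_ap1T = min(ko$ap1_T[edges]),
    wt_min_tfl1 = min(wt$tfl1))
  verdicts <- c(
    excess_center_ag = unname(ko$ag[centre] > wt$ag[centre]),
    low_edge_ap1T = max(ko$ap1_T[edges]) < min(wt$ap1_T[edges]),
    wt_tfl1_positive = all(wt$tfl1 > 0))
  .experiment_report("tfl1_knockout", list(wildtype = config, knockout = ko_cfg),
                     list(knockout = NULL), comparisons, verdicts)
}

#' WUS-driven exclusion variant
#'
#' Recomputes the AP1 exclusion transform against WUS instead of AG and
#' compares the zone layout to wild type: the qualitative pattern (peripheral
#' A, central C containing the centre cell, B between where present) and the
#' central minimum of effective AP1 are preserved, showing the patterning does
#' not depend on which of the two central fields carries the exclusion.
#'
#' @inheritParams run_wildtype
#' @return an `abc_experiment`.
#' @export
run_wus_exclusion_variant <- function(config = run_config(),
                                      half_fraction = 0.5) {
  opts_w <- config$options
  opts_w$exclusion_driver <- "WUS"
  var_cfg <- run_config(grid = config$grid, kinetics = config$kinetics,
                        wus = config$wus, boundary = config$boundary,
                        options = opts_w, dt = config$dt,
                        n_steps = config$n_steps,
                        sample_every = config$sample_every)
  wt_traj <- simulate_abc(config)
  var_traj <- simulate_abc(var_cfg)
  s_wt <- pattern_summary(wt_traj, half_fraction)
  s_var <- pattern_summary(var_traj, half_fraction)
  centre <- .centre_cell(config)
  comparisons <- c(
    wt_ap1T_min_cell = s_wt$ap1T_min_cell,
    variant_ap1T_min_cell = s_var$ap1T_min_cell,
    label_mismatches = sum(as.character(s_wt$zone_labels) !=
                             as.character(s_var$zone_labels)))
  verdicts <- c(
    ap1T_min_at_centre_both = s_wt$ap1T_min_cell == centre &&
      s_var$ap1T_min_cell == centre,
    zone_sequence_identical = identical(as.character(s_wt$zone_labels),
                                        as.character(s_var$zone_labels)),
    ordering_preserved = .zone_ordering_ok(as.character(s_var$zone_labels),
                                           centre))
  .experiment_report("wus_exclusion_variant",
                     list(wildtype = config, variant = var_cfg),
                     list(wildtype = s_wt, variant = s_var),
                     comparisons, verdicts)
}

#' Parameter robustness scan
#'
#' Re-runs the model with each rate constant k1..k16 perturbed and records
#' whether the emergent pattern survives. `mode = "pm10"` draws one value per
#' parameter uniformly within +/-10% of its working value (seeded);
#' `mode = "table_intervals"` evaluates both endpoints of each parameter's
#' stability interval ([param_intervals()], with the k5 interval in its
#' corrected reading). The stability verdict per run is: identical zone-label
#' sequence and unchanged AG peak cell relative to wild type.
#'
#' @param mode `"pm10"` or `"table_intervals"`.
#' @param seed integer seed for the `pm10` draws.
#' @inheritParams run_wildtype
#' @return an `abc_experiment`; `tables$scan` has one row per run.
#' @export
run_robustness_scan <- function(mode = c("pm10", "table_intervals"),
                                seed = 1L, config = run_config(),
                                half_fraction = 0.5) {
  mode <- match.arg(mode)
  wt <- pattern_summary(simulate_abc(config), half_fraction)
  wt_labels <- as.character(wt$zone_labels)
  pars <- paste0("k", 1:16)
  if (mode == "pm10") {
    set.seed(seed)
    base <- unlist(config$kinetics[pars])
    values <- lapply(seq_along(pars),
                     function(i) runif(1, 0.9 * base[i], 1.1 * base[i]))
    grid_tab <- data.frame(param = pars, value = unlist(values))
  } else {
    ints <- param_intervals()
    grid_tab <- data.frame(
      param = rep(pars, each = 2L),
      value = unlist(ints[pars]))
  }
  res <- lapply(seq_len(nrow(grid_tab)), function(i) {
    kin <- config$kinetics
    kin[[grid_tab$param[i]]] <- grid_tab$value[i]
    cfg <- run_config(grid = config$grid, kinetics = kin, wus = config$wus,
                      boundary = config$boundary, options = config$options,
                      dt = config$dt, n_steps = config$n_steps,
                      sample_every = config$sample_every)
    s <- pattern_summary(simulate_abc(cfg), half_fraction)
    data.frame(param = grid_tab$param[i], value = grid_tab$value[i],
               zone_match = identical(as.character(s$zone_labels), wt_labels),
               peak_match = s$ag_peak_cell == wt$ag_peak_cell,
               zones = paste(s$zone_labels, collapse = ""))
  })
  scan <- do.call(rbind, res)
  scan$stable <- scan$zone_match & scan$peak_match
  comparisons <- c(n_runs = nrow(scan), n_stable = sum(scan$stable),
                   n_params = length(unique(scan$param)))
  verdicts <- c(all_stable = all(scan$stable),
                one_row_per_parameter_value = nrow(scan) ==
                  (if (mode == "pm10") 16L else 32L))
  .experiment_report(paste0("robustness_", mode), list(wildtype = config),
                     list(wildtype = wt), comparisons, verdicts,
                     tables = list(scan = scan))
}

#' @export
print.abc_experiment <- function(x, ...) {
  cat("experiment:", x$name, "\n")
  cat("verdicts:\n")
  for (nm in names(x$verdicts)) {
    cat(sprintf("  [%s] %s\n", if (isTRUE(x$verdicts[[nm]])) "pass" else
      "FAIL", nm))
  }
  cat("metrics:\n")
  for (nm in names(x$comparisons)) {
    cat(sprintf("  %s = %.6g\n", nm, x$comparisons[[nm]]))
  }
  if (!is.null(x$tables)) {
    for (nm in names(x$tables)) {
      cat("table:", nm, "\n")
      print(utils::head(x$tables[[nm]], 40L))
    }
  }
  invisible(x)
}

## plain-list form used for (lossless) report serialization
report_to_list <- function(rep) {
  stopifnot(inherits(rep, "abc_experiment"))
  list(name = rep$name,
       comparisons = as.list(rep$comparisons),
       verdicts = lapply(as.list(rep$verdicts), isTRUE),
       zones = lapply(rep$summaries, function(s) {
         if (is.null(s)) NULL else paste(s$zone_labels, collapse = "")
       }))
}
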