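## Configuration files are YAML documents with the sections
## grid / kinetics / wus / boundary / options / run; every key defaults to the
## reference study conditions, unknown keys are rejected, and load -> dump ->
## load is idempotent.

.config_keys <- list(
  grid = c("n_cells", "cell_length"),
  kinetics = c(paste0("k", 1:16), "beta1", "beta2", "beta3", "gate_time",
               "epsilon"),
  wus = c("k17", "d_w", "h_w", "T_wy", "k_y", "d_y", "D_y", "time_scale",
          "sigmoid_variant", "amplitude_mode"),
  boundary = c("name", "L", "y0"),
  options = c("gate_scope", "denominator_scope", "ap1_feedback",
              "exclusion_driver", "clip_negative"),
  run = c("dt", "n_steps", "sample_every", "seed"))

#' Load a run configuration from a YAML file
#'
#' Missing sections and keys fall back to the default study conditions; an
#' empty file therefore yields the full default configuration. Unknown
#' sections or keys, and values outside their admissible range, raise an error
#' naming the offending key. The returned configuration carries a
#' `provenance` attribute listing every key that was set by the file.
#'
#' @param path path to a YAML configuration file.
#' @return a [run_config()] with attribute `provenance`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  doc <- yaml::read_yaml(path)
  if (is.null(doc)) doc <- list()
  if (!is.list(doc)) stop("malformed config: top level must be a mapping")
  bad <- setdiff(names(doc), names(.config_keys))
  if (length(bad)) stop("unknown config section(s): ",
                        paste(bad, collapse = ", "))
  prov <- character(0)
  for (sec in names(doc)) {
    unknown <- setdiff(names(doc[[sec]]), .config_keys[[sec]])
    if (length(unknown)) {
      stop("unknown key(s) in [", sec, "]: ",
           paste(unknown, collapse = ", "))
    }
    prov <- c(prov, paste(sec, names(doc[[sec]]), sep = "."))
  }
  get_sec <- function(sec) if (is.null(doc[[sec]])) list() else doc[[sec]]
  g <- get_sec("grid"); k <- get_sec("kinetics"); w <- get_sec("wus")
  b <- get_sec("boundary"); o <- get_sec("options"); r <- get_sec("run")

  wrap <- function(sec, expr) {
    tryCatch(expr, error = function(e) {
      stop("invalid value in [", sec, "]: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  grid <- wrap("grid", do.call(grid_spec, g))
  kin_over <- k[setdiff(names(k), c("gate_time", "epsilon"))]
  kin_args <- c(kin_over,
                list(gate_time = if (is.null(k$gate_time)) 18000 else
                  k$gate_time,
                  epsilon = if (is.null(k$epsilon)) 5 else k$epsilon))
  kinetics <- wrap("kinetics", do.call(kinetic_params, kin_args))
  wus <- wrap("wus", do.call(wus_params, w))
  b_args <- c(list(name = if (is.null(b$name)) "wide" else b$name,
                   grid = grid),
              b[setdiff(names(b), "name")])
  boundary <- wrap("boundary", do.call(boundary_config, b_args))
  options <- wrap("options", do.call(model_options, o))
  cfg <- wrap("run", run_config(
    grid = grid, kinetics = kinetics, wus = wus, boundary = boundary,
    options = options,
    dt = if (is.null(r$dt)) 0.05 else r$dt,
    n_steps = if (is.null(r$n_steps)) 1200000L else r$n_steps,
    sample_every = if (is.null(r$sample_every)) 2000L else r$sample_every,
    seed = r$seed))
  attr(cfg, "provenance") <- prov
  cfg
}

## plain-list image of a run_config, the canonical serialized form
.config_as_list <- function(config) {
  p <- config$kinetics
  w <- config$wus
  b <- config$boundary
  o <- config$options
  out <- list(
    grid = list(n_cells = config$grid$n_cells,
                cell_length = config$grid$cell_length),
    kinetics = c(p[c(paste0("k", 1:16), "beta1", "beta2", "beta3")],
                 list(gate_time = p$gate_time, epsilon = p$epsilon)),
    wus = w[c("k17", "d_w", "h_w", "T_wy", "k_y", "d_y", "D_y", "time_scale",
              "sigmoid_variant", "amplitude_mode")],
    boundary = if (b$name == "custom") {
      list(name = b$name, L = b$L, y0 = b$y0)
    } else list(name = b$name),
    options = o[c("gate_scope", "denominator_scope", "ap1_feedback",
                  "exclusion_driver", "clip_negative")],
    run = c(list(dt = config$dt, n_steps = config$n_steps,
                 sample_every = config$sample_every),
            if (!is.null(config$seed)) list(seed = config$seed)))
  lapply(out, function(sec) lapply(sec, function(v) {
    if (is.numeric(v) && length(v) == 1L) unname(v) else v
  }))
}

#' Write a run configuration to a YAML file
#'
#' Inverse of [load_config()]: dumping and re-loading yields an equal
#' configuration.
#'
#' @param config a [run_config()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(.config_as_list(config), path, precision = 15L)
  invisible(path)
}

#' Hash of a run configuration
#'
#' MD5 digest of the canonical YAML image of the configuration; recorded in
#' run summaries so any output can be traced to the exact configuration that
#' produced it.
#'
#' @param config a [run_config()].
#' @return hex digest string.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_config(config, tmp)
  unname(tools::md5sum(tmp))
}

#' Write a trajectory as a tab-separated table
#'
#' One row per (sampled time, cell) with columns `t_hours`, `cell`, `lfy`,
#' `ap1`, `ap1_T`, `ag`, `tfl1`, `wus`, `y`, written at full float precision
#' so a read-back reproduces the values bit exactly. A companion YAML
#' run-summary (`<path>.summary.yaml`) records the configuration hash, clip
#' counts and the final pattern summary.
#'
#' @param traj an [simulate_abc()] trajectory.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "abc_trajectory"))
  if (length(traj$times) == 0L) stop("empty trajectory")
  n <- traj$config$grid$n_cells
  m <- length(traj$times)
  cols <- c("lfy", "ap1", "ap1_T", "ag", "tfl1", "wus", "y")
  df <- data.frame(
    t_hours = sprintf("%.17g", rep(traj$hours, each = n)),
    cell = rep(seq_len(n), times = m))
  for (f in cols) df[[f]] <- sprintf("%.17g", as.vector(t(traj$fields[[f]])))
  ok <- tryCatch({
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) stop("cannot write trajectory to ", path, ": ",
                              conditionMessage(e), call. = FALSE))
  s <- pattern_summary(traj)
  yaml::write_yaml(
    list(config_hash = config_hash(traj$config),
         n_samples = m, n_cells = n,
         clip_counts = as.list(traj$clip_counts),
         final = list(zones = paste(s$zone_labels, collapse = ""),
                      ag_peak_cell = s$ag_peak_cell,
                      ag_halfmax_width = s$ag_halfmax_width,
                      ap1T_min_cell = s$ap1T_min_cell,
                      wus_peak_cell = s$wus_peak_cell,
                      symmetry_error = s$symmetry_error,
                      steady_time_h = s$steady_time / 3600,
                      zones_stable_from_h =
                        s$classification_stable_from / 3600)),
    paste0(path, ".summary.yaml"), precision = 15L)
  invisible(path)
}

#' Read back a trajectory table
#'
#' @param path a TSV written by [write_trajectory()].
#' @return data frame with numeric columns as written.
#' @export
read_trajectory <- function(path) {
  read.delim(path, check.names = FALSE)
}

#' Write the canonical boundary-configuration fixtures
#'
#' Writes `wide.yaml` and `narrow.yaml` (full default configuration with the
#' respective boundary signal) into `dir`.
#'
#' @param dir output directory (created if needed).
#' @return character vector of the two paths, invisibly.
#' @export
make_fixtures <- function(dir = "fixtures") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in c("wide", "narrow")) {
    cfg <- run_config(boundary = boundary_config(nm))
    p <- file.path(dir, paste0(nm, ".yaml"))
    write_config(cfg, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
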