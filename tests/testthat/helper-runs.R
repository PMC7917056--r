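## memoised expensive runs shared across test files
.run_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .run_cache)) {
    assign(name, force(expr), envir = .run_cache)
  }
  get(name, envir = .run_cache)
}

## full default (wild-type) trajectory at the reference step size
wt_traj <- function() cached("wt", simulate_abc(run_config()))

## same study conditions integrated at a 10x coarser step; used where the
## test exercises experiment plumbing rather than the reference numerics
coarse_config <- function(...) {
  run_config(dt = 0.5, n_steps = 120000L, sample_every = 200L, ...)
}

coarse_traj <- function() cached("coarse", simulate_abc(coarse_config()))

## uniform, WUS-silent configuration: the AG gate never produces (WUS absent
## and LFY production alone cannot beat the TFL1 sink), so the system reduces
## to the linear LFY/AP1/TFL1 subsystem
nowus_config <- function(n_steps = 240000L, dt = 0.05) {
  n <- 15L
  grid <- grid_spec(n)
  bc <- boundary_config("custom", grid, L = rep(0, n), y0 = rep(0, n))
  init <- field_state(0, lfy = rep(1, n), ap1 = rep(0, n), ag = rep(0, n),
                      tfl1 = rep(0.1, n), wus = rep(0, n), y = rep(0, n))
  run_config(grid = grid,
             wus = wus_params(k17 = 0, amplitude_mode = "literal"),
             boundary = bc, dt = dt, n_steps = n_steps,
             sample_every = 2000L, initial_state = init)
}
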