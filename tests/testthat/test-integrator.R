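## Heun scheme, engines, determinism, conservation properties

test_that("Heun step matches the closed-form update on linear decay", {
  expect_equal(heun_step(1, 0, 0.1, function(t, x) -x), 0.905)
  expect_identical(heun_step(c(1, 2), 5, 0.1, function(t, x) 0 * x),
                   c(1, 2))
  expect_error(heun_step(1, 0, 0, function(t, x) -x), "dt")
})

test_that("Heun is second order on linear decay", {
  integrate_to <- function(dt, t_end = 1) {
    x <- 1
    for (i in seq_len(round(t_end / dt))) {
      x <- heun_step(x, (i - 1) * dt, dt, function(t, x) -x)
    }
    x
  }
  e1 <- abs(integrate_to(0.1) - exp(-1))
  e2 <- abs(integrate_to(0.05) - exp(-1))
  expect_gt(e1 / e2, 3.5)
  expect_lt(e1 / e2, 4.5)
})

test_that("compiled and reference engines agree step for step", {
  cfgs <- list(
    run_config(kinetics = kinetic_params(gate_time = 50),
               n_steps = 2000L, sample_every = 400L),
    run_config(kinetics = kinetic_params(gate_time = 50),
               boundary = boundary_config("narrow"),
               n_steps = 2000L, sample_every = 400L,
               epsilon_schedule = list(values = c(0, 7, 3), every_s = 25)),
    run_config(kinetics = kinetic_params(gate_time = 50),
               options = model_options(ap1_feedback = "effective",
                                       exclusion_driver = "WUS",
                                       gate_scope = "wus_term_only",
                                       denominator_scope = "lfy_term_only"),
               n_steps = 1000L, sample_every = 250L,
               epsilon_schedule = list(
                 values = matrix(seq(0, 10, length.out = 15), nrow = 1),
                 every_s = 0)))
  for (cfg in cfgs) {
    a <- simulate_abc(cfg, engine = "compiled")
    b <- simulate_abc(cfg, engine = "reference")
    expect_equal(a$times, b$times)
    for (f in names(a$fields)) {
      expect_lt(max(abs(a$fields[[f]] - b$fields[[f]])), 1e-12)
    }
  }
})

test_that("plain Euler differs from Heun and both are deterministic", {
  cfg <- run_config(n_steps = 1000L, sample_every = 500L)
  h1 <- simulate_abc(cfg)
  h2 <- simulate_abc(cfg)
  eu <- simulate_abc(cfg, method = "euler")
  expect_identical(h1$fields, h2$fields) # bit-identical rerun
  expect_gt(max(abs(h1$fields$tfl1 - eu$fields$tfl1)), 0)
})

test_that("clipping keeps concentrations non-negative and is counted", {
  cfg <- run_config(n_steps = 2000L, sample_every = 500L)
  traj <- simulate_abc(cfg)
  expect_true(all(vapply(traj$fields, function(m) all(m >= 0), logical(1))))
  expect_gt(traj$clip_counts[["ag"]], 0) # pre-gate AG drain clips at 0
  raw_cfg <- run_config(options = model_options(clip_negative = FALSE),
                        n_steps = 2000L, sample_every = 500L)
  raw <- simulate_abc(raw_cfg)
  expect_lt(min(raw$fields$ag), 0) # unclipped drain goes negative
})

test_that("uniform initial fields stay exactly uniform when the repressor
           subsystem is silent", {
  traj <- simulate_abc(nowus_config(n_steps = 5000L))
  for (f in c("lfy", "ap1", "ag", "tfl1", "wus", "y")) {
    spread <- apply(traj$fields[[f]], 1, function(v) diff(range(v)))
    expect_identical(max(spread), 0)
  }
})

test_that("the uniform AG-free run converges to the linear-solve fixed
           point", {
  traj <- simulate_abc(nowus_config(n_steps = 100000L))
  fin <- final_state(traj)
  fp <- uniform_fixed_point(kinetic_params())
  expect_equal(unname(fin$lfy), rep(fp[["lfy"]], 15), tolerance = 1e-6)
  expect_equal(unname(fin$ap1), rep(fp[["ap1"]], 15), tolerance = 1e-6)
  expect_equal(unname(fin$tfl1), rep(fp[["tfl1"]], 15), tolerance = 1e-6)
})

test_that("gross step sizes are reported as instabilities", {
  cfg <- run_config(dt = 1e5, n_steps = 400L, sample_every = 1L,
                    options = model_options(clip_negative = FALSE))
  expect_error(simulate_abc(cfg), "unstable")
})

test_that("settling-time detection matches closed forms", {
  mk_traj <- function(times, value_fun) {
    n <- 15
    fields <- lapply(setNames(nm = c("lfy", "ap1", "ap1_T", "ag", "tfl1",
                                     "wus", "y")),
                     function(f) outer(value_fun(times), rep(1, n)))
    structure(list(times = times, hours = times / 3600, fields = fields,
                   config = run_config()),
              class = "abc_trajectory")
  }
  times <- seq(0, 16 * 3600, by = 100)
  const <- mk_traj(times, function(t) rep(2, length(t)))
  expect_equal(steady_state_time(const)$time, 0)
  expect_true(steady_state_time(const)$reached)
  # unit-amplitude decay with a 2 h time constant: settling time for a
  # relative-rate tolerance tol is ~ tau * log(1 / (tol * tau))
  tau_h <- 2
  dec <- mk_traj(times, function(t) exp(-t / (tau_h * 3600)))
  got <- steady_state_time(dec, tol = 1e-3)
  expect_true(got$reached)
  expect_equal(got$hours, tau_h * log(1 / (1e-3 * tau_h)), tolerance = 0.05)
  # a trajectory still moving at the end is flagged as not settled
  lin <- mk_traj(times, function(t) t / max(times))
  expect_false(steady_state_time(lin)$reached)
})
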