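## rate laws, exclusion transform, lattice coupling, uniform fixed point

uniform_state <- function(lfy = 0, ap1 = 0, ag = 0, tfl1 = 0, wus = 0,
                          y = 0, t = 0, n = 15) {
  field_state(t, rep(lfy, n), rep(ap1, n), rep(ag, n), rep(tfl1, n),
              rep(wus, n), rep(y, n))
}

test_that("AG exclusion transform scales AP1 by a saturating factor", {
  expect_equal(effective_ap1(c(1, 1), c(0, 0), 0.05), c(1, 1))
  expect_equal(effective_ap1(2, 0.05, 0.05), 1) # half suppression at ag=beta1
  expect_equal(effective_ap1(1, 0.45, 0.05), 1 * (1 - 0.45 / 0.5))
  expect_error(effective_ap1(c(1, 2), 1, 0.05), "length")
  expect_error(effective_ap1(1, 1, 0), "beta1")
  set.seed(41)
  for (i in 1:20) {
    ap1 <- runif(15, 0, 5)
    ag <- runif(15, 0, 3)
    out <- effective_ap1(ap1, ag, 0.05)
    expect_true(all(out >= 0 & out <= ap1))
  }
})

test_that("AG gate is closed before and open from the gate time", {
  expect_identical(heaviside_gate(17999, 18000), 0)
  expect_identical(heaviside_gate(18000, 18000), 1) # right-continuous
  expect_identical(heaviside_gate(57600, 18000), 1)
  expect_error(heaviside_gate(-1), ">= 0")
})

test_that("no-flux Laplacian mirrors ghost cells and conserves mass", {
  expect_equal(noflux_laplacian(rep(3.7, 9)), rep(0, 9))
  expect_equal(noflux_laplacian(c(0, 1, 0)), c(1, -2, 1))
  expect_error(noflux_laplacian(c(1, 2)), "3 cells")
  set.seed(42)
  for (i in 1:20) {
    v <- runif(sample(3:25, 1), 0, 10)
    expect_equal(sum(noflux_laplacian(v)), 0, tolerance = 1e-12)
  }
})

test_that("rate laws reproduce direct evaluations of the kinetic model", {
  p <- kinetic_params()
  expect_equal(lfy_rate(uniform_state(lfy = 1), p), rep(-0.01, 15))
  expect_equal(lfy_rate(uniform_state(), p), rep(0.03, 15))
  expect_equal(ap1_rate(uniform_state(), p), rep(0.09, 15))
  expect_equal(ap1_rate(uniform_state(lfy = 1, tfl1 = 1), p), rep(0.12, 15))
  expect_equal(tfl1_rate(uniform_state(), p), rep(0.9, 15))
  # pre-gate AG silence and trivial post-gate zero
  expect_equal(ag_rate(uniform_state(wus = 1, lfy = 1, t = 0), p),
               rep(0, 15))
  expect_equal(ag_rate(uniform_state(t = 18000), p), rep(0, 15))
  # direct evaluation at the near-fixed-point state with a strong WUS input
  st <- uniform_state(lfy = 1.548, ap1 = 2.85, tfl1 = 1.256, wus = 1,
                      t = 18000)
  pk <- kinetic_params(k9 = 0.5)
  expected <- (0.5 * 1 + 0.025 * 1.548) / (1 + 0.55 * 2.85) - 0.03 * 1.256
  expect_equal(ag_rate(st, pk), rep(expected, 15), tolerance = 1e-12)
})

test_that("a uniform LFY field feels no coupling at any epsilon", {
  st <- uniform_state(lfy = 2.5, ap1 = 1, tfl1 = 0.5)
  r0 <- lfy_rate(st, kinetic_params(epsilon = 0))
  r10 <- lfy_rate(st, kinetic_params(epsilon = 10))
  expect_identical(r0, r10)
})

test_that("the TFL1 rate vanishes at the uniform fixed point", {
  p <- kinetic_params()
  fp <- uniform_fixed_point(p)
  st <- uniform_state(lfy = fp[["lfy"]], ap1 = fp[["ap1"]], tfl1 = fp[["tfl1"]])
  expect_equal(tfl1_rate(st, p), rep(0, 15), tolerance = 1e-12)
  expect_equal(lfy_rate(st, p), rep(0, 15), tolerance = 1e-12)
  expect_equal(ap1_rate(st, p), rep(0, 15), tolerance = 1e-12)
})

test_that("uniform fixed point matches closed forms and handles clipping", {
  # decoupled: each gene balances its own production and decay
  p <- kinetic_params(k2 = 0, k3 = 0, k6 = 0, k7 = 0, k14 = 0, k15 = 0)
  expect_equal(uniform_fixed_point(p),
               c(lfy = 0.03 / 0.04, ap1 = 0.09 / 0.05, tfl1 = 0.9 / 0.55))
  # no production at all
  p0 <- kinetic_params(k1 = 0, k5 = 0, k13 = 0)
  expect_equal(uniform_fixed_point(p0), c(lfy = 0, ap1 = 0, tfl1 = 0))
  # strong AP1 production drives TFL1 negative; it must be pinned at zero
  pc <- kinetic_params(k5 = 0.9)
  fp <- uniform_fixed_point(pc)
  expect_identical(unname(fp[["tfl1"]]), 0)
  st <- uniform_state(lfy = fp[["lfy"]], ap1 = fp[["ap1"]], tfl1 = 0)
  expect_equal(lfy_rate(st, pc), rep(0, 15), tolerance = 1e-12)
  expect_equal(ap1_rate(st, pc), rep(0, 15), tolerance = 1e-12)
  expect_lt(max(tfl1_rate(st, pc)), 0) # clipping is self-consistent
})

test_that("parameter validation rejects bad values and flags intervals", {
  expect_error(kinetic_params(k3 = -1), "k3")
  expect_error(kinetic_params(bogus = 1), "bogus")
  expect_error(kinetic_params(epsilon = -1), "epsilon")
  expect_warning(kinetic_params(k9 = 0.6, check_intervals = TRUE),
                 "k9.*interval")
  # k5 is exempt from interval checking: its printed interval excludes its
  # working value
  expect_silent(kinetic_params(check_intervals = TRUE))
  ints <- param_intervals(corrected = FALSE)
  expect_identical(ints$k5, c(0.9, 1.5))
  expect_identical(param_intervals()$k5, c(0.09, 0.15))
})

test_that("grid and field-state invariants hold", {
  g <- grid_spec()
  expect_identical(g$n_cells, 15L)
  expect_equal(g$diameter, 66)
  expect_error(grid_spec(2), "n_cells")
  expect_error(grid_spec(15, 0), "cell_length")
  st <- uniform_state(ap1 = 2, ag = 0.05)
  expect_equal(st$ap1_T, rep(1, 15)) # derived profile stored consistently
  expect_error(field_state(0, 1:3 / 10, 1:2 / 10, rep(0, 3), rep(0, 3),
                           rep(0, 3), rep(0, 3)),
               "ap1")
})
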