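## pattern quantification: peaks, zones, widths, symmetry, distances

mk_state <- function(ag, ap1T) {
  # field_state with a prescribed ag and effective-AP1 profile: choose raw
  # ap1 so that the derived ap1_T equals the requested profile
  n <- length(ag)
  beta1 <- 0.05
  ap1 <- ap1T / (1 - ag / (ag + beta1))
  ap1[!is.finite(ap1)] <- 0
  field_state(0, rep(1, n), ap1, ag, rep(0.1, n), rep(0, n), rep(0, n),
              beta1 = beta1)
}

test_that("peak_cell returns the lowest-index maximum", {
  expect_identical(peak_cell(c(0, 1, 0)), 2L)
  expect_identical(peak_cell(rep(2, 7)), 1L) # tie-break toward low index
  expect_error(peak_cell(numeric(0)), "empty")
})

test_that("peak and width agree with exhaustive scans", {
  scan_peak <- function(v) {
    best <- 1L
    for (j in seq_along(v)) if (v[j] > v[best]) best <- j
    best
  }
  scan_width <- function(v) {
    w <- 0L
    for (j in seq_along(v)) if (v[j] >= max(v) / 2) w <- w + 1L
    w
  }
  set.seed(11)
  for (i in 1:25) {
    v <- runif(sample(3:30, 1), 0, 10)
    expect_identical(peak_cell(v), scan_peak(v))
    expect_identical(halfmax_width(v), scan_width(v))
  }
})

test_that("zone classification labels a constructed unimodal pattern", {
  ag <- c(0, 0, 0.1, 0.8, 1, 0.8, 0.1, 0, 0)
  ap1T <- c(1, 0.9, 0.4, 0.1, 0, 0.1, 0.4, 0.9, 1)
  lab <- zone_classify(list(ag = ag, ap1_T = ap1T))
  expect_identical(as.character(lab),
                   c("A", "A", "B", "C", "C", "C", "B", "A", "A"))
  memb <- attr(lab, "membership")
  expect_identical(unname(memb[, "C"]), ag >= 0.5)
  expect_identical(unname(memb[, "A"]), ap1T >= 0.5)
})

test_that("zone classification handles degenerate inputs", {
  all_a <- zone_classify(list(ag = rep(0, 5), ap1_T = rep(2, 5)))
  expect_identical(as.character(all_a), rep("A", 5))
  undef <- zone_classify(list(ag = rep(0, 5), ap1_T = rep(0, 5)))
  expect_true(all(is.na(undef)))
  expect_true(attr(undef, "undefined"))
  expect_error(zone_classify(list(ag = 1, ap1_T = 1), half_fraction = 0),
               "half_fraction")
})

test_that("zone labels are invariant under rescaling both profiles", {
  set.seed(13)
  for (i in 1:15) {
    ag <- runif(15, 0, 2)
    ap1T <- runif(15, 0, 3)
    base <- as.character(zone_classify(list(ag = ag, ap1_T = ap1T)))
    s <- runif(1, 0.01, 100)
    expect_identical(
      as.character(zone_classify(list(ag = s * ag, ap1_T = s * ap1T))),
      base)
  }
})

test_that("half-max width counts cells at or above half maximum", {
  expect_identical(halfmax_width(c(0, 0, 1, 0, 0)), 1L)
  expect_identical(halfmax_width(c(0, 0.6, 1, 0.6, 0)), 3L)
  expect_error(halfmax_width(rep(0, 5)), "all-zero")
  expect_error(halfmax_width(c(-1, 1)), "non-negative")
})

test_that("symmetry error measures the worst mirror mismatch", {
  expect_equal(symmetry_error(c(1, 2, 3, 2, 1)), 0)
  expect_equal(symmetry_error(c(1, 0, 0)), 1)
  expect_error(symmetry_error(c(1, 2)), "odd")
})

test_that("profile distance is the max field-wise deviation", {
  a <- mk_state(c(0, 0, 1, 0, 0), c(1, 1, 0, 1, 1))
  expect_equal(profile_distance(a, a), 0)
  b <- a
  b$ag[2] <- b$ag[2] + 0.25
  expect_equal(profile_distance(a, b), 0.25)
  small <- mk_state(c(0, 1, 0), c(1, 0, 1))
  expect_error(profile_distance(a, small), "mismatch")
})

test_that("pattern summary of the default-conditions run reports the
           central AG domain", {
  s <- pattern_summary(coarse_traj())
  expect_identical(s$ag_peak_cell, 8L)
  expect_identical(s$wus_peak_cell, 8L)
  expect_identical(s$ap1T_min_cell, 8L)
  expect_identical(as.character(s$zone_labels)[c(1, 8, 15)],
                   c("A", "C", "A"))
  runs <- rle(as.character(s$zone_labels))$values
  expect_true(identical(runs, c("A", "C", "A")) ||
                identical(runs, c("A", "B", "C", "B", "A")))
  expect_lt(s$symmetry_error, 1e-12)
  expect_true(s$steady_reached)
  expect_lt(s$classification_stable_from, 16 * 3600)
})
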