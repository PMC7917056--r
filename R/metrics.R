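#' Index of the profile maximum
#'
#' Ties are broken toward the lowest index.
#'
#' @param profile non-empty numeric vector.
#' @return 1-based cell index.
#' @export
peak_cell <- function(profile) {
  if (length(profile) == 0L) stop("empty profile")
  unname(which.max(profile))
}

#' Classify cells into the A, B and C expression zones
#'
#' A cell is labelled C where AG is at least `half_fraction` of its spatial
#' maximum, A where it is not C and the effective AP1 (`ap1_T`) is at least
#' `half_fraction` of its maximum, and B otherwise. A field whose maximum is
#' zero contributes no cells (so an all-zero AG profile yields no C zone).
#' The labels carry a `membership` attribute with the raw per-cell A- and
#' C-eligibility calls, a soft output where the B region overlaps its
#' neighbours rather than excluding them.
#'
#' @param state a [field_state()], or a list with elements `ag` and `ap1_T`.
#' @param half_fraction threshold as a fraction of the spatial maximum.
#' @return character vector of labels "A"/"B"/"C" with attribute
#'   `membership` (logical matrix, columns `A` and `C`). If both profiles are
#'   identically zero the classification is undefined: all labels are `NA`
#'   and attribute `undefined` is `TRUE`.
#' @export
zone_classify <- function(state, half_fraction = 0.5) {
  ag <- state$ag
  ap1T <- state$ap1_T
  if (is.null(ag) || is.null(ap1T)) stop("state must provide ag and ap1_T")
  if (!is.finite(half_fraction) || half_fraction <= 0 || half_fraction > 1) {
    stop("half_fraction must be in (0, 1]")
  }
  n <- length(ag)
  c_on <- max(ag) > 0 & ag >= half_fraction * max(ag)
  a_on <- max(ap1T) > 0 & ap1T >= half_fraction * max(ap1T)
  if (max(ag) == 0 && max(ap1T) == 0) {
    lab <- rep(NA_character_, n)
    attr(lab, "undefined") <- TRUE
    attr(lab, "membership") <- cbind(A = a_on, C = c_on)
    return(lab)
  }
  lab <- rep("B", n)
  lab[c_on] <- "C"
  lab[!c_on & a_on] <- "A"
  attr(lab, "undefined") <- FALSE
  attr(lab, "membership") <- cbind(A = a_on, C = c_on)
  lab
}

#' Number of cells at or above half maximum
#'
#' Width metric for a unimodal expression domain: counts the cells whose value
#' is at least half the profile maximum.
#'
#' @param profile non-negative numeric vector with a positive maximum.
#' @return integer cell count.
#' @export
halfmax_width <- function(profile) {
  if (any(profile < 0)) stop("profile must be non-negative")
  m <- max(profile)
  if (m <= 0) stop("all-zero profile has no half-max width")
  sum(profile >= m / 2)
}

#' Deviation from mirror symmetry about the centre cell
#'
#' For an odd-length profile, the maximum absolute difference between each
#' cell and its mirror image through the centre.
#'
#' @param profile odd-length numeric vector.
#' @return maximum absolute mirror mismatch (uM).
#' @export
symmetry_error <- function(profile) {
  n <- length(profile)
  if (n %% 2L == 0L) stop("profile must have odd length (no centre cell)")
  max(abs(profile - rev(profile)))
}

#' Largest per-cell difference between two states
#'
#' Maximum over the fields lfy, ap1_T, ag, tfl1, wus and over cells of the
#' absolute concentration difference; the distance used by the
#' coupling-invariance and robustness checks.
#'
#' @param a,b [field_state()] objects on matching grids.
#' @return distance (uM).
#' @export
profile_distance <- function(a, b) {
  if (length(a$lfy) != length(b$lfy)) stop("grid mismatch")
  nm <- c("lfy", "ap1_T", "ag", "tfl1", "wus")
  max(vapply(nm, function(f) max(abs(a[[f]] - b[[f]])), numeric(1)))
}

## first sample from which the zone labels equal the final labels through the
## end of the run; NA labels (undefined classification) never match
.zone_stable_from <- function(traj, half_fraction = 0.5) {
  m <- length(traj$times)
  labs <- lapply(seq_len(m), function(i) {
    as.character(zone_classify(get_state(traj, i), half_fraction))
  })
  final <- labs[[m]]
  same <- vapply(labs, function(l) identical(l, final), logical(1))
  bad <- which(!same)
  i0 <- if (length(bad)) max(bad) + 1L else 1L
  traj$times[i0]
}

#' Summarise the emergent pattern of a run
#'
#' Collects the zone labels of the final state, the AG / WUS peak cells and
#' the effective-AP1 minimum cell, the AG half-max width, the worst mirror
#' asymmetry over the final fields, the settling time of the trajectory and
#' the time from which the zone classification equals its final form.
#'
#' @param traj an [simulate_abc()] trajectory.
#' @param half_fraction threshold passed to [zone_classify()].
#' @param tol settling tolerance passed to [steady_state_time()].
#' @return object of class `pattern_summary`.
#' @export
pattern_summary <- function(traj, half_fraction = 0.5, tol = 1e-3) {
  stopifnot(inherits(traj, "abc_trajectory"))
  fin <- final_state(traj)
  st <- steady_state_time(traj, tol)
  sym <- max(vapply(c("lfy", "ap1_T", "ag", "tfl1", "wus"),
                    function(f) symmetry_error(fin[[f]]), numeric(1)))
  structure(
    list(zone_labels = zone_classify(fin, half_fraction),
         ag_peak_cell = peak_cell(fin$ag),
         ap1T_min_cell = unname(which.min(fin$ap1_T)),
         wus_peak_cell = peak_cell(fin$wus),
         ag_halfmax_width = if (max(fin$ag) > 0) halfmax_width(fin$ag)
                            else NA_integer_,
         symmetry_error = sym,
         steady_time = st$time,
         steady_reached = st$reached,
         classification_stable_from = .zone_stable_from(traj, half_fraction),
         half_fraction = half_fraction),
    class = "pattern_summary")
}

#' @export
print.pattern_summary <- function(x, ...) {
  cat("pattern summary\n")
  cat("  zones:", paste(ifelse(is.na(x$zone_labels), ".", x$zone_labels),
                        collapse = " "), "\n")
  cat(sprintf("  AG peak cell %d (half-max width %s); ap1_T min cell %d; WUS peak cell %d\n",
              x$ag_peak_cell, x$ag_halfmax_width, x$ap1T_min_cell,
              x$wus_peak_cell))
  cat(sprintf("  mirror asymmetry %.3g uM\n", x$symmetry_error))
  cat(sprintf("  settled by %.2f h (%s); zones final from %.2f h\n",
              x$steady_time / 3600,
              if (x$steady_reached) "reached" else "not reached",
              x$classification_stable_from / 3600))
  invisible(x)
}
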