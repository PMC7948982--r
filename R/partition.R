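#' Flux-competition branching at the C4a-hydroperoxyflavin node
#'
#' The oxygenated flavin either eliminates H2O2 (uncoupling, `k_unc`) or
#' reacts with halide to form HOX (`k_hox_obs`); the memoryless competition
#' gives `f_unc = k_unc / (k_unc + k_hox_obs)`.
#'
#' @param k_unc Uncoupling rate, s^-1.
#' @param k_hox_obs Observed HOX-formation rate, s^-1 (see [k_hox_obs()]).
#' @return Named vector `c(f_unc, f_hox)` summing to 1.
#' @export
branching_fractions <- function(k_unc, k_hox_obs) {
  check_nonneg(k_unc, "k_unc")
  check_nonneg(k_hox_obs, "k_hox_obs")
  if (k_unc + k_hox_obs == 0) {
    halokin_error("branching undefined: both rates are zero",
                  "halokin_undefined_branch_error")
  }
  f_unc <- k_unc / (k_unc + k_hox_obs)
  c(f_unc = f_unc, f_hox = 1 - f_unc)
}

#' Capture-vs-leakage budget from the measured coupling ratio
#'
#' Given the fraction of flavin flux that forms HOX and the end-point
#' coupling ratio (halogenated product per flavin consumed), solve the
#' two-way HOX partition: `f_capture = coupling_ratio / f_hox`,
#' `f_leak = 1 - f_capture`.
#'
#' @param f_hox Fraction of C4aOOH flux forming HOX, in (0, 1].
#' @param coupling_ratio Product formed per flavin consumed, in
#'   \[0, f_hox\].
#' @return A `partition_result` list with `f_unc`, `f_hox`, `f_capture`,
#'   `f_leak`, `coupling_ratio`; satisfies
#'   `f_unc + f_hox * (f_capture + f_leak) = 1` exactly.
#' @export
coupling_budget <- function(f_hox, coupling_ratio) {
  if (f_hox <= 0 || f_hox > 1) {
    halokin_error("'f_hox' must lie in (0, 1]", "halokin_validation_error")
  }
  if (coupling_ratio < 0 || coupling_ratio > f_hox) {
    halokin_error("inconsistent budget: coupling_ratio exceeds f_hox",
                  "halokin_inconsistency_error")
  }
  f_capture <- coupling_ratio / f_hox
  structure(
    list(f_unc = 1 - f_hox, f_hox = f_hox,
         f_capture = f_capture, f_leak = 1 - f_capture,
         coupling_ratio = coupling_ratio),
    class = "partition_result"
  )
}

#' Analytic coupling ratio predicted from scheme parameters
#'
#' Product per flavin consumed along the deterministic scheme:
#' `P_ox * f_hox * f_capture`, where `P_ox = k_ox [O2] / (k_ox [O2] + k_inact)`
#' is the probability that a bound complex is oxidized before it
#' isomerizes to the inactive form.
#'
#' @inheritParams simulate_scheme
#' @param X_conc Halide concentration, mM.
#' @param O2 Oxygen bath concentration, µM.
#' @return Predicted coupling ratio in \[0, 1\].
#' @export
predicted_coupling <- function(params, halide, X_conc,
                               O2 = 128) {
  kox <- params$k_ox * O2
  p_ox <- if (kox + params$k_inact == 0) 0 else kox / (kox + params$k_inact)
  khobs <- k_hox_obs(params, halide, X_conc)
  f_hox <- if (is.na(params$f_unc_pop)) {
    if (params$k_unc + khobs == 0) 0 else khobs / (params$k_unc + khobs)
  } else {
    1 - params$f_unc_pop
  }
  cap <- params$k_capture + params$k_leak
  f_capture <- if (cap == 0) 0 else params$k_capture / cap
  p_ox * f_hox * f_capture
}

#' Single-turnover halogenation time course
#'
#' Simulates the rapid-quench-flow experiment: FADH- limiting, substrate
#' tryptophan in excess, and the halogenated-product fraction
#' `[TrpX](t) / [FADH-]_0` read at each quench time. The plateau equals the
#' analytic [predicted_coupling()] for the same parameters.
#'
#' @inheritParams simulate_scheme
#' @param quench_times Quench time points, s (increasing, > 0).
#' @return Data frame `time_s`, `halogenated_fraction`.
#' @export
simulate_single_turnover <- function(params, init, halide, quench_times,
                                     mode = "rapid_equilibrium") {
  check_grid(quench_times)
  fadh0 <- init$y0[["FADH_free"]] + init$y0[["E_FADH"]]
  if (fadh0 <= 0) {
    halokin_error("no reduced flavin in the initial conditions",
                  "halokin_validation_error")
  }
  if (init$y0[["Trp"]] < fadh0) {
    warning("Trp below FADH-: substrate-limited regime is not modeled")
  }
  tc <- simulate_scheme(params, init, halide, quench_times, mode = mode)
  data.frame(time_s = tc$time_s,
             halogenated_fraction = tc$TrpX / fadh0)
}

#' Phase-amplitude fraction of a 450-nm rise
#'
#' Decomposes a completed absorbance rise into its kinetic phases and
#' returns the phase-2 share of the total post-formation rise,
#' `|A2| / (|A2| + |A3|)`. Phases are resolved by multi-exponential
#' fitting (so the result is independent of optical scale factors) and
#' assigned to windows by their characteristic times `1/kobs` relative to
#' `phase_boundaries`; in population-partition simulations the fraction
#' recovers the committed uncoupling fraction.
#'
#' @param trace_450 A `kin_trace` (typically channel A450) containing a
#'   completed rise.
#' @param phase_boundaries Increasing interior boundaries, s: two values
#'   delimit phases 1 / 2 / 3.
#' @return Fraction in \[0, 1\].
#' @export
amplitude_partition <- function(trace_450, phase_boundaries = c(0.15, 2.5)) {
  if (is.unsorted(phase_boundaries, strictly = TRUE)) {
    halokin_error("'phase_boundaries' must be strictly increasing",
                  "halokin_validation_error")
  }
  xy <- as_trace_xy(trace_450)
  if (diff(range(xy$value)) == 0) {
    halokin_error("zero total rise: amplitude fraction undefined",
                  "halokin_undefined_fraction_error")
  }
  n_max <- length(phase_boundaries) + 1L
  n <- select_phase_count(trace_450, max_n = n_max)
  fit <- fit_exponentials(trace_450, n)
  tau <- 1 / fit$phases$kobs
  bounds <- c(0, phase_boundaries, Inf)
  win <- findInterval(tau, bounds)
  amp2 <- sum(abs(fit$phases$amplitude[win == 2L]))
  amp3 <- sum(abs(fit$phases$amplitude[win == 3L]))
  if (amp2 + amp3 == 0) {
    halokin_error("no rise amplitude beyond the formation phase",
                  "halokin_undefined_fraction_error")
  }
  amp2 / (amp2 + amp3)
}

#' Branch fates from a stochastic event log
#'
#' Counts per-molecule fates in a [gillespie_scheme()] run and returns the
#' empirical partition fractions.
#'
#' @param sim Result of [gillespie_scheme()].
#' @return Named vector `f_unc`, `f_hox`, `f_capture`, `f_leak` (NA where
#'   the corresponding branch saw no events).
#' @export
gillespie_fractions <- function(sim) {
  ev <- sim$events$reaction
  n_unc <- sum(ev %in% c("uncoupling", "uncoupling_X"))
  n_hox <- sum(ev == "hox_formation")
  n_cap <- sum(ev == "hox_capture")
  n_leak <- sum(ev == "hox_leak")
  branch <- n_unc + n_hox
  hoxfate <- n_cap + n_leak
  c(f_unc = if (branch) n_unc / branch else NA_real_,
    f_hox = if (branch) n_hox / branch else NA_real_,
    f_capture = if (hoxfate) n_cap / hoxfate else NA_real_,
    f_leak = if (hoxfate) n_leak / hoxfate else NA_real_)
}
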