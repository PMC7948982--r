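#' Additive Gaussian noise model for synthetic instrument data
#'
#' Stopped-flow photomultiplier noise at the signal levels emulated here is
#' approximately Gaussian and homoscedastic; the noise SD is expressed as a
#' fraction of each trace's dynamic range.
#'
#' @param sigma_frac Noise SD as a fraction of the dynamic range
#'   (default 0.02).
#' @param seed Integer seed; `NULL` leaves the RNG untouched.
#' @return A `noise_model` list.
#' @export
noise_model <- function(sigma_frac = 0.02, seed = NULL) {
  check_nonneg(sigma_frac, "sigma_frac")
  structure(list(sigma_frac = sigma_frac, seed = seed),
            class = "noise_model")
}

add_noise <- function(values, noise) {
  if (noise$sigma_frac == 0) return(values)
  sd <- noise$sigma_frac * diff(range(values))
  with_seed(noise$seed, values + stats::rnorm(length(values), 0, sd))
}

truth_record <- function(kind, truth, noise, extra = list()) {
  c(list(kind = kind, truth = truth,
         sigma_frac = noise$sigma_frac, seed = noise$seed),
    extra)
}

#' Write / read a generator truth sidecar
#'
#' Every generated dataset is accompanied by a structured sidecar recording
#' the exact truth (parameters, initial conditions, optics, noise, seed)
#' used to produce it, serialized losslessly (full double precision JSON).
#'
#' @param truth Truth list, as attached to generator outputs.
#' @param path Sidecar path (.json).
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(unclass_deep(truth), path,
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

unclass_deep <- function(x) {
  if (is.matrix(x)) {
    as.data.frame(x)
  } else if (is.list(x)) {
    lapply(unclass(x), unclass_deep)
  } else if (is.atomic(x) && !is.null(names(x))) {
    as.list(x)  # keep names: serialize as a JSON object, not an array
  } else {
    x
  }
}

#' Generate a noisy synthetic stopped-flow trace
#'
#' Runs [simulate_scheme()] under a truth configuration, reads out the
#' requested detector channel and adds seeded Gaussian noise. Identical
#' (truth, seed) pairs give identical output; `sigma_frac = 0` reproduces
#' the deterministic trace exactly.
#'
#' @param truth List with `params` ([rate_parameters()]), `init`
#'   ([initial_conditions()]) and `halide`, e.g. an entry of
#'   [thal_truths()].
#' @param channel Detector channel (see [kin_trace()]).
#' @param grid Time grid, s.
#' @param noise A [noise_model()].
#' @param optics An [optical_model()].
#' @return A `kin_trace` with the full truth attached as attribute
#'   `"truth"` (write it with [write_truth()]).
#' @export
generate_trace <- function(truth, channel, grid = log_grid(),
                           noise = noise_model(), optics = optical_model()) {
  tc <- simulate_scheme(truth$params, truth$init, truth$halide, grid)
  tr <- species_to_trace(tc, optics, channel)
  tr$value <- add_noise(tr$value, noise)
  attr(tr, "truth") <- truth_record(
    "trace", truth, noise,
    list(channel = channel, optics = optics)
  )
  tr
}

#' Generate a kobs-vs-halide-concentration dataset
#'
#' Points follow the two-step hyperbola [predict_kobs()] with seeded
#' Gaussian noise (SD = `sigma_frac` x the kobs dynamic range). When noise
#' is present the known SD is stored in the `se` column so downstream fits
#' can weight by it.
#'
#' @param halide Halide symbol.
#' @param Kd,k Truth parameters (mM, s^-1).
#' @param concs Distinct concentrations, mM (>= 4).
#' @param noise A [noise_model()].
#' @return A `saturation_dataset` with attribute `"truth"`.
#' @export
generate_saturation_dataset <- function(halide, Kd, k, concs,
                                        noise = noise_model()) {
  if (length(concs) < 4L) {
    halokin_error("need >= 4 concentrations", "halokin_validation_error")
  }
  kobs <- predict_kobs(Kd, k, concs)
  sd <- noise$sigma_frac * diff(range(kobs))
  vals <- add_noise(kobs, noise)
  ds <- saturation_dataset(halide, concs, vals,
                           se = if (sd > 0) rep(sd, length(concs)) else NULL)
  attr(ds, "truth") <- truth_record(
    "saturation", list(halide = halide, Kd = Kd, k = k, concs = concs), noise
  )
  ds
}

#' Generate a first-phase-amplitude vs. age-time series
#'
#' Emulates the double-mixing inactivation experiment:
#' `amplitude = floor + A0 exp(-k_inact age)` plus seeded noise.
#'
#' @param k_inact Isomerization rate, s^-1.
#' @param ages Strictly increasing age times, s.
#' @param A0 Amplitude at zero age (signal units).
#' @param floor Long-age asymptote.
#' @param noise A [noise_model()].
#' @return An `inactivation_series` with attribute `"truth"`.
#' @export
generate_inactivation_series <- function(k_inact, ages, A0 = 0.13, floor = 0,
                                         noise = noise_model()) {
  vals <- floor + A0 * exp(-k_inact * ages)
  vals <- add_noise(vals, noise)
  ser <- inactivation_series(ages, vals)
  attr(ser, "truth") <- truth_record(
    "inactivation",
    list(k_inact = k_inact, A0 = A0, floor = floor, ages = ages), noise
  )
  ser
}

#' Generate a rapid-quench product-fraction series
#'
#' Halogenated-product fractions from [simulate_single_turnover()] with
#' seeded noise, clipped to \[0, 1\].
#'
#' @param truth List with `params`, `init`, `halide` (e.g.
#'   `thal_truths()$single_turnover`).
#' @param quench_times Quench times, s.
#' @param noise A [noise_model()].
#' @return Data frame `time_s`, `halogenated_fraction` with attribute
#'   `"truth"`.
#' @export
generate_quench_series <- function(truth, quench_times,
                                   noise = noise_model()) {
  st <- simulate_single_turnover(truth$params, truth$init, truth$halide,
                                 quench_times)
  st$halogenated_fraction <- pmin(pmax(
    add_noise(st$halogenated_fraction, noise), 0), 1)
  attr(st, "truth") <- truth_record(
    "quench", truth, noise, list(quench_times = quench_times)
  )
  st
}
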