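#' Observed rate of the two-step halide reaction
#'
#' Rapid-equilibrium halide binding (Kd) followed by rate-limiting
#' chemistry (k) gives the hyperbola `kobs = k [X] / (Kd + [X])`: zero at
#' zero halide, approaching k at saturation.
#'
#' @param Kd Dissociation constant, mM (> 0).
#' @param k Limiting rate, s^-1.
#' @param conc Halide concentrations, mM (>= 0).
#' @return Observed rates, s^-1.
#' @export
predict_kobs <- function(Kd, k, conc) {
  if (Kd <= 0) halokin_error("'Kd' must be > 0", "halokin_validation_error")
  check_nonneg(conc, "conc")
  k * conc / (Kd + conc)
}

#' Assemble a kobs-vs-halide-concentration dataset
#'
#' @param halide Halide symbol.
#' @param conc_mM Distinct halide concentrations, mM (>= 4 for fitting).
#' @param kobs_s1 Observed rates, s^-1.
#' @param se Optional known per-point standard errors of kobs.
#' @return A `saturation_dataset` data frame.
#' @export
saturation_dataset <- function(halide, conc_mM, kobs_s1, se = NULL) {
  halide <- halide_id(halide)
  check_nonneg(conc_mM, "conc_mM")
  if (anyDuplicated(conc_mM)) {
    halokin_error("halide concentrations must be distinct",
                  "halokin_validation_error")
  }
  df <- data.frame(conc_mM = conc_mM, kobs_s1 = kobs_s1)
  if (!is.null(se)) df$se <- se
  structure(df, class = c("saturation_dataset", "data.frame"),
            halide = halide)
}

#' Fit the hyperbolic two-step saturation model
#'
#' Least squares of [predict_kobs()] to a `saturation_dataset`. The
#' hyperbola is linear in k at fixed Kd, so the fit profiles the weighted
#' RSS over log(Kd) with a one-dimensional golden-section search - no
#' starting values and no convergence failures on well-posed data. The
#' intercept is fixed at zero (the saturation curve passes through the
#' origin); standard errors come from the Jacobian-based covariance at the
#' optimum. When the dataset carries known per-point errors, the fit is
#' weighted by them and the covariance is not rescaled by the residuals.
#'
#' @param ds A [saturation_dataset()] with at least 4 points spanning
#'   concentrations below and above the eventual Kd.
#' @return A `saturation_fit`: `Kd`, `se_Kd` (mM), `k`, `se_k` (s^-1),
#'   `rmse`, `n_points`, `halide`.
#' @export
fit_saturation <- function(ds) {
  stopifnot(inherits(ds, "saturation_dataset") || is.data.frame(ds))
  conc <- ds$conc_mM
  kobs <- ds$kobs_s1
  if (length(conc) < 4L) {
    halokin_error("need >= 4 distinct concentrations", "halokin_validation_error")
  }
  w <- if (!is.null(ds$se)) 1 / ds$se^2 else rep(1, length(conc))
  absolute_sigma <- !is.null(ds$se)

  k_at <- function(Kd) {
    u <- conc / (Kd + conc)
    sum(w * u * kobs) / sum(w * u^2)
  }
  rss_at <- function(logKd) {
    Kd <- exp(logKd)
    u <- conc / (Kd + conc)
    kk <- sum(w * u * kobs) / sum(w * u^2)
    sum(w * (kobs - kk * u)^2)
  }
  cpos <- conc[conc > 0]
  lo <- log(min(cpos)) - log(1e4)
  hi <- log(max(cpos)) + log(1e4)
  opt <- stats::optimize(rss_at, c(lo, hi), tol = 1e-12)
  Kd <- exp(opt$minimum)
  k <- k_at(Kd)

  ## identifiability: the half-saturation point must lie inside (or near)
  ## the sampled range. A fit driven far above it means the data look like
  ## a straight line through the origin; far below, all points are already
  ## at saturation.
  if (Kd > 100 * max(cpos) || Kd < min(cpos) / 50 ||
      opt$minimum < lo + 1e-3 || opt$minimum > hi - 1e-3) {
    halokin_error(
      "Kd is unidentifiable: concentrations do not bracket the half-saturation point",
      "halokin_unidentifiable_error", Kd_attempt = Kd, k_attempt = k
    )
  }

  u <- conc / (Kd + conc)
  resid <- kobs - k * u
  rss <- sum(w * resid^2)
  J <- cbind(k_col = u, Kd_col = -k * conc / (Kd + conc)^2)
  JtWJ <- crossprod(J * sqrt(w))
  covm <- tryCatch(chol2inv(chol(JtWJ)), error = function(e)
    matrix(NA_real_, 2, 2))
  if (!absolute_sigma) {
    covm <- covm * rss / max(length(conc) - 2L, 1L)
  }
  se <- sqrt(pmax(diag(covm), 0))

  structure(
    list(Kd = Kd, se_Kd = se[2], k = k, se_k = se[1],
         rmse = sqrt(mean(resid^2)), n_points = length(conc),
         halide = attr(ds, "halide")),
    class = "saturation_fit"
  )
}

#' @export
print.saturation_fit <- function(x, ...) {
  cat(sprintf("two-step saturation fit (%s, %d points)\n",
              x$halide %||% "?", x$n_points))
  cat(sprintf("  Kd = %.4g +/- %.2g mM\n  k  = %.4g +/- %.2g s^-1\n",
              x$Kd, x$se_Kd, x$k, x$se_k))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble a first-phase-amplitude vs. age-time series
#'
#' The double-mixing inactivation experiment: the enzyme-FADH- complex is
#' aged anaerobically before oxygen exposure, and the amplitude of the
#' fast C4aOOH-FAD formation phase reports how much active complex is left.
#'
#' @param age_s Strictly increasing anaerobic incubation times, s.
#' @param amplitude First-phase amplitudes (signal units).
#' @return An `inactivation_series` data frame.
#' @export
inactivation_series <- function(age_s, amplitude) {
  if (any(age_s < 0) || any(diff(age_s) <= 0)) {
    halokin_error("'age_s' must be >= 0 and strictly increasing",
                  "halokin_validation_error")
  }
  structure(data.frame(age_s = age_s, amplitude = amplitude),
            class = c("inactivation_series", "data.frame"))
}

#' Fit the single-exponential inactivation decay
#'
#' Fits `amplitude(t_age) = floor + A0 exp(-k_inact t_age)`, the
#' isomerization of the active enzyme-flavin complex to its dead-end form.
#'
#' @param series An [inactivation_series()] with >= 4 points.
#' @return List with `k_inact`, `se_k_inact` (s^-1), `A0`, `floor`, `rmse`.
#' @export
fit_inactivation <- function(series) {
  if (nrow(series) < 4L) {
    halokin_error("need >= 4 age points", "halokin_validation_error")
  }
  fit <- fit_exp_core(series$age_s, series$amplitude, n_phases = 1L)
  A0 <- fit$phases$amplitude[1]
  if (A0 <= 0) {
    halokin_error("series does not decay: fitted amplitude is not positive",
                  "halokin_fit_error")
  }
  list(k_inact = fit$phases$kobs[1], se_k_inact = fit$phases$se_kobs[1],
       A0 = A0, floor = fit$offset, rmse = fit$rmse)
}

#' Read / write kobs-saturation datasets as CSV
#'
#' Columns `conc_mM`, `kobs_s1` and optionally `se`.
#'
#' @param ds A [saturation_dataset()].
#' @param path CSV path.
#' @param halide Halide symbol used when reading (stored as an attribute).
#' @export
write_saturation_csv <- function(ds, path) {
  utils::write.csv(as.data.frame(ds), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_saturation_csv
#' @export
read_saturation_csv <- function(path, halide) {
  df <- utils::read.csv(path)
  saturation_dataset(halide, df$conc_mM, df$kobs_s1, se = df$se)
}
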