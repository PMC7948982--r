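#' Validate a halide identifier
#'
#' Halides are identified by their element symbol. Fluoride is accepted as
#' input everywhere but carries a hypohalous-acid formation rate of exactly
#' zero: no fluorinating species is formed at the flavin site.
#'
#' @param halide Character scalar, one of `"Cl"`, `"Br"`, `"I"`, `"F"`.
#' @return The validated halide symbol.
#' @export
halide_id <- function(halide) {
  if (!is.character(halide) || length(halide) != 1L ||
      !halide %in% c("Cl", "Br", "I", "F")) {
    halokin_error("'halide' must be one of \"Cl\", \"Br\", \"I\", \"F\"",
                  "halokin_validation_error")
  }
  halide
}

#' Microscopic rate constants of the halogenase scheme
#'
#' Container for all rate and equilibrium constants of the branched FDH
#' catalytic cycle. Defaults are the reference parameterization for Thal
#' (tryptophan 6-halogenase) assembled from published transient-kinetics
#' measurements; see the package vignette for provenance and units.
#'
#' @param k_bind_flavin Enzyme + FADH- association, µM^-1 s^-1.
#' @param k_inact Isomerization of the active enzyme:FADH- complex to the
#'   dead-end inactive complex, s^-1.
#' @param k_ox Reaction of bound FADH- with O2 to form C4a-hydroperoxyflavin
#'   (C4aOOH-FAD), µM^-1 s^-1. The pseudo-first-order formation rate is
#'   `k_ox * [O2]`.
#' @param k_unc Uncoupling: C4aOOH-FAD -> FAD + H2O2 without HOX formation,
#'   s^-1.
#' @param Kd_X Named vector of rapid-equilibrium halide dissociation
#'   constants for C4aOOH-FAD, mM, for `I`, `Br`, `Cl`. Fluoride needs no
#'   entry (its HOX rate is identically zero).
#' @param k_hox Named vector of limiting HOX-formation rates from the
#'   C4aOOH-FAD:X- complex, s^-1, for `I`, `Br`, `Cl`.
#' @param k_dehyd Dehydration of C4a-hydroxyflavin to FAD, s^-1.
#' @param k_capture Enzyme-guided reaction of nascent HOX with bound
#'   tryptophan, s^-1.
#' @param k_leak Escape of nascent HOX to bulk solution, s^-1.
#' @param f_unc_pop Optional population-partition fraction in \[0, 1\]: the
#'   fraction of oxidized enzyme-flavin complexes committed to the
#'   uncoupling branch irrespective of flux competition. `NA` (default)
#'   selects ordinary flux-competition branching.
#' @return An object of class `rate_parameters`.
#' @export
rate_parameters <- function(k_bind_flavin = 5,
                            k_inact = 0.41,
                            k_ox = 16.52 / 128,
                            k_unc = 0.41,
                            Kd_X = c(I = 0.064, Br = 0.40, Cl = 0.78),
                            k_hox = c(I = 4.51, Br = 2.54, Cl = 1.83),
                            k_dehyd = 0.073,
                            k_capture = 37.5,
                            k_leak = 62.5,
                            f_unc_pop = NA_real_) {
  for (nm in c("k_bind_flavin", "k_inact", "k_ox", "k_unc", "k_dehyd",
               "k_capture", "k_leak")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L) {
      halokin_error(sprintf("'%s' must be a single number", nm),
                    "halokin_validation_error")
    }
    check_nonneg(v, nm)
  }
  need <- c("I", "Br", "Cl")
  if (!all(need %in% names(Kd_X)) || !all(need %in% names(k_hox))) {
    halokin_error("'Kd_X' and 'k_hox' need named entries for I, Br, Cl",
                  "halokin_validation_error")
  }
  Kd_X <- Kd_X[need]
  k_hox <- k_hox[need]
  if (any(!is.finite(Kd_X)) || any(Kd_X <= 0)) {
    halokin_error("'Kd_X' entries must be finite and > 0",
                  "halokin_validation_error")
  }
  check_nonneg(k_hox, "k_hox")
  ## fluoride carries no entries: its HOX-formation rate is identically
  ## zero, enforced in k_hox_obs() and the reaction builder
  if (!is.na(f_unc_pop) && (f_unc_pop < 0 || f_unc_pop > 1)) {
    halokin_error("'f_unc_pop' must be NA or within [0, 1]",
                  "halokin_validation_error")
  }
  structure(
    list(k_bind_flavin = k_bind_flavin, k_inact = k_inact, k_ox = k_ox,
         k_unc = k_unc, Kd_X = Kd_X, k_hox = k_hox, k_dehyd = k_dehyd,
         k_capture = k_capture, k_leak = k_leak,
         f_unc_pop = as.numeric(f_unc_pop)),
    class = "rate_parameters"
  )
}

#' Effective (observed) HOX-formation rate under rapid-equilibrium binding
#'
#' Lumps halide binding (Kd) and chemistry (k) into the observed
#' first-order decay rate of C4a-hydroperoxyflavin through the HOX branch:
#' `k_hox * [X] / (Kd + [X])`. Zero for fluoride or zero halide.
#'
#' @param params A [rate_parameters()] object.
#' @param halide Halide symbol, see [halide_id()].
#' @param X_conc Halide concentration, mM.
#' @return Observed rate, s^-1.
#' @export
k_hox_obs <- function(params, halide, X_conc) {
  halide <- halide_id(halide)
  check_nonneg(X_conc, "X_conc")
  if (halide == "F" || X_conc == 0) return(0)
  unname(params$k_hox[[halide]] * X_conc / (params$Kd_X[[halide]] + X_conc))
}

#' Initial conditions for the halogenase scheme
#'
#' All concentrations in µM except the halide bath, which follows the
#' field's convention of mM. O2 and halide are non-depleting baths held
#' constant (pseudo-first-order treatment, justified by their large excess
#' over flavin in all emulated experiments).
#'
#' @param ... Named starting concentrations (µM) for any species in
#'   [scheme_species()]; unnamed species start at zero.
#' @param O2 Dissolved oxygen, µM (default 128, an air-saturated mix).
#' @param X_conc Halide concentration, mM.
#' @return An object of class `initial_conditions`.
#' @export
initial_conditions <- function(..., O2 = 128, X_conc = 0) {
  extra <- list(...)
  y0 <- stats::setNames(numeric(length(.halokin_species)), .halokin_species)
  if (length(extra)) {
    bad <- setdiff(names(extra), .halokin_species)
    if (length(bad) || is.null(names(extra)) || any(names(extra) == "")) {
      halokin_error(
        sprintf("unknown species in initial conditions: %s",
                paste(bad, collapse = ", ")),
        "halokin_validation_error"
      )
    }
    y0[names(extra)] <- as.numeric(unlist(extra))
  }
  check_nonneg(y0, "initial concentrations")
  check_nonneg(O2, "O2")
  check_nonneg(X_conc, "X_conc")
  structure(list(y0 = y0, O2 = O2, X_conc = X_conc),
            class = "initial_conditions")
}
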