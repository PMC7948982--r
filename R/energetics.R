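## Physical constants (CODATA); R in kcal/(mol K) because barriers are
## quoted in kcal/mol throughout the halogenase literature.
.kB <- 1.380649e-23     # J/K
.h  <- 6.62607015e-34   # J s
.Rkcal <- 1.987204259e-3  # kcal/(mol K)

#' Reaction energetics profile for HOX formation
#'
#' Relative potential energies (kcal/mol) of reactant, transition state
#' and product for the reaction of C4a-hydroperoxyflavin with one halide.
#' Used only as fixed inputs to ordering checks; potential energies are
#' free-energy proxies here, never absolute rate predictors.
#'
#' @param halide Halide symbol.
#' @param E_TS Transition-state energy, kcal/mol (reactant = 0 by
#'   convention).
#' @param E_product Product energy, kcal/mol.
#' @param E_reactant Reactant energy; must be 0.
#' @return An `energetics_profile` list.
#' @export
energetics_profile <- function(halide, E_TS, E_product, E_reactant = 0) {
  halide <- halide_id(halide)
  if (E_reactant != 0) {
    halokin_error("'E_reactant' is 0 by convention", "halokin_validation_error")
  }
  if (E_TS < E_reactant) {
    halokin_error("'E_TS' must be >= E_reactant", "halokin_validation_error")
  }
  structure(list(halide = halide, E_reactant = E_reactant,
                 E_TS = E_TS, E_product = E_product),
            class = "energetics_profile")
}

#' Transition-state-theory (Eyring) rate from an activation barrier
#'
#' `rate = (kB T / h) exp(-barrier / (R T))`; strictly decreasing in the
#' barrier. At zero barrier this is the universal prefactor kB T / h
#' (about 6.21e12 s^-1 at 298.15 K).
#'
#' @param barrier Activation barrier, kcal/mol.
#' @param T Absolute temperature, K (> 0).
#' @return Rate, s^-1.
#' @export
eyring_rate <- function(barrier, T = 298.15) {
  if (any(T <= 0)) {
    halokin_error("'T' must be positive", "halokin_validation_error")
  }
  (.kB * T / .h) * exp(-barrier / (.Rkcal * T))
}

#' Consistency of computed barrier ordering with measured rate ordering
#'
#' Ranks halides by their HOX-formation barrier and by their measured
#' limiting rate k, and reports whether the two orderings are perfectly
#' anti-correlated (Spearman rank correlation -1): the lowest barrier
#' should belong to the fastest halide.
#'
#' @param profiles List of [energetics_profile()] objects.
#' @param measured List of `saturation_fit` objects (or lists with
#'   `halide` and `k`) covering the same halides.
#' @param T Temperature for the Eyring rates, K.
#' @return List with per-halide table, `barrier_order`, `k_order`,
#'   `rank_correlation`, `consistent`, and a `tied` flag.
#' @export
rank_reactivity <- function(profiles, measured, T = 298.15) {
  hb <- vapply(profiles, function(p) p$halide, character(1))
  hm <- vapply(measured, function(m) m$halide, character(1))
  if (!setequal(hb, hm) || anyDuplicated(hb) || anyDuplicated(hm)) {
    halokin_error("profiles and measured fits must cover the same halide set",
                  "halokin_validation_error")
  }
  barrier <- vapply(profiles, function(p) p$E_TS - p$E_reactant, numeric(1))
  k <- vapply(measured, function(m) m$k, numeric(1))[match(hb, hm)]
  tab <- data.frame(halide = hb, barrier_kcal_mol = barrier,
                    eyring_rate_s1 = eyring_rate(barrier, T),
                    measured_k_s1 = k)
  tab <- tab[order(tab$barrier_kcal_mol), ]
  rownames(tab) <- NULL
  tied <- anyDuplicated(barrier) > 0 || anyDuplicated(k) > 0
  rho <- if (tied) {
    NA_real_  # rank correlation undefined under ties; flagged instead
  } else if (length(barrier) > 1L) {
    stats::cor(barrier, k, method = "spearman")
  } else {
    -1  # a single halide is trivially consistent
  }
  list(table = tab,
       barrier_order = tab$halide,
       k_order = tab$halide[order(tab$measured_k_s1, decreasing = TRUE)],
       rank_correlation = rho,
       consistent = isTRUE(all.equal(rho, -1)) && !tied,
       tied = tied)
}
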