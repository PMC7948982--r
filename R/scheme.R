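#' Time grids for simulated stopped-flow windows
#'
#' @param t_min,t_max Window bounds in seconds; `t_min` must be > 0 for the
#'   log grid.
#' @param n Number of points.
#' @return Numeric vector of strictly increasing times (s). The log grid
#'   mirrors stopped-flow sampling over 0.002-100 s by default.
#' @export
log_grid <- function(t_min = 0.002, t_max = 100, n = 500) {
  if (t_min <= 0 || t_max <= t_min) {
    halokin_error("log_grid needs 0 < t_min < t_max", "halokin_validation_error")
  }
  exp(seq(log(t_min), log(t_max), length.out = n))
}

#' @rdname log_grid
#' @export
linear_grid <- function(t_min = 0, t_max = 100, n = 500) {
  if (t_max <= t_min) {
    halokin_error("linear_grid needs t_min < t_max", "halokin_validation_error")
  }
  seq(t_min, t_max, length.out = n)
}

check_grid <- function(times) {
  if (!is.numeric(times) || length(times) < 2L || any(!is.finite(times)) ||
      times[1] < 0 || any(diff(times) <= 0)) {
    halokin_error("time grid must be strictly increasing with first point >= 0",
                  "halokin_validation_error")
  }
  times
}

## Reaction network of the branched FDH cycle.
##
## Each reaction is a list with:
##   rate  - first-order (or bath-folded pseudo-first-order) rate constant
##   order - species whose concentrations enter the mass-action propensity
##   d     - named stoichiometry change applied per reaction event
## The same table drives the deterministic ODE and the Gillespie sampler.
build_reactions <- function(params, halide, init,
                            mode = c("rapid_equilibrium", "explicit"),
                            kon = NULL) {
  mode <- match.arg(mode)
  halide <- halide_id(halide)
  rxn <- list()
  add <- function(name, rate, order, d) {
    rxn[[length(rxn) + 1L]] <<- list(name = name, rate = rate,
                                     order = order, d = d)
  }

  add("bind", params$k_bind_flavin, c("E_free", "FADH_free"),
      c(E_free = -1, FADH_free = -1, E_FADH = 1))
  add("inactivation", params$k_inact, "E_FADH",
      c(E_FADH = -1, E_FADHstar = 1))

  kox <- params$k_ox * init$O2
  f <- params$f_unc_pop
  if (is.na(f)) {
    ## flux-competition mode: one C4aOOH pool carrying both decay channels
    add("oxidation", kox, "E_FADH", c(E_FADH = -1, C4aOOH = 1))
    add("uncoupling", params$k_unc, "C4aOOH",
        c(C4aOOH = -1, E_FAD = 1, H2O2 = 1))
  } else {
    ## population-partition mode: a fixed fraction of complexes commits to
    ## the uncoupling branch at the oxidation step
    add("oxidation_productive", kox * (1 - f), "E_FADH",
        c(E_FADH = -1, C4aOOH = 1))
    add("oxidation_uncoupling", kox * f, "E_FADH",
        c(E_FADH = -1, C4aOOH_unc = 1))
    add("uncoupling", params$k_unc, "C4aOOH_unc",
        c(C4aOOH_unc = -1, E_FAD = 1, H2O2 = 1))
  }

  if (mode == "rapid_equilibrium") {
    khobs <- k_hox_obs(params, halide, init$X_conc)
    if (khobs > 0) {
      add("hox_formation", khobs, "C4aOOH",
          c(C4aOOH = -1, C4aOH = 1, HOX_site = 1))
    }
  } else {
    if (halide != "F" && init$X_conc > 0 && params$k_hox[[halide]] > 0) {
      if (is.null(kon)) kon <- 1000 / params$Kd_X[[halide]]  # fast binding, mM^-1 s^-1
      add("halide_on", kon * init$X_conc, "C4aOOH",
          c(C4aOOH = -1, C4aOOH_X = 1))
      add("halide_off", kon * params$Kd_X[[halide]], "C4aOOH_X",
          c(C4aOOH_X = -1, C4aOOH = 1))
      add("hox_formation", params$k_hox[[halide]], "C4aOOH_X",
          c(C4aOOH_X = -1, C4aOH = 1, HOX_site = 1))
      ## uncoupling is insensitive to halide occupancy (the lumped mode
      ## applies k_unc to the whole C4aOOH pool); without this channel the
      ## two modes would diverge at saturating halide
      if (is.na(f) && params$k_unc > 0) {
        add("uncoupling_X", params$k_unc, "C4aOOH_X",
            c(C4aOOH_X = -1, E_FAD = 1, H2O2 = 1))
      }
    }
  }

  add("dehydration", params$k_dehyd, "C4aOH", c(C4aOH = -1, E_FAD = 1))
  add("hox_capture", params$k_capture, "HOX_site",
      c(HOX_site = -1, Trp = -1, TrpX = 1))
  add("hox_leak", params$k_leak, "HOX_site",
      c(HOX_site = -1, HOX_free = 1, product_leaked_trap = 1))

  Filter(function(r) r$rate > 0, rxn)
}

#' Integrate the branched halogenase kinetic scheme
#'
#' Deterministic mass-action integration of the FDH catalytic cycle:
#' flavin binding, isomerization to the inactive complex, oxidation to
#' C4a-hydroperoxyflavin, competition between H2O2-eliminating uncoupling
#' and HOX formation, C4a-hydroxyflavin dehydration, and partitioning of
#' nascent HOX between substrate capture and leakage. O2 and halide are
#' fixed baths. A stiff-capable integrator (`deSolve::lsoda`) is used with
#' rtol 1e-8 / atol 1e-10 µM; round-off negatives are clipped to zero on
#' output only.
#'
#' @param params A [rate_parameters()] object.
#' @param init An [initial_conditions()] object.
#' @param halide Halide symbol ([halide_id()]).
#' @param grid Strictly increasing times, s (see [log_grid()]).
#' @param mode `"rapid_equilibrium"` (default) lumps halide binding into an
#'   observed rate `k_hox * [X]/(Kd + [X])`; `"explicit"` integrates finite
#'   on/off binding consistent with the same Kd.
#' @param kon Optional explicit-mode association rate, mM^-1 s^-1.
#' @return A `species_timecourse`: data frame with `time_s` and one column
#'   per species (µM).
#' @export
simulate_scheme <- function(params, init, halide, grid,
                            mode = c("rapid_equilibrium", "explicit"),
                            kon = NULL) {
  stopifnot(inherits(params, "rate_parameters"),
            inherits(init, "initial_conditions"))
  mode <- match.arg(mode)
  halide <- halide_id(halide)
  times <- check_grid(grid)
  rxn <- build_reactions(params, halide, init, mode = mode, kon = kon)

  y0 <- init$y0
  t0_extra <- times[1] > 0
  tt <- if (t0_extra) c(0, times) else times

  deriv <- function(t, y, p) {
    dy <- numeric(length(y))
    names(dy) <- names(y)
    for (r in rxn) {
      v <- r$rate * prod(y[r$order])
      dy[names(r$d)] <- dy[names(r$d)] + v * r$d
    }
    list(dy)
  }

  out <- deSolve::lsoda(y = y0, times = tt, func = deriv, parms = NULL,
                        rtol = 1e-8, atol = 1e-10)
  if (nrow(out) < length(tt) || anyNA(out)) {
    last_t <- if (nrow(out)) out[nrow(out), 1] else tt[1]
    halokin_error(
      sprintf("stiff integration failed in the interval [%g, %g] s",
              last_t, tt[length(tt)]),
      "halokin_integration_error"
    )
  }
  out <- as.data.frame(out)
  if (t0_extra) out <- out[-1, , drop = FALSE]
  names(out)[1] <- "time_s"
  out[-1] <- lapply(out[-1], function(x) pmax(x, 0))
  rownames(out) <- NULL
  structure(out,
            class = c("species_timecourse", "data.frame"),
            params = params, init = init, halide = halide, mode = mode)
}

#' Total flavin concentration over a simulated time course
#'
#' @param tc A `species_timecourse` from [simulate_scheme()].
#' @return Numeric vector, summed flavin species (µM) at each grid point.
#' @export
flavin_total <- function(tc) {
  rowSums(as.data.frame(tc)[, .halokin_flavin_species, drop = FALSE])
}

#' Closed-form two-step irreversible chain A -> B -> C
#'
#' Analytic oracle for the linear sub-chain of the scheme (e.g. bound
#' FADH- -> C4aOOH-FAD -> FAD):
#' `A = A0 e^(-k1 t)`, `B = A0 k1/(k2-k1) (e^(-k1 t) - e^(-k2 t))`,
#' `C = A0 - A - B`.
#'
#' @param k1,k2 Step rate constants, s^-1; must be positive and distinct.
#' @param A0 Starting concentration of A, µM.
#' @param t Times, s.
#' @return Data frame with columns `time_s`, `A`, `B`, `C`.
#' @export
closed_form_chain <- function(k1, k2, A0, t) {
  if (!is.numeric(k1) || !is.numeric(k2) || k1 <= 0 || k2 <= 0) {
    halokin_error("'k1' and 'k2' must be positive", "halokin_validation_error")
  }
  if (isTRUE(all.equal(k1, k2))) {
    halokin_error("degenerate chain: k1 = k2 has no two-exponential form",
                  "halokin_degenerate_error")
  }
  A <- A0 * exp(-k1 * t)
  B <- A0 * k1 / (k2 - k1) * (exp(-k1 * t) - exp(-k2 * t))
  data.frame(time_s = t, A = A, B = B, C = A0 - A - B)
}
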