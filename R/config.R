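#' Write / read a kinetics configuration file
#'
#' Structured key-value (YAML) configuration holding the rate parameters,
#' initial conditions, per-halide sub-blocks (Kd, k_hox, energetics) and
#' optical coefficients. Numeric values round-trip at full double
#' precision.
#'
#' @param params A [rate_parameters()] object.
#' @param init An [initial_conditions()] object.
#' @param optics An [optical_model()].
#' @param profiles Optional list of [energetics_profile()] objects.
#' @param path File path (.yaml).
#' @export
write_kinetics_config <- function(params, init, optics = optical_model(),
                                  profiles = NULL, path) {
  halides <- c("I", "Br", "Cl")
  cfg <- list(
    rates = list(
      k_bind_flavin = params$k_bind_flavin, k_inact = params$k_inact,
      k_ox = params$k_ox, k_unc = params$k_unc, k_dehyd = params$k_dehyd,
      k_capture = params$k_capture, k_leak = params$k_leak,
      f_unc_pop = if (is.na(params$f_unc_pop)) NULL else params$f_unc_pop
    ),
    halides = stats::setNames(lapply(halides, function(h) {
      b <- list(Kd_mM = unname(params$Kd_X[[h]]),
                k_hox_s1 = unname(params$k_hox[[h]]))
      if (!is.null(profiles)) {
        p <- Filter(function(x) x$halide == h, profiles)
        if (length(p)) {
          b$E_TS_kcal_mol <- p[[1]]$E_TS
          b$E_product_kcal_mol <- p[[1]]$E_product
        }
      }
      b
    }), halides),
    initial = c(as.list(init$y0[init$y0 > 0]),
                list(O2_uM = init$O2, X_conc_mM = init$X_conc)),
    optics = list(path_length_cm = optics$path_length,
                  eps = apply(optics$eps, 1, as.list, simplify = FALSE),
                  phi = apply(optics$phi, 1, as.list, simplify = FALSE))
  )
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

#' @rdname write_kinetics_config
#' @return `read_kinetics_config()` returns a list with `params`, `init`,
#'   `optics` and (when present) `profiles`.
#' @export
read_kinetics_config <- function(path) {
  if (!file.exists(path)) {
    halokin_error(sprintf("config file not found: %s", path),
                  "halokin_config_error")
  }
  cfg <- yaml::read_yaml(path)
  r <- cfg$rates
  hb <- cfg$halides
  params <- rate_parameters(
    k_bind_flavin = r$k_bind_flavin, k_inact = r$k_inact, k_ox = r$k_ox,
    k_unc = r$k_unc,
    Kd_X = vapply(hb, `[[`, numeric(1), "Kd_mM")[c("I", "Br", "Cl")],
    k_hox = vapply(hb, `[[`, numeric(1), "k_hox_s1")[c("I", "Br", "Cl")],
    k_dehyd = r$k_dehyd, k_capture = r$k_capture, k_leak = r$k_leak,
    f_unc_pop = if (is.null(r$f_unc_pop)) NA_real_ else r$f_unc_pop
  )
  ini <- cfg$initial
  species <- ini[setdiff(names(ini), c("O2_uM", "X_conc_mM"))]
  init <- do.call(initial_conditions,
                  c(species, list(O2 = ini$O2_uM, X_conc = ini$X_conc_mM)))
  optics <- optical_model(
    path_length = cfg$optics$path_length_cm,
    eps = do.call(rbind, lapply(cfg$optics$eps, function(x)
      unlist(x)[c("A380", "A450")])),
    phi = do.call(rbind, lapply(cfg$optics$phi, function(x)
      unlist(x)[c("F_ex380", "F_ex450")]))
  )
  profiles <- NULL
  if (all(c("E_TS_kcal_mol", "E_product_kcal_mol") %in% names(hb[[1]]))) {
    profiles <- lapply(names(hb), function(h)
      energetics_profile(h, E_TS = hb[[h]]$E_TS_kcal_mol,
                         E_product = hb[[h]]$E_product_kcal_mol))
  }
  list(params = params, init = init, optics = optics, profiles = profiles)
}
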