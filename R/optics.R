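## Chromophore class of each scheme species: all flavin species share the
## spectrum of their flavin state regardless of enzyme association.
.chromophore_class <- c(
  FADH_free = "FADH", E_FADH = "FADH", E_FADHstar = "FADH",
  C4aOOH = "C4aOOH", C4aOOH_unc = "C4aOOH", C4aOOH_X = "C4aOOH",
  C4aOH = "C4aOH",
  E_FAD = "FAD", FAD_free = "FAD",
  E_free = "none", HOX_site = "none", HOX_free = "none", H2O2 = "none",
  Trp = "none", TrpX = "none", product_leaked_trap = "none"
)

.optics_channels <- c("A380", "A450", "F_ex380", "F_ex450")

#' Optical model mapping flavin species to detector observables
#'
#' Molar absorptivities (mM^-1 cm^-1) at 380/450 nm and relative
#' fluorescence brightness (arbitrary units per µM, long-pass emission
#' > 495 nm) per chromophore class. The defaults are literature-typical
#' flavin / C4a-adduct spectra and are deliberate placeholders: no
#' Thal-bound extinction coefficients have been published, and every
#' analysis in this package depends on rate constants and relative
#' amplitudes, not on absolute coefficients. The two C4a adducts are given
#' equal 450-nm coefficients so that channel reports FAD regeneration
#' cleanly. C4a-hydroxyflavin is by far the brightest fluorophore, which is
#' what makes it distinguishable from C4a-hydroperoxyflavin.
#'
#' @param path_length Optical path, cm.
#' @param eps Matrix of absorptivities, rows = chromophore classes
#'   (`FADH`, `C4aOOH`, `C4aOH`, `FAD`, `none`), columns `A380`, `A450`.
#' @param phi Matrix of fluorescence brightness, same rows, columns
#'   `F_ex380`, `F_ex450`.
#' @return An object of class `optical_model`.
#' @export
optical_model <- function(path_length = 1,
                          eps = NULL, phi = NULL) {
  classes <- c("FADH", "C4aOOH", "C4aOH", "FAD", "none")
  if (is.null(eps)) {
    eps <- rbind(FADH   = c(A380 = 3.0, A450 = 0.7),
                 C4aOOH = c(A380 = 8.0, A450 = 0.8),
                 C4aOH  = c(A380 = 7.5, A450 = 0.8),
                 FAD    = c(A380 = 6.0, A450 = 11.3),
                 none   = c(A380 = 0.0, A450 = 0.0))
  }
  if (is.null(phi)) {
    phi <- rbind(FADH   = c(F_ex380 = 0.02, F_ex450 = 0.02),
                 C4aOOH = c(F_ex380 = 0.02, F_ex450 = 0.02),
                 C4aOH  = c(F_ex380 = 1.00, F_ex450 = 0.30),
                 FAD    = c(F_ex380 = 0.02, F_ex450 = 0.02),
                 none   = c(F_ex380 = 0.00, F_ex450 = 0.00))
  }
  if (!all(classes %in% rownames(eps)) || !all(classes %in% rownames(phi))) {
    halokin_error("optical model needs coefficients for every chromophore class",
                  "halokin_config_error")
  }
  if (any(eps < 0) || any(phi < 0) || path_length <= 0) {
    halokin_error("optical coefficients must be >= 0 and path_length > 0",
                  "halokin_config_error")
  }
  fl <- phi[setdiff(classes, "none"), , drop = FALSE]
  if (any(fl["C4aOH", ] <= apply(fl[rownames(fl) != "C4aOH", , drop = FALSE], 2, max))) {
    halokin_error("C4aOH must be the brightest flavin species in every fluorescence channel",
                  "halokin_config_error")
  }
  structure(list(path_length = path_length, eps = eps, phi = phi),
            class = "optical_model")
}

#' Construct a detector trace object
#'
#' @param time_s Times, s.
#' @param value Signal values (absorbance units or arbitrary fluorescence
#'   units).
#' @param channel One of `"A380"`, `"A450"`, `"F_ex380"`, `"F_ex450"`.
#' @return A `kin_trace` data frame with columns `time_s`, `value`.
#' @export
kin_trace <- function(time_s, value, channel) {
  if (!channel %in% .optics_channels) {
    halokin_error(sprintf("unknown channel '%s'", channel),
                  "halokin_validation_error")
  }
  if (length(time_s) != length(value) || any(!is.finite(value))) {
    halokin_error("trace values must be finite and match the grid length",
                  "halokin_validation_error")
  }
  structure(data.frame(time_s = time_s, value = value),
            class = c("kin_trace", "data.frame"), channel = channel)
}

#' Beer-Lambert / fluorescence readout of a species time course
#'
#' `signal(t) = sum_s coeff(s, channel) * conc_s(t) * path_length`.
#' Absorbance uses eps (mM^-1 cm^-1) on µM concentrations (divided by
#' 1000); fluorescence uses the per-µM brightness without the path factor
#' (arbitrary units, never comparable across detector settings).
#'
#' @param tc A `species_timecourse` from [simulate_scheme()].
#' @param optics An [optical_model()].
#' @param channel Detector channel, see [kin_trace()].
#' @return A `kin_trace`.
#' @export
species_to_trace <- function(tc, optics = optical_model(), channel) {
  stopifnot(inherits(tc, "species_timecourse"),
            inherits(optics, "optical_model"))
  if (!channel %in% .optics_channels) {
    halokin_error(sprintf("unknown channel '%s'", channel),
                  "halokin_validation_error")
  }
  df <- as.data.frame(tc)
  species <- setdiff(names(df), "time_s")
  missing <- species[!species %in% names(.chromophore_class)]
  if (length(missing)) {
    halokin_error(sprintf("no optical coefficient for species: %s",
                          paste(missing, collapse = ", ")),
                  "halokin_config_error")
  }
  cls <- .chromophore_class[species]
  is_abs <- channel %in% c("A380", "A450")
  tab <- if (is_abs) optics$eps else optics$phi
  coeff <- tab[cls, channel]
  conc <- as.matrix(df[, species, drop = FALSE])
  sig <- drop(conc %*% coeff)
  if (is_abs) sig <- sig / 1000 * optics$path_length
  kin_trace(df$time_s, sig, channel)
}

#' Write / read detector traces as long-format CSV
#'
#' Long format: columns `time_s`, `value`, `channel`. [read_traces()] also
#' accepts per-channel files without the `channel` column.
#'
#' @param traces A `kin_trace` or list of them.
#' @param path CSV path.
#' @return `write_traces()` returns `path` invisibly; [read_traces()] a
#'   named list of `kin_trace` objects.
#' @export
write_traces <- function(traces, path) {
  if (inherits(traces, "kin_trace")) traces <- list(traces)
  long <- do.call(rbind, lapply(traces, function(tr) {
    data.frame(time_s = tr$time_s, value = tr$value,
               channel = attr(tr, "channel"))
  }))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  df <- utils::read.csv(path)
  if (!"channel" %in% names(df)) df$channel <- "A380"
  split_df <- split(df, df$channel)
  lapply(split_df, function(d) kin_trace(d$time_s, d$value, d$channel[1]))
}
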