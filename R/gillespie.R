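#' Stochastic simulation of the halogenase scheme (Gillespie direct method)
#'
#' Exact-trajectory stochastic oracle over the same reaction network as
#' [simulate_scheme()]. Concentrations (µM) are converted to integer
#' molecule counts through `scale` (molecules per µM); bimolecular
#' propensities are divided by the same factor. Branch-count fractions
#' converge to the deterministic [branching_fractions()] as counts grow.
#'
#' @inheritParams simulate_scheme
#' @param t_end End time, s.
#' @param seed Integer RNG seed; the same seed reproduces the event log
#'   byte for byte.
#' @param scale Molecules per µM of concentration (default 1).
#' @return List with `events` (data frame `time`, `reaction`), `counts`
#'   (final species counts) and `scale`.
#' @export
gillespie_scheme <- function(params, init, halide, t_end, seed, scale = 1,
                             mode = c("rapid_equilibrium", "explicit"),
                             kon = NULL) {
  stopifnot(inherits(params, "rate_parameters"),
            inherits(init, "initial_conditions"))
  mode <- match.arg(mode)
  if (!is.numeric(t_end) || t_end <= 0) {
    halokin_error("'t_end' must be positive", "halokin_validation_error")
  }
  rxn <- build_reactions(params, halide_id(halide), init,
                         mode = mode, kon = kon)
  counts <- round(init$y0 * scale)
  n_rxn <- length(rxn)

  with_seed(seed, {
    t_now <- 0
    cap <- 1024L
    n_ev <- 0L
    ev_time <- numeric(cap)
    ev_rxn <- integer(cap)
    repeat {
      a <- vapply(rxn, function(r) {
        p <- r$rate * prod(counts[r$order])
        if (length(r$order) == 2L) p <- p / scale
        p
      }, numeric(1))
      a0 <- sum(a)
      if (a0 <= 0) break
      tau <- stats::rexp(1, rate = a0)
      if (t_now + tau > t_end) break
      t_now <- t_now + tau
      j <- sample.int(n_rxn, 1L, prob = a)
      d <- rxn[[j]]$d
      counts[names(d)] <- counts[names(d)] + d
      n_ev <- n_ev + 1L
      if (n_ev > cap) {
        cap <- cap * 2L
        length(ev_time) <- cap
        length(ev_rxn) <- cap
      }
      ev_time[n_ev] <- t_now
      ev_rxn[n_ev] <- j
    }
    rxn_names <- vapply(rxn, `[[`, character(1), "name")
    list(events = data.frame(time = ev_time[seq_len(n_ev)],
                             reaction = rxn_names[ev_rxn[seq_len(n_ev)]],
                             stringsAsFactors = FALSE),
         counts = counts, scale = scale)
  })
}
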