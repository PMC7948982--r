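# Shared fixtures: truth configurations and small helpers used across the
# suite. All synthetic data are built in code at test time.

truths <- thal_truths()

rel_err <- function(x, ref) abs(x - ref) / abs(ref)

# Minimal parameter set with only the chain bound-FADH- -> C4aOOH -> FAD
# active (the analytically solvable sub-scheme).
chain_params <- function(k_form = 16.52, k_unc = 0.41) {
  rate_parameters(k_bind_flavin = 0, k_inact = 0, k_ox = k_form / 128,
                  k_unc = k_unc, k_capture = 0, k_leak = 0)
}

chain_init <- function(A0 = 15) {
  initial_conditions(E_FADH = A0, O2 = 128, X_conc = 0)
}

# Independent brute-force oracle for the saturation fit: exhaustive
# 2-D grid search of the residual sum of squares over (Kd, k).
grid_search_saturation <- function(conc, kobs, n = 200,
                                   Kd_range = c(1e-3, 1e2),
                                   k_range = c(1e-2, 1e2)) {
  Kds <- exp(seq(log(Kd_range[1]), log(Kd_range[2]), length.out = n))
  ks <- exp(seq(log(k_range[1]), log(k_range[2]), length.out = n))
  best <- c(Inf, NA, NA)
  for (Kd in Kds) {
    u <- conc / (Kd + conc)
    for (k in ks) {
      rss <- sum((kobs - k * u)^2)
      if (rss < best[1]) best <- c(rss, Kd, k)
    }
  }
  list(Kd = best[2], k = best[3],
       cell_Kd = log(Kds[2]) - log(Kds[1]),
       cell_k = log(ks[2]) - log(ks[1]))
}
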