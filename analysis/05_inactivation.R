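#!/usr/bin/env Rscript
# Double-mixing inactivation analysis: the first-phase 380-nm amplitude
# decays with anaerobic age time as the active enzyme:FADH- complex
# isomerizes to its dead-end form. Generates the amplitude-vs-age series
# and refits the single-exponential decay.

suppressPackageStartupMessages(library(halokin))
dir.create("results", showWarnings = FALSE)
tr <- thal_truths()$inactivation

ser0 <- generate_inactivation_series(tr$k_inact, tr$ages, A0 = tr$A0,
                                     noise = noise_model(0))
fit0 <- fit_inactivation(ser0)
sern <- generate_inactivation_series(tr$k_inact, tr$ages, A0 = tr$A0,
                                     noise = noise_model(0.02, seed = 3))
fitn <- fit_inactivation(sern)

cat(sprintf("isomerization rate: truth %.3f s^-1, noise-free fit %.4f, 2%%-noise fit %.3f +/- %.3f\n",
            tr$k_inact, fit0$k_inact, fitn$k_inact, fitn$se_k_inact))
cat(sprintf("shortest age (%.2f s) keeps %.0f%% of the amplitude; 30 s keeps %.1f%%\n",
            tr$ages[1], 100 * ser0$amplitude[1] / tr$A0,
            100 * ser0$amplitude[length(tr$ages)] / tr$A0))

write.csv(cbind(ser0, amplitude_noisy = sern$amplitude),
          "results/inactivation_series.csv", row.names = FALSE)
write.csv(data.frame(k_inact_true = tr$k_inact,
                     k_inact_fit = fit0$k_inact,
                     k_inact_fit_noisy = fitn$k_inact,
                     se = fitn$se_k_inact),
          "results/inactivation_fit.csv", row.names = FALSE)
cat("inactivation tables written to results/\n")
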