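#!/usr/bin/env Rscript
# Synthetic recovery study: can the pipeline recover a known effective dose?
#
# A phenomenological dose field (two-exponential axial profile, ~40:1
# in-field/out-of-field spread) defines the truth; 200 seeded replicates of
# six noisy exposures per dosimeter (relative noise 2% + 15.5%/sqrt(D)) are
# pushed through the full pipeline. Reported: bias of the estimate, its
# spread against the analytic standard error, and coverage of the k=2
# expanded-uncertainty interval.

library(ankledose)

ph <- default_ankle_phantom()
fr <- default_ankle_fractions()
w <- default_icrp_weights()
prot <- default_protocols()$cbct_hires_12x8

truth <- generate_dose_field(prot, ph, dose_field_params())
E_true <- ground_truth_effective_dose(truth, ph, fr, w)$E_uSv
se <- effective_dose_se(truth, ph, fr, w)
nm <- noise_model()

rec <- t(vapply(1:200, function(seed) {
  r <- sample_readings(truth, nm, 6, seed = seed)
  est <- do.call(rbind, lapply(split(r, r$dosimeter_no), function(g) {
    e <- mean_dose(g$dose_mGy)
    e$dosimeter_no <- g$dosimeter_no[1]
    class(e) <- "data.frame"
    e
  }))
  b <- uncertainty_budget(est[order(est$dosimeter_no), ], ph, fr, w)
  c(seed = seed, E_hat = b$effective_dose$E_uSv, U_pct = b$expanded_pct)
}, numeric(3)))
rec <- as.data.frame(rec)

dir.create("results", showWarnings = FALSE)
write.csv(rec, "results/synthetic_recovery.csv", row.names = FALSE)

bias <- mean(rec$E_hat) - E_true
cover <- mean(abs(rec$E_hat - E_true) <= rec$U_pct / 100 * rec$E_hat)
cat(sprintf("E_true = %.3f uSv; analytic SE of one study = %.3f uSv\n", E_true, se))
cat(sprintf("mean(E_hat) = %.3f uSv; bias = %+.3f uSv (%.2f%% of E_true)\n",
            mean(rec$E_hat), bias, 100 * bias / E_true))
cat(sprintf("empirical SD of E_hat = %.3f uSv (analytic %.3f)\n",
            sd(rec$E_hat), se))
cat(sprintf("k=2 interval coverage: %.1f%% (the expanded budget also carries\n",
            100 * cover))
cat("systematic components absent from the simulation, so near-total\n")
cat("coverage of pure reading noise is expected).\n")
cat("Replicates written to results/synthetic_recovery.csv.\n")
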