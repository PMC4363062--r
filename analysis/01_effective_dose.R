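#!/usr/bin/env Rscript
# Effective dose of the bundled high-resolution CBCT ankle study.
#
# Twenty MOSFET point doses (mGy, six exposures each) measured in the
# six-layer ankle phantom are combined into organ equivalent doses
# H_T = w_R * sum f_i D_i and the ICRP-103 effective dose E = sum w_T H_T,
# with muscle and lymphatic nodes as remainder organs (w = 0.12/13 each).

library(ankledose)

res <- run_study(
  study_config(ankledose_example("cbct_hires_doses.csv"),
               protocol = "cbct_hires_12x8"),
  out_dir = "results/cbct_hires")

print(res$effective_dose)
cat(sprintf(
  "\nThe small-FOV high-resolution CBCT scan deposits an effective dose of %.1f uSv.\n",
  res$effective_dose$E_uSv))
cat("Bone surface and bone marrow dominate because the calcaneal-tuberosity\n")
cat("sites carry 4.9% of the whole-body bone surface and the marrow weight\n")
cat("is 0.12; skin, lymphatic nodes and muscle follow.\n")
cat("Report written to results/cbct_hires/.\n")
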