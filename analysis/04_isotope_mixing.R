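#!/usr/bin/env Rscript
# Two-source mixing on the simulated isotope samples: dietary contribution
# of each alga to the consumer, at both stated trophic fractionation
# assumptions (3.4 and 2.4 permil), with percentile-bootstrap intervals.
# The mixed-diet consumer ingests the two foods ~50/50 (see 03) yet the
# mixing model attributes ~92% of assimilated carbon to the diatom:
# ingestion and assimilation are different quantities.

library(daphniafeed)

ds <- read_experiment_csv("results/simulated")
rep <- contribution_report(ds$isotope_samples,
                           source_X_group = "source_S_hantzschii",
                           source_Y_group = "source_C_vulgaris",
                           fractionations_permil = c(3.4, 2.4),
                           n_boot = 2000, seed = 101)
print(rep, row.names = FALSE, digits = 3)
write.csv(rep, "results/mixing.csv", row.names = FALSE, quote = FALSE)

mix <- rep[rep$group == "MIX" & rep$fractionation_permil == 2.4, ]
cat(sprintf("\nAt the generating fractionation (2.4 permil) the MIX consumer's
assimilated carbon splits %d%% S. hantzschii / %d%% C. vulgaris
(95%% CI for the diatom share: %.2f-%.2f).\n",
            mix$pct_X, mix$pct_Y, mix$ci_low, mix$ci_high))
cat("Rows at the mismatched fractionation show the bias an assumed
fractionation off by 1 permil induces: ~1/12 of the source separation here.
Wrote results/mixing.csv\n")
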