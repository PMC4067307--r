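#!/usr/bin/env Rscript
# Statistical analysis of the Phase 3 outcomes.
#
# Competition outcomes: PerMANOVA with SGV, EH and PT as predictors and the
# final relative abundances of the two competitors as the multivariate
# response (999 permutations; the three-way interaction is omitted from the
# reduced model, which keeps main effects and first-order interactions).
# Trait deltas: group means with percentile-bootstrap 95% CIs; the long
# table for external mixed-model fitting is written by 05_phase3_assays.R.

suppressPackageStartupMessages(library(digiprey))
cfg <- default_config()

outcomes <- read_report("results/phase3/competition_outcomes.csv")
# response: final shares of the two competitors; factors describe the "a"
# competitor's history (the "b" share is 1 - a, carrying the anticorrelation)
resp <- cbind(share_a = outcomes$final_share_a,
              share_b = 1 - outcomes$final_share_a)
fac <- data.frame(
  SGV = sub("^.*:", "", outcomes$a_treatment),
  EH = sub(":.*$", "", outcomes$a_treatment),
  PT = outcomes$pt
)
set.seed(701)
res <- permanova(resp, fac,
                 terms = c("SGV", "EH", "PT", "SGV:EH", "SGV:PT", "EH:PT"),
                 n_perm = 999)
print(res)
write_report(res$table, "results/phase3/permanova.csv", cfg)

deltas <- read_report("results/phase3/trait_deltas.csv")
summ <- summarize_deltas(deltas, grouping = c("eh", "sgv", "pt"),
                         vars = c("d_moves", "d_turns", "d_looks",
                                  "d_total", "d_attacks_received"),
                         n_boot = 2000)
cat("\ntrait-delta group means (95% bootstrap CI):\n")
print(summ[summ$variable == "d_looks", ], digits = 3)
write_report(summ, "results/phase3/trait_delta_summary.csv", cfg)

att <- summarize_deltas(deltas[deltas$pt == "present", ],
                        grouping = "eh", vars = "d_attacks_received",
                        n_boot = 2000)
cat("\nchange in attacks received (predators present), by EH:\n")
print(att, digits = 3)
cat("\nwrote results/phase3/permanova.csv, trait_delta_summary.csv\n")
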