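#!/usr/bin/env Rscript
# Step 3: run every behavioral analysis against the score table -- QC filter,
# treatment count model, percent change, Hotelling choice tests with
# acceptability-weighted nulls, choice odds ratios, exact olfactometer tests,
# and the PD/PS predictor regressions -- then repeat with phytotoxic
# treatments excluded (the sensitivity re-analysis).

suppressMessages(library(repelscore))

sc <- utils::read.csv("results/score_table.csv")
nochoice <- utils::read.csv("results/synthetic/nochoice.csv")
choice <- utils::read.csv("results/synthetic/choice.csv")
olf <- utils::read.csv("results/synthetic/olfactometer.csv")
phyto <- utils::read.csv("results/synthetic/treatments.csv")

res <- run_behavior(sc, nochoice, choice, olf, phytotoxic = phyto,
                    out_dir = "results/behavior")
cat("Full analysis (results/behavior/):\n")
print(res)

cat(sprintf("\nWeek blocks dropped by the <5-larvae control QC: %d of %d\n",
            sum(res$qc$report$dropped), nrow(res$qc$report)))
cat(sprintf("Treatments with >90%% larval reduction: %s\n",
            paste(res$percent_change$treatment[res$percent_change$percent_change > 90],
                  collapse = ", ")))
sep <- res$choice_tests$treatment[res$choice_tests$separation]
if (length(sep) > 0)
  cat(sprintf("Choice tests with complete separation (unbounded OR): %s\n",
              paste(sep, collapse = ", ")))

res2 <- run_behavior(sc, nochoice, choice, olf, phytotoxic = phyto,
                     exclude_phytotoxic = TRUE,
                     out_dir = "results/behavior_nophyto")
cat(sprintf("\nRe-analysis excluding %d phytotoxic treatment(s): %s\n",
            length(res2$excluded_treatments),
            paste(res2$excluded_treatments, collapse = ", ")))
cat("Regression summary with phytotoxic treatments removed:\n")
print(res2$regression_summary, digits = 4)
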