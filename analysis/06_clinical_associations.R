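#!/usr/bin/env Rscript
# Stage 6: clinical associations.
#
# Spearman associations of the units that survived the group comparisons
# with illness duration, symptom scores and antipsychotic dose (within the
# patient group) and cognitive scores (within each group), BH-corrected
# per clinical variable. Because illness duration is generated as a
# near-deterministic function of age, raw correlations with duration are
# also re-examined after rank-based age adjustment — the collinearity that
# makes duration effects hard to separate from aging.

library(mscortex)
dir.create("results", showWarnings = FALSE)

cohort <- generate_cohort(demo_cohort_config(seed = 42L))
meta <- cohort_metadata(cohort)
ms <- cohort_ms_matrices(cohort)
summaries <- cohort_ms_summaries(ms, cohort$atlas)
regional_cmp <- run_family(t(summaries$regional), meta, "regional_mean_ms")
sig_units <- regional_cmp$unit_id[regional_cmp$significant]
cat(sprintf("Testing %d significant regions against clinical variables\n",
            length(sig_units)))

scz <- which(meta$group == "SCZ")
units <- t(summaries$regional[, sig_units, drop = FALSE])
rows <- list()
for (v in c("illness_duration", "panss_positive", "panss_negative",
            "antipsychotic_dose")) {
  clin <- meta[[v]][scz]
  if (sum(complete.cases(clin)) < 4) next
  for (mth in c("raw", "age_adjusted")) {
    tab <- run_association_family(units[, scz, drop = FALSE], clin,
                                  variable_name = v, age = meta$age[scz],
                                  method = mth)
    tab$method <- mth
    rows[[paste(v, mth)]] <- tab
    n_sig <- sum(tab$significant)
    if (mth == "raw" || n_sig > 0) {
      cat(sprintf("  %-20s (%-12s): %d/%d significant at q < 0.05, max |rho| = %.2f (n = %d)\n",
                  v, mth, n_sig, nrow(tab), max(abs(tab$rho)), tab$n_used[1]))
    }
  }
}
assoc <- do.call(rbind, rows)
write.csv(assoc, "results/06_clinical_associations.csv", row.names = FALSE)
cat("Wrote results/06_clinical_associations.csv\n")
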