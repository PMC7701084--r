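#!/usr/bin/env Rscript

# Patient-level analysis: does the mean 12-month log10 TTV load differ by
# fixed clinical characteristics? Categorical covariates (gender, disease,
# donation type, DSA, regimen class, dual vs triple immunosuppression) by
# one-way ANOVA; continuous ones (ages, post-transplant time, HLA mismatch
# count) by simple linear regression. No multiple-testing adjustment: the
# p-values are descriptive.

suppressPackageStartupMessages(library(ttvload))

cohort <- read_cohort("results/cohort/patients.csv",
                      "results/cohort/visits.csv")
res <- run_association_scan(cohort)

fitted <- Filter(function(r) inherits(r, "ttv_association"), res)
for (r in fitted) print(r)
skipped <- Filter(function(r) inherits(r, "ttv_skipped"), res)
for (r in skipped) cat(r$variable, "not tested:", r$message, "\n")

sig <- names(Filter(function(r) r$p_value < 0.05, fitted))
cat("\nbelow the 0.05 descriptive threshold:",
    if (length(sig)) paste(sig, collapse = ", ") else "none", "\n")

write_results(unname(fitted), "results/tables")
cat("wrote results/tables/table2_associations.csv\n")
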