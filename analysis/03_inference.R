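#!/usr/bin/env Rscript
# Permutation inference: one-way permutation ANOVA on the distance matrix
# per factor, plus pairwise central-tendency post hoc tests with Bonferroni
# correction, aggregated (mean +/- SD) over random resolutions of the
# polymorphism in both matrices.

source("analysis/00_config.R")

res <- suppressWarnings(run_pipeline(study_config("test")))

cat("\n--- permutation ANOVA per factor (results/tests_anova.tsv) ---\n")
for (f in names(res$test)) print(res$test[[f]]$anova)

cat("\n--- post hoc pairwise tests, climate (results/tests_posthoc.tsv) ---\n")
print(res$test$climate$posthoc$pairs, digits = 3, row.names = FALSE)
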