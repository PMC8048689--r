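#!/usr/bin/env Rscript
# Disparity contrast between the two clusters of associated categories
# found in 04 (membership = intersection across constrained factors, union
# of categories within a factor), tested with a central-tendency
# permutation test.

source("analysis/00_config.R")

res <- suppressWarnings(run_pipeline(study_config("cluster-contrast")))

cat("\n--- cluster disparity contrast (results/cluster_contrast.json) ---\n")
print(res$cluster_contrast)
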