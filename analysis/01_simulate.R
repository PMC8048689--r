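#!/usr/bin/env Rscript
# Generate the study dataset and write it to results/inputs/ alongside a
# manifest of the generating truth (used by the recovery checks).

source("analysis/00_config.R")

res <- run_pipeline(study_config("simulate"))
ds <- gen_dataset(study_spec())

cat("\n--- simulated study dataset ---\n")
print(ds$m)
print(ds$ft)
cat(sprintf("occurrences: %d records for %d species\n",
            nrow(ds$occ), length(unique(ds$occ$species))))
cat("files written under", file.path(OUT_DIR, "inputs"), "\n")
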