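#!/usr/bin/env Rscript
# Associations among factor categories: chi-squared tests per factor pair
# (polar merged into cold, root parasites excluded, as is standard for
# sparse categories), Pearson-residual strength, significant-edge list and
# the NMDS association-network embedding.

source("analysis/00_config.R")

res <- suppressWarnings(run_pipeline(study_config("associations")))

cat("\n--- chi-squared tests per factor pair (results/associations.tsv) ---\n")
print(association_table(res$associations$scan), digits = 4, row.names = FALSE)

edges <- res$associations$edges
cat(sprintf("\n%d significant association edges (|PR| >= 2): %d positive, %d negative\n",
            nrow(edges), sum(edges$sign > 0), sum(edges$sign < 0)))
cat("\npositive-association clusters (connected components):\n")
print(network_clusters(edges))
cat(sprintf("\nNMDS stress: %.4f (coordinates in results/nmds_coordinates.tsv)\n",
            res$associations$embedding$stress))
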