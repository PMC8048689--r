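#!/usr/bin/env Rscript
# Descriptive disparity: mean pairwise dissimilarity (D-bar +/- SD) for
# every category of every ecological factor. Multi-membership species count
# in each of their categories here (tests in 03 resolve them instead).

source("analysis/00_config.R")

res <- suppressWarnings(run_pipeline(study_config("disparity")))
tab <- res$disparity

cat("\n--- disparity by factor category (results/disparity.tsv) ---\n")
print(tab, digits = 3, row.names = FALSE)

clim <- tab[tab$factor == "climate", ]
best <- clim[which.max(clim$mean), ]
cat(sprintf("\nhighest climate-category disparity: %s (D-bar = %.3f +/- %.3f, n = %d)\n",
            best$category, best$mean, best$sd, best$n_taxa))
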