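# Shared configuration for the numbered analysis drivers.
# The study dataset is synthetic but structurally matched to a large floral
# dataset: 380 taxa x 36 mixed characters (13.4% missing, 2.2% polymorphic),
# four ecological factors (3.6% missing, 16.5% multi-valued), a planted
# two-block ecology (tropical forest trees of Africa/South America vs
# temperate-to-polar herbs/shrubs of open or wet habitats in North
# America/Eurasia), elevated trait dispersion for tropical species, and
# climate-linked latitudinal ranges.

library(floradisp)

MASTER_SEED <- 20260928L
OUT_DIR <- "results"

study_spec <- function() synth_spec(seed = MASTER_SEED)

study_config <- function(stages) {
  run_config(study_spec(), stages = stages, out_dir = OUT_DIR,
             seed = MASTER_SEED,
             n_perm = 999, n_resolutions = 10, n_perm_contrast = 9999,
             n_null_draws = 1000,
             merges = c(polar = "cold"), exclusions = "root parasites")
}
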