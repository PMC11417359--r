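# Shared settings for the analysis scripts.
#
# The narrative run uses a half-scale panel (300 genes, 300 cells per
# sample) so the whole workflow replays in a few minutes; the acceptance
# script (scripts/acceptance.R) runs the full default conditions.

library(velotrend)

SEED <- 20240101L
RESULTS <- "results"
CACHE <- file.path("scratch", "analysis_cache")

an_genes <- function() default_kinetic_genes(
  n_repression = 120, n_induction = 105, n_steady = 75,
  frozen_repression = 40, frozen_induction = 20, seed = SEED)

an_sim_config <- function() simulation_config(
  n_cells_per_sample = 300, seed = SEED + 1L)

dir.create(RESULTS, showWarnings = FALSE)
dir.create(CACHE, recursive = TRUE, showWarnings = FALSE)

cached <- function(name, expr) {
  path <- file.path(CACHE, paste0(name, ".rds"))
  if (file.exists(path)) return(readRDS(path))
  val <- expr
  saveRDS(val, path)
  val
}

tsv <- function(d, name) {
  utils::write.table(d, file.path(RESULTS, name), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  message("wrote ", file.path(RESULTS, name))
}
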