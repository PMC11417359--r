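#!/usr/bin/env Rscript
# Collect the stage tables into one machine-readable report.

source("analysis/00_config.R")

read_tab <- function(name) utils::read.delim(file.path(RESULTS, name))

cls <- read_tab("classification.tsv")
drv <- read_tab("drivers.tsv")
term <- read_tab("terminal_scores_ko.tsv")
ov <- read_tab("deg_overlap.tsv")
calls <- read_tab("trend_calls.tsv")

report <- list(
  n_driver_genes = nrow(drv),
  n_targets_classified = sum(cls$count),
  classification = cls,
  terminal_cluster = term$cluster[which.max(term$terminal_score)],
  deg_overlap = ov,
  config = list(seed = SEED, n_genes = 300, n_cells_per_sample = 300))
stopifnot(sum(cls$count) == nrow(calls))   # report audits its sources

jsonlite::write_json(report, file.path(RESULTS, "report.json"),
                     auto_unbox = TRUE, digits = NA)
message("wrote ", file.path(RESULTS, "report.json"))
message(sprintf(
  "summary: %d drivers; %d targets classified (%s); terminal cluster %s",
  nrow(drv), sum(cls$count),
  paste(sprintf("%s %d", cls$label, cls$count), collapse = ", "),
  term$cluster[which.max(term$terminal_score)]))
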