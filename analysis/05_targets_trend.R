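#!/usr/bin/env Rscript
# Promoter binding: annotate peaks, scan the GAA-family motif grammar,
# intersect bound genes with drivers (driver-gene targets), and classify
# each target's trend change between samples with the Mann-Kendall /
# slope-ratio rule.

source("analysis/00_config.R")

pair_qc <- cached("pair_qc", stop("run 02_qc_expression.R first"))
genome <- cached("genome", stop("run 01_simulate_data.R first"))
fits_wt <- cached("fits_wt", stop("run 03_fit_kinetics.R first"))
times <- readRDS(file.path(CACHE, "times.rds"))
wt <- subset_pair(pair_qc, "WT")
ko <- subset_pair(pair_qc, "KO")

ann <- annotate_peaks(genome$peaks, genome$gene_models, genome$tss_records)
tsv(ann, "peak_annotations.tsv")
fr <- category_fractions(ann)
message("peak category fractions:")
print(round(fr, 4))

hept <- motif_pattern("heptamer", "HRGAAYV")
hits <- scan_motif(genome$contigs[["chrS"]], hept)
write_bed_hits(hits, "chrS", file.path(RESULTS, "heptamer_hits.bed"))
hse <- detect_hse(genome$contigs[["chrS"]])
tsv(hse, "hse_hits.tsv")
message(sprintf("%d heptamer windows, %d heat-shock elements on the toy contig",
                nrow(hits), nrow(hse)))

drivers <- select_driver_genes(fits_wt)
bound <- peaks_to_genes(ann)
dgt <- overlap_driver_targets(bound, drivers$gene_id)
message(sprintf("bound genes: %d, drivers: %d, driver-gene targets: %d",
                dgt$n_bound, dgt$n_driver, dgt$n_overlap))

dgt_drivers <- drivers[drivers$gene_id %in% dgt$dgt, ]
calls <- trend_calls(size_normalize(wt$unspliced),
                     size_normalize(ko$unspliced),
                     times$time_wt, times$time_ko, dgt_drivers)
tsv(calls, "trend_calls.tsv")
cls <- summarize_classification(calls)
tsv(cls, "classification.tsv")
message(sprintf("three-way classification of %d targets:",
                attr(cls, "total")))
print(cls)

# how the calls line up with the generator's planted truth
gm <- pair_qc$gene_meta
truth <- ifelse(gm$ko_frozen & gm$gene_class == "repression",
                "frozen_repression",
                ifelse(gm$ko_frozen & gm$gene_class == "induction",
                       "frozen_induction", gm$gene_class))
confusion <- table(truth = truth[match(calls$gene_id, gm$gene_id)],
                   call = calls$label)
print(confusion)
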