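#!/usr/bin/env Rscript
# Cell QC, highly-variable genes, pseudobulk cluster correlation and the
# differential-expression / overlap accounting between the knockout
# arrest cluster and the normal stages.

source("analysis/00_config.R")

pair <- cached("pair", stop("run 01_simulate_data.R first"))
keep <- qc_filter(pair$cell_meta)
message(sprintf("QC: %d of %d cells survive (bounds 200 < genes < 8500, mito < 20%%)",
                sum(keep), length(keep)))
pair_qc <- cached("pair_qc", subset_pair(pair, cells = keep))

norm <- log_normalize(pair_qc$spliced + pair_qc$unspliced)
hvg <- select_hvg(norm, n = 100)
tsv(data.frame(gene_id = hvg), "highly_variable_genes.tsv")

cc <- suppressWarnings(pseudobulk_correlation(pair_qc, n_top = 200))
tsv(data.frame(cluster = rownames(cc), round(cc, 3)),
    "pseudobulk_spearman.tsv")
message("pseudobulk Spearman: matching stages correlate across samples")

meta <- pair_qc$cell_meta
norm_lin <- size_normalize(pair_qc$spliced + pair_qc$unspliced)
grp <- function(s, cl) norm_lin[meta$sample == s & meta$cluster == cl, ,
                                drop = FALSE]
de_plike <- differential_expression(grp("KO", "P-like"), grp("KO", "eP"))
de_mp <- differential_expression(grp("WT", "mP"), grp("WT", "eP"))
tsv(de_plike, "deg_plike_vs_eP.tsv")
tsv(de_mp, "deg_mP_vs_eP.tsv")

ov <- overlap_fractions(de_plike$gene_id[de_plike$direction == "up"],
                        de_mp$gene_id[de_mp$direction == "up"],
                        de_plike$gene_id[de_plike$direction == "down"],
                        de_mp$gene_id[de_mp$direction == "down"])
tsv(ov, "deg_overlap.tsv")
message("DEG overlap between the arrest-vs-eP and mP-vs-eP comparisons:")
print(ov)
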