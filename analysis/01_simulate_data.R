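#!/usr/bin/env Rscript
# Simulate the two-sample spliced/unspliced dataset and the toy genome.
#
# The wild-type sample follows two-state kinetics along a latent time on
# [0,1]; the knockout-like sample stalls at the arrest time, with frozen
# repression targets transcribing ON indefinitely and frozen induction
# targets never switching on. A minority of genes carry promoter peaks
# with planted GAA-family motifs.

source("analysis/00_config.R")

genes <- an_genes()
cfg <- an_sim_config()
pair <- cached("pair", simulate_dataset(genes, cfg))

gene_ids <- pair$gene_meta$gene_id
set.seed(SEED + 2L)
bound <- c(sample(gene_ids[pair$gene_meta$gene_class != "steady"], 40),
           sample(gene_ids[pair$gene_meta$gene_class == "steady"], 15))
genome <- cached("genome", simulate_genome(genes, motif_spec(bound),
                                           seed = SEED + 3L))

write_pair(pair, file.path(RESULTS, "counts"))
write_genome(genome, file.path(RESULTS, "genome"))

message(sprintf("simulated %d cells x %d genes (%d bound genes planted)",
                nrow(pair$spliced), ncol(pair$spliced), length(bound)))
print(table(pair$cell_meta$sample, pair$cell_meta$cluster))
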