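#!/usr/bin/env Rscript
# RNA velocity field, cell-cell transition Markov chain, terminal-state
# scores and the cluster-graph abstraction for the knockout sample. The
# arrest cluster should carry the highest terminal-state score: the
# random walk driven by the velocity field accumulates there.

source("analysis/00_config.R")

pair_qc <- cached("pair_qc", stop("run 02_qc_expression.R first"))
ko <- subset_pair(pair_qc, "KO")
mom_ko <- cached("mom_ko", stop("run 03_fit_kinetics.R first"))
fits_wt <- cached("fits_wt", stop("run 03_fit_kinetics.R first"))

# KO velocities use the wild-type-fitted rates (reference manifold) and
# only well-fitted genes: unresolved fits contribute arbitrary rates
vel <- compute_velocity(fits_wt, mom_ko, likelihood_quantile = 0.5)
trans <- velocity_graph(mom_ko, vel)
term <- terminal_states(trans, ko$cell_meta$cluster)
tsv(data.frame(cluster = names(term$cluster_score),
               terminal_score = as.numeric(term$cluster_score)),
    "terminal_scores_ko.tsv")
message("terminal-state score by KO cluster (max should be the arrest state):")
print(term$cluster_score)

cg <- cluster_graph(mom_ko$knn, ko$cell_meta$cluster, trans)
conn <- as.data.frame(as.table(cg$connectivity))
names(conn) <- c("from", "to", "connectivity")
flux <- as.data.frame(as.table(cg$flux))
names(flux) <- c("from", "to", "net_flux")
tsv(merge(conn, flux), "cluster_graph_ko.tsv")
message("cluster connectivity (kNN edges over random expectation):")
print(round(cg$connectivity, 3))
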