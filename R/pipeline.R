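#' Assemble an end-to-end run configuration
#'
#' Bundles every stage's settings with a single master seed; each
#' stochastic stage consumes a sub-seed derived deterministically from
#' it, so a rerun with the same configuration reproduces every output.
#'
#' @param seed master integer seed.
#' @param genes list of gene-panel arguments for
#'   [default_kinetic_genes()] (class sizes and frozen counts).
#' @param sim arguments for [simulation_config()] (the seed is filled in
#'   from the master seed).
#' @param n_bound_drivers,n_bound_nondrivers how many driver /
#'   non-driver genes receive promoter peaks in the toy genome.
#' @param qc a [qc_thresholds()].
#' @param kinetics list: `n_neighbors`, `n_pcs`, `likelihood_threshold`,
#'   `max_iter`, `time_quantile` (contributing-gene cutoff for inferred
#'   cell time).
#' @param trend list: `alpha`, `ratio_threshold`, `gate`.
#' @param annotation list: `proximal`, `upstream` promoter windows (bp).
#' @param out_dir optional directory for stage outputs (NULL = keep in
#'   memory only).
#' @return object of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       genes = list(n_repression = 240, n_induction = 210,
                                    n_steady = 150, frozen_repression = 80,
                                    frozen_induction = 40),
                       sim = list(),
                       n_bound_drivers = 40L,
                       n_bound_nondrivers = 20L,
                       qc = qc_thresholds(),
                       kinetics = list(n_neighbors = 30L, n_pcs = 30L,
                                       likelihood_threshold = 0,
                                       max_iter = 10L,
                                       time_quantile = 0.5),
                       trend = list(alpha = 0.01, ratio_threshold = 4,
                                    gate = "wt"),
                       annotation = list(proximal = 500L, upstream = 2000L),
                       out_dir = NULL) {
  cfg <- structure(
    list(seed = as.integer(seed), genes = genes, sim = sim,
         n_bound_drivers = n_bound_drivers,
         n_bound_nondrivers = n_bound_nondrivers, qc = qc,
         kinetics = kinetics, trend = trend, annotation = annotation,
         out_dir = out_dir),
    class = "run_config")
  v <- validate_config(cfg)
  if (!isTRUE(v)) stop(paste(v, collapse = "; "))
  cfg
}

#' Validate a run configuration
#'
#' Checks every embedded setting's invariants and returns `TRUE` or a
#' character vector of violations with actionable messages.
#'
#' @param cfg a [run_config()] (or a bare list with the same fields).
#' @return `TRUE`, or character vector of violations.
#' @export
validate_config <- function(cfg) {
  msgs <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) msgs <<- c(msgs, msg)
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1L,
      "seed must be a single integer")
  g <- cfg$genes
  for (f in c("n_repression", "n_induction", "n_steady"))
    chk(is.numeric(g[[f]]) && g[[f]] >= 0, paste(f, "must be >= 0"))
  chk(g$frozen_repression <= g$n_repression,
      "frozen_repression exceeds n_repression")
  chk(g$frozen_induction <= g$n_induction,
      "frozen_induction exceeds n_induction")
  chk(inherits(cfg$qc, "qc_thresholds") ||
        (cfg$qc$min_genes < cfg$qc$max_genes),
      "qc: min_genes must be below max_genes")
  sim_full <- try(do.call(simulation_config,
                          c(cfg$sim, list(seed = cfg$seed))), silent = TRUE)
  if (inherits(sim_full, "try-error"))
    msgs <- c(msgs, paste("sim:", attr(sim_full, "condition")$message))
  k <- cfg$kinetics
  chk(k$n_neighbors >= 1, "kinetics: n_neighbors must be >= 1")
  chk(k$likelihood_threshold >= 0 && k$likelihood_threshold <= 1,
      "kinetics: likelihood_threshold must lie in [0, 1]")
  chk(cfg$trend$alpha > 0 && cfg$trend$alpha < 1,
      "trend: alpha must lie in (0, 1)")
  chk(cfg$trend$ratio_threshold > 0,
      "trend: ratio_threshold must be positive")
  chk(cfg$trend$gate %in% c("wt", "ko", "both"),
      "trend: gate must be one of wt/ko/both")
  chk(cfg$annotation$proximal > 0 && cfg$annotation$upstream >
        cfg$annotation$proximal,
      "annotation: upstream window must exceed the proximal half-width")
  if (length(msgs)) msgs else TRUE
}

#' Write / read a run configuration as a YAML file
#' @param cfg a [run_config()].
#' @param path file path.
#' @return `path` (write) or a `run_config` (read).
#' @export
write_run_config <- function(cfg, path) {
  plain <- unclass(cfg)
  plain$qc <- unclass(plain$qc)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$qc <- do.call(qc_thresholds, raw$qc)
  do.call(run_config, raw)
}

sub_seed <- function(seed, stage) {
  # deterministic per-stage sub-seed, kept within 32-bit integer range
  (seed * 101L + stage * 7919L) %% .Machine$integer.max
}

#' Run the full synthetic-study pipeline
#'
#' simulate -> toy genome -> QC -> moments -> kinetic fits -> drivers ->
#' inferred cell time -> velocity / transition chain / terminal states /
#' cluster graph (KO) -> trend classification of driver-gene targets ->
#' DEG overlap accounting -> report. All stage outputs are returned (and
#' written as TSV/MTX/BED under `cfg$out_dir` when set); the report's
#' tables are re-derivable from them.
#'
#' @param cfg a [run_config()].
#' @param quiet suppress per-stage progress messages.
#' @return object of class `run_report` (a list; see Details in the
#'   package vignette).
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()

  say("[1/8] simulating dataset (seed %d)", cfg$seed)
  genes <- do.call(default_kinetic_genes,
                   c(cfg$genes, list(seed = sub_seed(cfg$seed, 1L))))
  sim_cfg <- do.call(simulation_config,
                     c(cfg$sim, list(seed = sub_seed(cfg$seed, 2L))))
  pair <- simulate_dataset(genes, sim_cfg)

  say("[2/8] building toy genome")
  gene_ids <- pair$gene_meta$gene_id
  nonsteady <- gene_ids[pair$gene_meta$gene_class != "steady"]
  steady <- gene_ids[pair$gene_meta$gene_class == "steady"]
  set.seed(sub_seed(cfg$seed, 3L))
  bound <- c(sample(nonsteady, min(cfg$n_bound_drivers, length(nonsteady))),
             sample(steady, min(cfg$n_bound_nondrivers, length(steady))))
  genome <- simulate_genome(genes, motif_spec(bound),
                            seed = sub_seed(cfg$seed, 4L))

  say("[3/8] QC filtering")
  keep <- qc_filter(pair$cell_meta, cfg$qc)
  pair_qc <- subset_pair(pair, cells = keep)

  say("[4/8] moments + kinetic fits (WT)")
  k <- cfg$kinetics
  wt <- subset_pair(pair_qc, "WT")
  ko <- subset_pair(pair_qc, "KO")
  mom_wt <- compute_moments(wt, n_neighbors = k$n_neighbors,
                            n_pcs = k$n_pcs)
  fits_wt <- fit_all_genes(mom_wt, max_iter = k$max_iter)
  drivers <- select_driver_genes(fits_wt,
                                 threshold = k$likelihood_threshold)
  time_wt <- inferred_cell_time(fits_wt,
                                likelihood_quantile = k$time_quantile)

  say("[5/8] KO moments + projection onto the WT manifold")
  mom_ko <- compute_moments(ko, n_neighbors = k$n_neighbors,
                            n_pcs = k$n_pcs)
  # the arrested sample's own fits are dominated by the stalled blob,
  # so all KO quantities derive from the WT-fitted reference manifold:
  # cell times by projection (on unsmoothed values - kNN smoothing
  # leaks neighbouring states into the blob), velocities with the
  # WT-fitted degradation rates
  time_ko <- inferred_cell_time(fits_wt,
                                likelihood_quantile = k$time_quantile,
                                mu = size_normalize(ko$unspliced),
                                ms = size_normalize(ko$spliced))

  say("[6/8] velocity graph, terminal states, cluster graph (KO)")
  vel_ko <- compute_velocity(fits_wt, mom_ko,
                             likelihood_quantile = k$time_quantile)
  trans_ko <- velocity_graph(mom_ko, vel_ko)
  term_ko <- terminal_states(trans_ko, ko$cell_meta$cluster)
  cgraph_ko <- cluster_graph(mom_ko$knn, ko$cell_meta$cluster, trans_ko)

  say("[7/8] peak annotation + trend classification of targets")
  ann <- annotate_peaks(genome$peaks, genome$gene_models,
                        genome$tss_records,
                        proximal = cfg$annotation$proximal,
                        upstream = cfg$annotation$upstream)
  bound_genes <- peaks_to_genes(ann)
  dgt <- overlap_driver_targets(bound_genes, drivers$gene_id)
  dgt_drivers <- drivers[drivers$gene_id %in% dgt$dgt, , drop = FALSE]
  # trend series use size-normalized, unsmoothed unspliced counts: the
  # kNN smoothing behind Mu correlates adjacent cells and would inflate
  # the Mann-Kendall significance
  calls <- trend_calls(size_normalize(wt$unspliced),
                       size_normalize(ko$unspliced), time_wt, time_ko,
                       dgt_drivers, alpha = cfg$trend$alpha,
                       ratio_threshold = cfg$trend$ratio_threshold,
                       gate = cfg$trend$gate)
  classification <- summarize_classification(calls)

  say("[8/8] DEG overlap accounting")
  # linear-scale normalized expression: the rank test is scale-free but
  # the fold change must not be computed on log values
  norm <- size_normalize(pair_qc$spliced + pair_qc$unspliced)
  meta <- pair_qc$cell_meta
  grp <- function(s, cl) norm[meta$sample == s & meta$cluster == cl, ,
                              drop = FALSE]
  arrest <- sim_cfg$arrest_label
  first_cl <- sim_cfg$cluster_labels[1]
  mid_cl <- sim_cfg$cluster_labels[2]
  de_plike <- differential_expression(grp("KO", arrest),
                                      grp("KO", first_cl))
  de_mp <- differential_expression(grp("WT", mid_cl), grp("WT", first_cl))
  overlap <- overlap_fractions(
    de_plike$gene_id[de_plike$direction == "up"],
    de_mp$gene_id[de_mp$direction == "up"],
    de_plike$gene_id[de_plike$direction == "down"],
    de_mp$gene_id[de_mp$direction == "down"])

  report <- structure(list(
    n_cells_simulated = nrow(pair$spliced),
    n_cells_qc = nrow(pair_qc$spliced),
    n_genes = ncol(pair$spliced),
    n_peaks = nrow(genome$peaks),
    n_driver_genes = nrow(drivers),
    n_bound_genes = dgt$n_bound,
    n_dgt = dgt$n_overlap,
    classification = classification,
    category_fractions = category_fractions(ann),
    terminal_cluster_score = term_ko$cluster_score,
    deg_overlap = overlap,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    seed = cfg$seed), class = "run_report")

  out <- list(report = report, pair = pair_qc, genome = genome,
              drivers = drivers, fits_wt = fits_wt,
              time_wt = time_wt, time_ko = time_ko, calls = calls,
              annotations = ann, dgt = dgt, terminal = term_ko,
              cluster_graph = cgraph_ko, de_plike = de_plike,
              de_mp = de_mp)
  if (!is.null(cfg$out_dir)) write_pipeline_outputs(out, cfg$out_dir)
  out
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> seed %d: %d/%d cells after QC, %d genes\n",
              x$seed, x$n_cells_qc, x$n_cells_simulated, x$n_genes))
  cat(sprintf("  drivers: %d  bound genes: %d  DGTs: %d\n",
              x$n_driver_genes, x$n_bound_genes, x$n_dgt))
  cls <- x$classification
  cat(sprintf("  %s: %d (%.1f%%)\n", cls$label, cls$count, cls$percent))
  cat(sprintf("  terminal-state score max in cluster '%s'\n",
              names(which.max(x$terminal_cluster_score))))
  invisible(x)
}

write_pipeline_outputs <- function(out, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_pair(out$pair, file.path(dir, "counts"))
  write_genome(out$genome, file.path(dir, "genome"))
  tsv <- function(d, f) utils::write.table(
    d, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  tsv(out$drivers, "drivers.tsv")
  tsv(out$calls, "trend_calls.tsv")
  tsv(out$annotations, "peak_annotations.tsv")
  tsv(data.frame(cell_id = out$pair$cell_meta$cell_id
                 [out$pair$cell_meta$sample == "WT"],
                 inferred_time = out$time_wt), "cell_time_wt.tsv")
  tsv(data.frame(cell_id = out$pair$cell_meta$cell_id
                 [out$pair$cell_meta$sample == "KO"],
                 inferred_time = out$time_ko), "cell_time_ko.tsv")
  tsv(out$report$classification, "classification.tsv")
  tsv(out$report$deg_overlap, "deg_overlap.tsv")
  rep <- out$report
  rep$classification <- NULL; rep$deg_overlap <- NULL
  rep$terminal_cluster_score <- as.list(rep$terminal_cluster_score)
  rep$category_fractions <- as.list(rep$category_fractions)
  jsonlite::write_json(unclass(rep), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
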