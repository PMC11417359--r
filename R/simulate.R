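#' Simulation configuration for the two-sample kinetics generator
#'
#' Bundles the knobs of the synthetic dataset: number of cells per sample,
#' how latent cell times are drawn on `[0, 1]`, how times map to cluster
#' labels (analogues of early/mid/late pachytene), the time beyond which
#' the knockout sample's perturbed genes are frozen, and the count noise
#' model.
#'
#' @param n_cells_per_sample cells per sample (WT and KO each).
#' @param time_distribution either `"uniform"` or a length-2 numeric of
#'   beta-distribution shapes, for the latent time density on `[0, 1]`.
#' @param cluster_breakpoints strictly increasing thresholds in `(0, 1)`
#'   splitting time into `length(cluster_breakpoints) + 1` stages.
#' @param cluster_labels labels for the stages, one more than breakpoints.
#' @param ko_arrest_time time in `[0, 1]` at which KO progression stalls:
#'   KO cells with later true times keep evolving `ko_frozen` genes on the
#'   perturbed branch but hold every other gene at the arrest-time state,
#'   and are labelled `arrest_label`. The default sits just past the
#'   first-to-second stage boundary, so a small normal second-stage
#'   population remains and no KO cell reaches the third stage.
#' @param arrest_label cluster label of arrested KO cells ("P-like"
#'   analogue).
#' @param noise_model `"poisson"`, `"negative_binomial"`, or `"none"`
#'   (deterministic expectations).
#' @param dispersion negative-binomial dispersion (ignored otherwise);
#'   `size = 1/dispersion` in [stats::rnbinom()] terms.
#' @param capture_efficiency scalar in `(0, 1]` scaling expected molecule
#'   numbers into observed count space.
#' @param round_counts in deterministic mode, whether to round the scaled
#'   expectations to integers (disable for exact closed-form oracles).
#' @param seed integer master seed for the generator.
#' @return object of class `sim_config`.
#' @export
simulation_config <- function(n_cells_per_sample = 500,
                              time_distribution = "uniform",
                              cluster_breakpoints = c(1 / 3, 2 / 3),
                              cluster_labels = c("eP", "mP", "lP"),
                              ko_arrest_time = 0.45,
                              arrest_label = "P-like",
                              noise_model = c("poisson",
                                              "negative_binomial", "none"),
                              dispersion = 0.2,
                              capture_efficiency = 0.5,
                              round_counts = TRUE,
                              seed = 1L) {
  noise_model <- match.arg(noise_model)
  cfg <- structure(
    list(n_cells_per_sample = as.integer(n_cells_per_sample),
         time_distribution = time_distribution,
         cluster_breakpoints = cluster_breakpoints,
         cluster_labels = cluster_labels,
         ko_arrest_time = ko_arrest_time,
         arrest_label = arrest_label,
         noise_model = noise_model,
         dispersion = dispersion,
         capture_efficiency = capture_efficiency,
         round_counts = round_counts,
         seed = as.integer(seed)),
    class = "sim_config")
  msgs <- validate_sim_config(cfg)
  if (length(msgs)) stop(paste(msgs, collapse = "; "))
  cfg
}

validate_sim_config <- function(cfg) {
  msgs <- character()
  if (cfg$n_cells_per_sample <= 0)
    msgs <- c(msgs, "n_cells_per_sample must be positive")
  bp <- cfg$cluster_breakpoints
  if (length(bp) && (any(diff(bp) <= 0) || any(bp <= 0) || any(bp >= 1)))
    msgs <- c(msgs, "cluster_breakpoints must be strictly increasing within (0,1)")
  if (length(cfg$cluster_labels) != length(bp) + 1L)
    msgs <- c(msgs, "need one more cluster label than breakpoints")
  if (cfg$ko_arrest_time < 0 || cfg$ko_arrest_time > 1)
    msgs <- c(msgs, "ko_arrest_time must lie within [0,1]")
  if (cfg$capture_efficiency <= 0 || cfg$capture_efficiency > 1)
    msgs <- c(msgs, "capture_efficiency must be in (0,1]")
  if (cfg$noise_model == "negative_binomial" && cfg$dispersion <= 0)
    msgs <- c(msgs, "negative binomial dispersion must be positive")
  msgs
}

#' Default gene panel for the synthetic study
#'
#' Draws a panel of [kinetic_gene()] records with the study's default class
#' mix: repression genes (ON, then switched off early in the trajectory),
#' induction genes (OFF, switched on mid-trajectory) and steady genes.
#' Perturbed (`ko_frozen`) genes are a minority of the non-steady panel,
#' mirroring a regulator whose direct targets are a small subset of all
#' trajectory drivers.
#'
#' Rates are drawn so that dynamics play out on the unit time window:
#' splicing rates 4-8 per unit time, degradation-to-splicing ratios
#' 0.25-1.5, ON-state unspliced steady levels (alpha/beta) of 2-10
#' molecules.
#'
#' @param n_repression,n_induction,n_steady class sizes.
#' @param frozen_repression,frozen_induction how many genes of each class
#'   are `ko_frozen` (taken from the head of each class).
#' @param seed integer seed.
#' @return list of [kinetic_gene()].
#' @export
default_kinetic_genes <- function(n_repression = 240, n_induction = 210,
                                  n_steady = 150, frozen_repression = 80,
                                  frozen_induction = 40, seed = 1L) {
  stopifnot(frozen_repression <= n_repression,
            frozen_induction <= n_induction)
  set.seed(seed)
  n <- n_repression + n_induction + n_steady
  classes <- rep(c("repression", "induction", "steady"),
                 c(n_repression, n_induction, n_steady))
  frozen <- c(seq_len(n_repression) <= frozen_repression,
              seq_len(n_induction) <= frozen_induction,
              rep(FALSE, n_steady))
  beta <- runif(n, 4, 8)
  ratio <- runif(n, 0.25, 1.5)
  alpha <- beta * runif(n, 2, 10)
  tsw <- ifelse(classes == "repression", runif(n, 0.10, 0.35),
                ifelse(classes == "induction", runif(n, 0.25, 0.60), 0))
  lapply(seq_len(n), function(i) {
    kinetic_gene(sprintf("g%04d", i), alpha[i], beta[i], beta[i] * ratio[i],
                 tsw[i], classes[i], frozen[i])
  })
}

draw_times <- function(n, spec) {
  if (identical(spec, "uniform")) return(runif(n))
  if (is.numeric(spec) && length(spec) == 2L)
    return(rbeta(n, spec[1], spec[2]))
  stop("time_distribution must be \"uniform\" or two beta shapes")
}

#' Map latent times and sample to cluster labels
#'
#' Cluster labels are a deterministic function of the cell's latent time
#' and sample: times are cut at `cluster_breakpoints`; KO cells past
#' `ko_arrest_time` receive the arrest label instead.
#'
#' @param true_time numeric vector in `[0, 1]`.
#' @param sample `"WT"` or `"KO"` per cell (recycled).
#' @param config a [simulation_config()].
#' @return character vector of cluster labels.
#' @export
cluster_from_time <- function(true_time, sample, config) {
  idx <- findInterval(true_time, config$cluster_breakpoints) + 1L
  lab <- config$cluster_labels[idx]
  arrested <- sample == "KO" & true_time > config$ko_arrest_time
  lab[arrested] <- config$arrest_label
  lab
}

expected_matrix <- function(genes, true_time, arrested, arrest_time = 1) {
  n <- length(true_time)
  u <- matrix(0, n, length(genes))
  s <- matrix(0, n, length(genes))
  # arrested cells stall: non-perturbed genes are evaluated at the
  # arrest time (progression stops), perturbed genes follow the frozen
  # branch (repression stays ON, induction never switches ON)
  stalled_time <- ifelse(arrested, pmin(true_time, arrest_time), true_time)
  for (j in seq_along(genes)) {
    g <- genes[[j]]
    if (g$ko_frozen && any(arrested)) {
      norm <- kinetics_expected(g, true_time[!arrested])
      frz <- kinetics_expected(g, true_time[arrested], perturbed = TRUE)
      u[!arrested, j] <- norm$u; s[!arrested, j] <- norm$s
      u[arrested, j] <- frz$u; s[arrested, j] <- frz$s
    } else {
      e <- kinetics_expected(g, stalled_time)
      u[, j] <- e$u; s[, j] <- e$s
    }
  }
  list(u = u, s = s)
}

apply_noise <- function(mat, config) {
  lam <- config$capture_efficiency * mat
  out <- switch(config$noise_model,
    none = if (config$round_counts) round(lam) else lam,
    poisson = matrix(rpois(length(lam), lam), nrow(lam)),
    negative_binomial = matrix(
      rnbinom(length(lam), mu = lam, size = 1 / config$dispersion),
      nrow(lam)))
  dimnames(out) <- dimnames(mat)
  out
}

#' Simulate a paired spliced/unspliced two-sample dataset
#'
#' Generates a WT and a KO sample of cells along a latent time trajectory
#' on `[0, 1]`. WT cells follow each gene's two-state kinetics at their
#' true time. KO cells with `true_time > ko_arrest_time` are arrested:
#' `ko_frozen` repression genes stay ON (never switch off, sustained high
#' nascent transcription), `ko_frozen` induction genes never switch ON,
#' and every other gene is held at its arrest-time state (progression
#' stalls, so arrested cells form a distinct aberrant cluster branching
#' off the normal trajectory). Counts are
#' drawn from the configured noise model around capture-scaled
#' expectations. `genes_detected` and `mito_fraction` in the cell metadata
#' are drawn independently of the kinetics, solely to exercise QC.
#'
#' @param genes list of [kinetic_gene()].
#' @param config a [simulation_config()].
#' @return object of class `cell_matrix_pair`: list with integer (or, in
#'   deterministic mode, numeric) matrices `spliced` and `unspliced`
#'   (cells x genes, identical ordering), `cell_meta` and `gene_meta`
#'   data frames.
#' @export
simulate_dataset <- function(genes, config) {
  if (!length(genes)) stop("empty gene list")
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_cells_per_sample
  gene_ids <- vapply(genes, `[[`, "", "gene_id")

  t_wt <- draw_times(n, config$time_distribution)
  t_ko <- draw_times(n, config$time_distribution)
  arrested <- t_ko > config$ko_arrest_time

  ewt <- expected_matrix(genes, t_wt, rep(FALSE, n))
  eko <- expected_matrix(genes, t_ko, arrested, config$ko_arrest_time)
  u <- rbind(ewt$u, eko$u)
  s <- rbind(ewt$s, eko$s)
  cell_ids <- c(sprintf("WT_%04d", seq_len(n)), sprintf("KO_%04d", seq_len(n)))
  dimnames(u) <- dimnames(s) <- list(cell_ids, gene_ids)

  sample <- rep(c("WT", "KO"), each = n)
  true_time <- c(t_wt, t_ko)
  cell_meta <- data.frame(
    cell_id = cell_ids,
    sample = sample,
    cluster = cluster_from_time(true_time, sample, config),
    true_time = true_time,
    genes_detected = pmax(0L, as.integer(round(rnorm(2 * n, 3000, 900)))),
    mito_fraction = rbeta(2 * n, 2, 30),
    stringsAsFactors = FALSE)
  gene_meta <- data.frame(
    gene_id = gene_ids,
    gene_class = vapply(genes, `[[`, "", "gene_class"),
    ko_frozen = vapply(genes, `[[`, TRUE, "ko_frozen"),
    alpha_on = vapply(genes, `[[`, 1, "alpha_on"),
    beta = vapply(genes, `[[`, 1, "beta"),
    gamma = vapply(genes, `[[`, 1, "gamma"),
    t_switch = vapply(genes, `[[`, 1, "t_switch"),
    stringsAsFactors = FALSE)

  structure(list(spliced = apply_noise(s, config),
                 unspliced = apply_noise(u, config),
                 cell_meta = cell_meta, gene_meta = gene_meta),
            class = "cell_matrix_pair")
}

#' @export
print.cell_matrix_pair <- function(x, ...) {
  cat(sprintf("<cell_matrix_pair> %d cells x %d genes (%s)\n",
              nrow(x$spliced), ncol(x$spliced),
              paste(sprintf("%s: %d", names(table(x$cell_meta$sample)),
                            table(x$cell_meta$sample)), collapse = ", ")))
  invisible(x)
}

#' Subset a cell_matrix_pair to one sample (or arbitrary cells/genes)
#'
#' @param pair a `cell_matrix_pair`.
#' @param cells logical/integer/character index over cells, or a sample
#'   name `"WT"`/`"KO"`.
#' @param genes optional index over genes.
#' @return a `cell_matrix_pair` restricted to the selection.
#' @export
subset_pair <- function(pair, cells = NULL, genes = NULL) {
  stopifnot(inherits(pair, "cell_matrix_pair"))
  if (is.character(cells) && length(cells) == 1L &&
      cells %in% pair$cell_meta$sample)
    cells <- pair$cell_meta$sample == cells
  if (is.null(cells)) cells <- seq_len(nrow(pair$spliced))
  if (is.null(genes)) genes <- seq_len(ncol(pair$spliced))
  structure(list(spliced = pair$spliced[cells, genes, drop = FALSE],
                 unspliced = pair$unspliced[cells, genes, drop = FALSE],
                 cell_meta = pair$cell_meta[cells, , drop = FALSE],
                 gene_meta = pair$gene_meta[genes, , drop = FALSE]),
            class = "cell_matrix_pair")
}
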