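#' Cell QC thresholds
#'
#' Cells survive QC iff `min_genes < genes_detected < max_genes` and
#' `mito_fraction < max_mito_fraction` — i.e. cells with detected gene
#' counts at or below 200, at or above 8500, or mitochondrial fraction at
#' or above 20% are filtered out.
#'
#' @param min_genes,max_genes exclusive bounds on detected genes.
#' @param max_mito_fraction exclusive upper bound on the mitochondrial
#'   fraction.
#' @return object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_genes = 200L, max_genes = 8500L,
                          max_mito_fraction = 0.20) {
  if (min_genes >= max_genes) stop("min_genes must be below max_genes")
  if (max_mito_fraction < 0 || max_mito_fraction > 1)
    stop("max_mito_fraction must lie in [0, 1]")
  structure(list(min_genes = min_genes, max_genes = max_genes,
                 max_mito_fraction = max_mito_fraction),
            class = "qc_thresholds")
}

#' Filter cells on QC thresholds
#'
#' @param cell_meta data.frame with `genes_detected` and `mito_fraction`
#'   (and optionally `cell_id`).
#' @param thresholds a [qc_thresholds()].
#' @return logical vector over the rows of `cell_meta` (TRUE = keep),
#'   named by `cell_id` when present.
#' @export
qc_filter <- function(cell_meta, thresholds = qc_thresholds()) {
  need <- c("genes_detected", "mito_fraction")
  miss <- setdiff(need, names(cell_meta))
  if (length(miss))
    stop("cell_meta lacks column(s): ", paste(miss, collapse = ", "))
  bad <- !stats::complete.cases(cell_meta[need])
  if (any(bad)) {
    who <- if ("cell_id" %in% names(cell_meta))
      cell_meta$cell_id[bad] else which(bad)
    stop("missing QC fields for cell(s): ",
         paste(utils::head(who, 10), collapse = ", "))
  }
  keep <- cell_meta$genes_detected > thresholds$min_genes &
    cell_meta$genes_detected < thresholds$max_genes &
    cell_meta$mito_fraction < thresholds$max_mito_fraction
  if ("cell_id" %in% names(cell_meta)) names(keep) <- cell_meta$cell_id
  keep
}

#' LogNormalize a counts matrix
#'
#' `value = ln(1 + scale * count / cell_total)`, per cell.
#'
#' @param counts cells x genes nonnegative matrix.
#' @param scale scale factor (default 1e4).
#' @return matrix of the same shape.
#' @export
log_normalize <- function(counts, scale = 1e4) {
  tot <- rowSums(counts)
  if (any(tot == 0)) stop("cell(s) with zero total counts")
  log1p(scale * counts / tot)
}

#' Select highly variable genes by dispersion
#'
#' Ranks genes by variance-to-mean dispersion of the (normalized) values
#' and returns the top `n`; ties are broken deterministically by gene id.
#'
#' @param normalized cells x genes matrix (e.g. [log_normalize()]
#'   output) with gene column names.
#' @param n how many genes (default 2000).
#' @return character vector of gene ids.
#' @export
select_hvg <- function(normalized, n = 2000L) {
  if (ncol(normalized) < n)
    stop("fewer genes (", ncol(normalized), ") than requested (", n, ")")
  ids <- colnames(normalized)
  if (is.null(ids)) ids <- sprintf("gene%05d", seq_len(ncol(normalized)))
  mu <- colMeans(normalized)
  v <- apply(normalized, 2L, stats::var)
  disp <- ifelse(mu > 0, v / mu, 0)
  ids[order(-disp, ids)][seq_len(n)]
}

#' Pseudobulk Spearman correlation between cluster profiles
#'
#' Aggregates log-normalized expression to per-(sample, cluster) mean
#' profiles, restricts to the `n_top` genes with the highest standard
#' deviation across the WT cluster profiles, and returns the Spearman
#' correlation matrix between all cluster profiles.
#'
#' @param pair a `cell_matrix_pair` (both samples).
#' @param n_top size of the high-SD gene panel (capped at the gene
#'   count).
#' @param min_cells clusters below this size are dropped with a warning.
#' @return correlation matrix with `sample.cluster` dimnames.
#' @export
pseudobulk_correlation <- function(pair, n_top = 3000L, min_cells = 5L) {
  stopifnot(inherits(pair, "cell_matrix_pair"))
  norm <- log_normalize(pair$spliced + pair$unspliced)
  grp <- interaction(pair$cell_meta$sample, pair$cell_meta$cluster,
                     drop = TRUE, sep = ".")
  sizes <- table(grp)
  small <- names(sizes)[sizes < min_cells]
  if (length(small)) {
    warning("dropping cluster(s) under ", min_cells, " cells: ",
            paste(small, collapse = ", "))
    keep <- !(as.character(grp) %in% small)
    norm <- norm[keep, , drop = FALSE]
    grp <- droplevels(grp[keep])
  }
  prof <- t(vapply(levels(grp), function(g)
    colMeans(norm[grp == g, , drop = FALSE]), numeric(ncol(norm))))
  wt <- grepl("^WT\\.", rownames(prof))
  sds <- if (any(wt)) apply(prof[wt, , drop = FALSE], 2L, stats::sd)
         else apply(prof, 2L, stats::sd)
  panel <- order(-sds)[seq_len(min(n_top, ncol(prof)))]
  stats::cor(t(prof[, panel, drop = FALSE]), method = "spearman")
}

#' Rank-test differential expression between two cell groups
#'
#' Two-sided Wilcoxon rank-sum test per gene on normalized values, with
#' the log2 fold change of mean expression (pseudocount 1). Direction is
#' `up` iff `log2FC > lfc_threshold` and `p < p_threshold`, `down` iff
#' `log2FC < -lfc_threshold` and `p < p_threshold`, otherwise `ns`.
#'
#' The rank test is invariant under monotone transforms of the values,
#' but the fold change is not: pass expression on a linear scale (e.g.
#' size-normalized counts) so `log2((mean_A + 1)/(mean_B + 1))` reads as
#' a fold change of expression, not of log-expression.
#'
#' @param exprA,exprB cells x genes matrices of linear-scale normalized
#'   expression for the two groups (same genes, >= 10 cells each).
#' @param lfc_threshold,p_threshold the calling thresholds.
#' @return data.frame with `gene_id`, `log2_fold_change`, `p_value`,
#'   `direction`.
#' @export
differential_expression <- function(exprA, exprB, lfc_threshold = 1,
                                    p_threshold = 0.01) {
  if (!nrow(exprA) || !nrow(exprB)) stop("empty cell group")
  if (nrow(exprA) < 10L || nrow(exprB) < 10L)
    stop("both groups need at least 10 cells")
  stopifnot(ncol(exprA) == ncol(exprB))
  ids <- colnames(exprA)
  if (is.null(ids)) ids <- sprintf("gene%05d", seq_len(ncol(exprA)))
  res <- lapply(seq_len(ncol(exprA)), function(j) {
    a <- exprA[, j]; b <- exprB[, j]
    lfc <- log2((mean(a) + 1) / (mean(b) + 1))
    p <- if (all(a == a[1]) && all(b == a[1])) 1 else
      suppressWarnings(stats::wilcox.test(a, b)$p.value)
    c(lfc = lfc, p = p)
  })
  lfc <- vapply(res, `[[`, 1, "lfc")
  p <- vapply(res, `[[`, 1, "p")
  direction <- ifelse(p < p_threshold & lfc > lfc_threshold, "up",
               ifelse(p < p_threshold & lfc < -lfc_threshold, "down", "ns"))
  data.frame(gene_id = ids, log2_fold_change = lfc, p_value = p,
             direction = direction, stringsAsFactors = FALSE)
}

#' Overlap table of up/down DEG sets between two comparisons
#'
#' For the up-regulated and down-regulated sets of two comparisons,
#' reports the intersection size and the percentage relative to each
#' denominator (rounded to 1 decimal).
#'
#' @param setA_up,setB_up,setA_down,setB_down character vectors of gene
#'   ids.
#' @return data.frame with one row per (direction, denominator).
#' @export
overlap_fractions <- function(setA_up, setB_up, setA_down, setB_down) {
  row <- function(direction, denom_set, denom_name, inter) {
    n <- length(unique(denom_set))
    data.frame(direction = direction, denominator = denom_name,
               n_overlap = length(inter), n_denominator = n,
               percent = if (n > 0) round(100 * length(inter) / n, 1) else 0,
               stringsAsFactors = FALSE)
  }
  up <- intersect(unique(setA_up), unique(setB_up))
  dn <- intersect(unique(setA_down), unique(setB_down))
  rbind(row("up", setA_up, "A", up), row("up", setB_up, "B", up),
        row("down", setA_down, "A", dn), row("down", setB_down, "B", dn))
}
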