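#' Annotate peaks against TSSs and gene models
#'
#' Each peak is assigned one genomic category from its midpoint with
#' precedence proximal_promoter > promoter > exon > intron > intergenic:
#' proximal promoter = within `[TSS - 500, TSS + 500)` in TSS-strand
#' orientation; promoter = further upstream, to `upstream` bases from the
#' TSS (default 2000); exon / intron from the gene models; intergenic
#' otherwise, assigned to the nearest TSS. Midpoint assignment keeps the
#' categories mutually exclusive and exhaustive, so category fractions are
#' well defined.
#'
#' @param peaks data.frame with `contig`, `start`, `end` (0-based
#'   half-open) and optionally `score`.
#' @param gene_models data.frame of exons: `gene_id`, `contig`, `start`,
#'   `end`, `strand`, `feature`.
#' @param tss_records data.frame: `gene_id`, `contig`, `position`
#'   (0-based), `strand`.
#' @param proximal half-width of the proximal window in bases.
#' @param upstream outer bound of the (non-proximal) promoter class,
#'   bases upstream of the TSS.
#' @return the `peaks` data.frame with added `category` and `gene_id`
#'   columns.
#' @export
annotate_peaks <- function(peaks, gene_models, tss_records,
                           proximal = 500L, upstream = 2000L) {
  stopifnot(all(peaks$start < peaks$end))
  unknown <- setdiff(peaks$contig,
                     union(tss_records$contig, gene_models$contig))
  if (length(unknown))
    stop("peak(s) on unknown contig: ", paste(unique(unknown), collapse = ", "))

  mid <- floor((peaks$start + peaks$end) / 2)
  mid_gr <- GenomicRanges::GRanges(peaks$contig,
                                   IRanges::IRanges(mid + 1L, mid + 1L))
  tss_gr <- GenomicRanges::GRanges(
    tss_records$contig,
    IRanges::IRanges(tss_records$position + 1L, tss_records$position + 1L),
    strand = tss_records$strand)
  prox_gr <- GenomicRanges::promoters(tss_gr, upstream = proximal,
                                      downstream = proximal)
  prom_gr <- GenomicRanges::promoters(tss_gr, upstream = upstream,
                                      downstream = 0L)
  exon_gr <- GenomicRanges::GRanges(
    gene_models$contig,
    IRanges::IRanges(gene_models$start + 1L, gene_models$end))
  # gene body = span of each gene's exons
  spans <- do.call(rbind, lapply(split(gene_models, gene_models$gene_id),
    function(d) data.frame(gene_id = d$gene_id[1], contig = d$contig[1],
                           start = min(d$start), end = max(d$end))))
  span_gr <- GenomicRanges::GRanges(
    spans$contig, IRanges::IRanges(spans$start + 1L, spans$end))

  pick_hit <- function(windows, owners) {
    hits <- GenomicRanges::findOverlaps(mid_gr, windows,
                                        ignore.strand = TRUE)
    got <- rep(NA_character_, length(mid_gr))
    if (length(hits)) {
      q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
      # nearest owning TSS wins on overlap ties
      d <- abs(mid[q] - tss_records$position[match(owners[s],
                                                   tss_records$gene_id)])
      ord <- order(q, d)
      got[q[ord][!duplicated(q[ord])]] <- owners[s[ord]][!duplicated(q[ord])]
    }
    got
  }
  prox_gene <- pick_hit(prox_gr, tss_records$gene_id)
  prom_gene <- pick_hit(prom_gr, tss_records$gene_id)
  exon_gene <- pick_hit(exon_gr, gene_models$gene_id)
  span_gene <- pick_hit(span_gr, spans$gene_id)
  near <- GenomicRanges::nearest(mid_gr, tss_gr, ignore.strand = TRUE)
  near_gene <- tss_records$gene_id[near]

  category <- ifelse(!is.na(prox_gene), "proximal_promoter",
              ifelse(!is.na(prom_gene), "promoter",
              ifelse(!is.na(exon_gene), "exon",
              ifelse(!is.na(span_gene), "intron", "intergenic"))))
  gene_id <- ifelse(!is.na(prox_gene), prox_gene,
             ifelse(!is.na(prom_gene), prom_gene,
             ifelse(!is.na(exon_gene), exon_gene,
             ifelse(!is.na(span_gene), span_gene, near_gene))))
  out <- peaks
  out$category <- factor(category, levels = GENOMIC_CATEGORIES)
  out$gene_id <- gene_id
  out
}

GENOMIC_CATEGORIES <- c("proximal_promoter", "promoter", "exon", "intron",
                        "intergenic")

#' Fraction of peaks per genomic category
#'
#' @param annotations output of [annotate_peaks()].
#' @return named numeric vector over the five categories, summing to 1.
#' @export
category_fractions <- function(annotations) {
  if (!nrow(annotations)) stop("no peaks to summarize")
  tab <- table(factor(annotations$category, levels = GENOMIC_CATEGORIES))
  fr <- as.numeric(tab) / sum(tab)
  names(fr) <- GENOMIC_CATEGORIES
  fr
}

#' Promoter-bound gene set from annotated peaks
#'
#' Genes owning at least one peak in a promoter-class category (by
#' default proximal promoter or promoter). Peak multiplicity per gene is
#' recorded.
#'
#' @param annotations output of [annotate_peaks()].
#' @param categories categories counted as binding.
#' @return data.frame with `gene_id` and `n_peaks`.
#' @export
peaks_to_genes <- function(annotations,
                           categories = c("proximal_promoter", "promoter")) {
  sel <- annotations[annotations$category %in% categories, , drop = FALSE]
  if (!nrow(sel))
    return(data.frame(gene_id = character(), n_peaks = integer()))
  tab <- table(sel$gene_id)
  out <- data.frame(gene_id = names(tab), n_peaks = as.integer(tab),
                    stringsAsFactors = FALSE)
  out[order(out$gene_id), , drop = FALSE]
}

#' Intersect bound genes with driver genes (driver-gene targets)
#'
#' @param bound_genes character vector (or the data.frame returned by
#'   [peaks_to_genes()]).
#' @param driver_genes character vector of driver gene ids.
#' @return list with `dgt` (sorted intersection), `n_bound`, `n_driver`,
#'   `n_overlap`.
#' @export
overlap_driver_targets <- function(bound_genes, driver_genes) {
  if (is.data.frame(bound_genes)) bound_genes <- bound_genes$gene_id
  if (!length(bound_genes) || !length(driver_genes))
    stop("both gene sets must be nonempty")
  dgt <- sort(intersect(bound_genes, driver_genes))
  list(dgt = dgt, n_bound = length(unique(bound_genes)),
       n_driver = length(unique(driver_genes)), n_overlap = length(dgt))
}
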