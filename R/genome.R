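#' Specification of motifs and peaks to plant in a toy genome
#'
#' @param peak_genes gene ids that receive a promoter peak.
#' @param motifs named character vector of IUPAC patterns available for
#'   planting; the default carries the degenerate heptamer and octamer
#'   grammars plus a literal three-unit alternating nGAAn heat-shock
#'   element.
#' @param plant concrete sequences to write into peaks, one drawn per
#'   peak; names must be a subset of `names(motifs)` (each concrete
#'   sequence must satisfy its pattern).
#' @return object of class `motif_spec`.
#' @export
motif_spec <- function(peak_genes,
                       motifs = c(heptamer = "HRGAAYV",
                                  octamer = "GAMSCKYC",
                                  hse = "AGAACGTTCTAGAAC"),
                       plant = c(heptamer = "TAGAACG",
                                 octamer = "GAACCTTC",
                                 hse = "AGAACGTTCTAGAAC")) {
  stopifnot(length(peak_genes) >= 1L, all(names(plant) %in% names(motifs)))
  for (id in names(plant)) {
    pat <- motif_pattern(id, motifs[[id]])
    hits <- scan_motif(plant[[id]], pat)
    if (!any(hits$position == 0L & hits$strand == "+"))
      stop("planted sequence for '", id, "' does not satisfy its pattern")
  }
  structure(list(peak_genes = peak_genes, motifs = motifs, plant = plant),
            class = "motif_spec")
}

#' Generate a toy genome with TSSs, gene models, peaks and planted motifs
#'
#' Lays the genes of a kinetic panel along a single contig of uniform
#' random background sequence (one 4-kb slot per gene, TSS 2 kb into the
#' slot, alternating strand), gives each gene a two-exon model, and for
#' every gene named in `spec$peak_genes` writes a peak interval centred
#' within 500 bp of its TSS containing at least one planted motif
#' (heptamer, octamer or HSE, cycled). All intervals are 0-based
#' half-open; the contig is padded if a promoter window would extend past
#' its bounds.
#'
#' @param genes list of [kinetic_gene()] (or a character vector of ids).
#' @param spec a [motif_spec()].
#' @param seed integer seed for the background sequence and planting.
#' @param slot_width bases of contig per gene.
#' @return object of class `toy_genome`: list with `contigs` (named
#'   character), `tss_records`, `gene_models`, `peaks`, `planted_motifs`
#'   data frames.
#' @export
simulate_genome <- function(genes, spec, seed = 1L, slot_width = 4000L) {
  stopifnot(inherits(spec, "motif_spec"))
  gene_ids <- if (is.character(genes)) genes
              else vapply(genes, `[[`, "", "gene_id")
  missing <- setdiff(spec$peak_genes, gene_ids)
  if (length(missing))
    stop("peak_genes absent from the gene panel: ",
         paste(missing, collapse = ", "))
  set.seed(seed)
  n <- length(gene_ids)
  pad <- 3000L                         # room for promoter windows at edges
  contig_len <- n * slot_width + 2L * pad
  letters <- sample(c("A", "C", "G", "T"), contig_len, replace = TRUE)

  strand <- rep(c("+", "-"), length.out = n)
  tss <- pad + (seq_len(n) - 1L) * slot_width + 2000L   # 0-based positions
  tss_records <- data.frame(gene_id = gene_ids, contig = "chrS",
                            position = tss, strand = strand,
                            stringsAsFactors = FALSE)

  # two exons downstream of the TSS in transcription orientation
  ex <- function(from, to) { # offsets in transcript orientation, half-open
    start <- ifelse(strand == "+", tss + from, tss + 1L - to)
    data.frame(gene_id = gene_ids, contig = "chrS",
               start = start, end = start + (to - from),
               strand = strand, feature = "exon", stringsAsFactors = FALSE)
  }
  gene_models <- rbind(ex(0L, 400L), ex(700L, 1200L))
  gene_models <- gene_models[order(gene_models$start), , drop = FALSE]
  rownames(gene_models) <- NULL

  planted <- list(); peaks <- list()
  motif_cycle <- names(spec$plant)
  for (k in seq_along(spec$peak_genes)) {
    gid <- spec$peak_genes[k]
    i <- match(gid, gene_ids)
    centre <- tss[i] + sample(-300L:300L, 1L)  # centre within TSS +/- 500
    pk_start <- centre - 250L; pk_end <- centre + 250L
    motif_id <- motif_cycle[(k - 1L) %% length(motif_cycle) + 1L]
    mseq <- spec$plant[[motif_id]]
    mlen <- nchar(mseq)
    mstrand <- sample(c("+", "-"), 1L)
    written <- if (mstrand == "+") mseq else revcomp(mseq)
    mpos <- pk_start + sample.int(pk_end - pk_start - mlen, 1L)  # 0-based
    letters[(mpos + 1L):(mpos + mlen)] <- strsplit(written, "")[[1]]
    planted[[k]] <- data.frame(contig = "chrS", position = mpos,
                               strand = mstrand, motif_id = motif_id,
                               seq = mseq, stringsAsFactors = FALSE)
    peaks[[k]] <- data.frame(contig = "chrS", start = pk_start,
                             end = pk_end, score = round(runif(1, 10, 100)),
                             gene_id = gid, stringsAsFactors = FALSE)
  }
  structure(list(contigs = c(chrS = paste(letters, collapse = "")),
                 tss_records = tss_records, gene_models = gene_models,
                 peaks = do.call(rbind, peaks),
                 planted_motifs = do.call(rbind, planted)),
            class = "toy_genome")
}

#' @export
print.toy_genome <- function(x, ...) {
  cat(sprintf("<toy_genome> %d contig(s), %d genes, %d peaks, %d planted motifs\n",
              length(x$contigs), nrow(x$tss_records), nrow(x$peaks),
              nrow(x$planted_motifs)))
  invisible(x)
}
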