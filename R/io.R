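#' Write a cell_matrix_pair as sparse triplet text plus TSV sidecars
#'
#' Counts go to MatrixMarket files `spliced.mtx` / `unspliced.mtx`
#' (cells x genes), metadata to `cells.tsv` / `genes.tsv`.
#'
#' @param pair a `cell_matrix_pair`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pair <- function(pair, dir) {
  stopifnot(inherits(pair, "cell_matrix_pair"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(Matrix::Matrix(pair$spliced, sparse = TRUE),
                  file.path(dir, "spliced.mtx"))
  Matrix::writeMM(Matrix::Matrix(pair$unspliced, sparse = TRUE),
                  file.path(dir, "unspliced.mtx"))
  utils::write.table(pair$cell_meta, file.path(dir, "cells.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(pair$gene_meta, file.path(dir, "genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a cell_matrix_pair written by [write_pair()]
#' @param dir directory holding the four files.
#' @return a `cell_matrix_pair`.
#' @export
read_pair <- function(dir) {
  cells <- utils::read.delim(file.path(dir, "cells.tsv"),
                             stringsAsFactors = FALSE)
  genes <- utils::read.delim(file.path(dir, "genes.tsv"),
                             stringsAsFactors = FALSE)
  s <- as.matrix(Matrix::readMM(file.path(dir, "spliced.mtx")))
  u <- as.matrix(Matrix::readMM(file.path(dir, "unspliced.mtx")))
  dimnames(s) <- dimnames(u) <- list(cells$cell_id, genes$gene_id)
  structure(list(spliced = s, unspliced = u, cell_meta = cells,
                 gene_meta = genes), class = "cell_matrix_pair")
}

#' Write a toy genome to FASTA / BED / GFF-lite files
#'
#' `genome.fa` (contigs), `tss.bed` (BED6, score 0), `peaks.bed` (BED4+
#' with score), `gene_models.gff` (tab-separated GFF-lite:
#' contig, feature, start, end, strand, gene_id, 0-based half-open) and
#' `planted_motifs.tsv`. All intervals are 0-based half-open on disk.
#'
#' @param genome a `toy_genome`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_genome <- function(genome, dir) {
  stopifnot(inherits(genome, "toy_genome"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(genome$contigs), file.path(dir, "genome.fa"))
  tss <- genome$tss_records
  utils::write.table(
    data.frame(tss$contig, tss$position, tss$position + 1L, tss$gene_id,
               0L, tss$strand),
    file.path(dir, "tss.bed"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  pk <- genome$peaks
  utils::write.table(
    data.frame(pk$contig, pk$start, pk$end,
               sprintf("peak%04d", seq_len(nrow(pk))), pk$score),
    file.path(dir, "peaks.bed"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  gm <- genome$gene_models
  utils::write.table(
    data.frame(gm$contig, gm$feature, gm$start, gm$end, gm$strand,
               gm$gene_id),
    file.path(dir, "gene_models.gff"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  utils::write.table(genome$planted_motifs,
                     file.path(dir, "planted_motifs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read peak intervals from a BED file (0-based half-open)
#' @param path BED3+ file; column 5 (if present) is the score.
#' @return data.frame with `contig`, `start`, `end`, `score`.
#' @export
read_bed_peaks <- function(path) {
  d <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  out <- data.frame(contig = d[[1]], start = d[[2]], end = d[[3]],
                    stringsAsFactors = FALSE)
  out$score <- if (ncol(d) >= 5) d[[5]] else 0
  out
}

#' Read TSS records from a BED6 file
#' @param path BED6 file with gene id in the name column.
#' @return data.frame with `gene_id`, `contig`, `position`, `strand`.
#' @export
read_bed_tss <- function(path) {
  d <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  data.frame(gene_id = d[[4]], contig = d[[1]], position = d[[2]],
             strand = d[[6]], stringsAsFactors = FALSE)
}

#' Export motif hits as BED6 (motif id in the name field)
#' @param hits data.frame from [scan_motif()].
#' @param contig contig name the hits refer to.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed_hits <- function(hits, contig, path) {
  utils::write.table(
    data.frame(contig, hits$position, hits$position + nchar(hits$match),
               hits$motif_id, 0L, hits$strand),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
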