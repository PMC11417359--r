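test_that("IUPAC scanning matches hand-checked windows", {
  hept <- motif_pattern("heptamer", "HRGAAYV")
  hits <- scan_motif("TTAGAACGTT", hept)
  fwd <- hits[hits$strand == "+", ]
  expect_identical(fwd$position, 1L)   # 0-based start of "TAGAACG"
  expect_identical(fwd$match, "TAGAACG")
  expect_identical(nrow(scan_motif("CCCCCCCC", hept)), 0L)
  # N never matches
  expect_identical(nrow(scan_motif("TTAGANCGTT", hept)), 0L)
  expect_error(motif_pattern("bad", "HRGAAXV"), "invalid IUPAC")
})

test_that("forward hits mirror reverse hits of the reverse complement", {
  set.seed(41)
  pat <- motif_pattern("heptamer", "HRGAAYV")
  for (i in 1:10) {
    seq <- random_dna(150)
    rc <- revcomp(seq)
    h1 <- scan_motif(seq, pat)
    h2 <- scan_motif(rc, pat)
    f1 <- h1$position[h1$strand == "+"]
    r2 <- h2$position[h2$strand == "-"]
    expect_setequal(f1, 150 - r2 - 7)
    expect_setequal(h1$position[h1$strand == "-"],
                    150 - h2$position[h2$strand == "+"] - 7)
  }
})

test_that("the scanner matches a regular-expression oracle exactly", {
  set.seed(42)
  for (pat_str in c("HRGAAYV", "GAMSCKYC")) {
    pat <- motif_pattern("m", pat_str)
    for (i in 1:100) {
      seq <- random_dna(200)
      got <- scan_motif(seq, pat)
      want <- scan_oracle(seq, pat_str)
      expect_identical(got$position[got$strand == "+"], want$fwd)
      expect_identical(got$position[got$strand == "-"], want$rev)
    }
  }
})

test_that("heat-shock elements require >= 3 alternating nGAAn units", {
  h <- detect_hse("AGAACGTTCTAGAAC")
  expect_identical(nrow(h), 1L)
  expect_identical(h$position, 0L)
  expect_identical(h$n_units, 3L)
  # two same-orientation units are not an HSE
  expect_identical(nrow(detect_hse("AGAACAGAAC")), 0L)
  # two alternating units fail min_units = 3 but pass min_units = 2
  expect_identical(nrow(detect_hse("AGAACGTTCT")), 0L)
  expect_identical(nrow(detect_hse("AGAACGTTCT", min_units = 2)), 1L)
  expect_error(detect_hse("AGAAC", min_units = 1), "min_units")
})

test_that("HSE detection is reverse-complement symmetric", {
  set.seed(43)
  for (i in 1:10) {
    seq <- paste0(random_dna(40), "AGAACGTTCTAGAACGTTCT", random_dna(40))
    h1 <- detect_hse(seq)
    h2 <- detect_hse(revcomp(seq))
    expect_identical(nrow(h1), nrow(h2))
    L <- nchar(seq)
    expect_setequal(h2$position, L - h1$position - h1$length)
  }
})

test_that("degenerate mode tolerates one mismatched unit within budget", {
  # middle unit core GTTCT -> GTGCT (one mismatch in TTC core)
  seq <- "AGAACGTGCTAGAAC"
  expect_identical(nrow(detect_hse(seq)), 0L)
  h <- detect_hse(seq, max_mismatch_units = 1)
  expect_identical(nrow(h), 1L)
  expect_identical(h$n_units, 3L)
  # two damaged units exceed a budget of one
  seq2 <- "AGCACGTGCTAGAAC"
  expect_identical(nrow(detect_hse(seq2, max_mismatch_units = 1)), 0L)
  expect_identical(detect_hse(seq2, max_mismatch_units = 2)$n_units, 3L)
})

test_that("the toy genome plants what it claims and is fully recoverable", {
  genes <- default_kinetic_genes(8, 6, 6, 4, 2, seed = 51)
  ids <- vapply(genes, `[[`, "", "gene_id")
  spec <- motif_spec(peak_genes = ids[c(2, 5, 9, 14, 17)])
  gnm <- simulate_genome(genes, spec, seed = 52)

  # peak intervals intersect the +/- 500 bp promoter window of their gene
  for (k in seq_len(nrow(gnm$peaks))) {
    tss <- gnm$tss_records$position[
      gnm$tss_records$gene_id == gnm$peaks$gene_id[k]]
    expect_lt(gnm$peaks$start[k], tss + 500)
    expect_gt(gnm$peaks$end[k], tss - 500)
  }

  # the planted ledger is literally present in the contig
  contig <- gnm$contigs[["chrS"]]
  for (k in seq_len(nrow(gnm$planted_motifs))) {
    m <- gnm$planted_motifs[k, ]
    written <- if (m$strand == "+") m$seq else revcomp(m$seq)
    expect_identical(substring(contig, m$position + 1,
                               m$position + nchar(m$seq)), written)
  }

  # scanning the contig recovers 100% of planted positions
  for (k in seq_len(nrow(gnm$planted_motifs))) {
    m <- gnm$planted_motifs[k, ]
    pat <- motif_pattern(m$motif_id, spec$motifs[[m$motif_id]])
    hits <- scan_motif(contig, pat)
    expect_true(any(hits$position == m$position & hits$strand == m$strand))
  }

  # peak-to-gene annotation reproduces the planted ledger exactly
  ann <- annotate_peaks(gnm$peaks, gnm$gene_models, gnm$tss_records)
  bound <- peaks_to_genes(ann)
  expect_setequal(bound$gene_id, spec$peak_genes)
})
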