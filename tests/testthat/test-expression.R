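test_that("QC keeps exactly the cells inside all three open bounds", {
  meta <- data.frame(cell_id = paste0("c", 1:5),
                     genes_detected = c(150L, 300L, 9000L, 300L, 8500L),
                     mito_fraction = c(0.05, 0.05, 0.05, 0.25, 0.05))
  keep <- qc_filter(meta)
  expect_identical(sum(keep), 1L)
  expect_true(keep[["c2"]])

  all_ok <- data.frame(genes_detected = rep(1000L, 4),
                       mito_fraction = rep(0.01, 4))
  expect_true(all(qc_filter(all_ok)))

  # idempotence: filtering the survivors changes nothing
  survivors <- meta[keep, ]
  expect_true(all(qc_filter(survivors)))

  expect_error(qc_filter(data.frame(genes_detected = 1L)), "lacks column")
  bad <- meta; bad$mito_fraction[2] <- NA
  expect_error(qc_filter(bad), "c2")
  expect_error(qc_thresholds(min_genes = 900, max_genes = 800), "below")
})

test_that("LogNormalize follows its closed form", {
  m <- rbind(c(0, 5, 5), c(2, 0, 8))
  out <- log_normalize(m, scale = 1e4)
  expect_identical(out[1, 1], 0)
  expect_equal(out[2, 3], log1p(1e4 * 8 / 10))
  # single-gene cell at full total
  one <- matrix(7, 1, 1)
  expect_equal(log_normalize(one)[1, 1], log(1 + 1e4))
  # doubling counts and totals together changes nothing
  expect_equal(log_normalize(2 * m), log_normalize(m))
  expect_error(log_normalize(rbind(c(0, 0)), 1e4), "zero total")
})

test_that("high-dispersion genes are always selected over flat ones", {
  set.seed(61)
  n_cells <- 100
  flat <- matrix(5, n_cells, 2000)
  noisy <- matrix(rpois(n_cells * 50, 20) * rep(1:50, each = n_cells),
                  n_cells, 50)
  m <- cbind(flat, noisy)
  colnames(m) <- c(sprintf("flat%04d", 1:2000), sprintf("hv%02d", 1:50))
  top <- select_hvg(m, n = 50)
  expect_setequal(top, sprintf("hv%02d", 1:50))
  expect_setequal(select_hvg(m, n = ncol(m)), colnames(m))
  expect_error(select_hvg(m, n = 5000), "fewer genes")
})

test_that("pseudobulk correlation pairs matching clusters across samples", {
  run <- small_run()
  suppressWarnings(cc <- pseudobulk_correlation(run$pair, n_top = 30))
  expect_true(all(diag(cc) == 1))
  expect_true(all(cc >= -1 & cc <= 1))
  # matching stages correlate better than stage vs arrest state
  expect_gt(cc["WT.eP", "KO.eP"], cc["WT.eP", "KO.P-like"])
  expect_gt(cc["WT.mP", "KO.mP"], cc["WT.eP", "KO.P-like"])
})

test_that("rank-test differential expression calls planted shifts", {
  set.seed(62)
  n <- 100
  base <- matrix(rpois(n * 60, 8), n, 60)
  shifted <- base
  shifted[, 1:20] <- matrix(rpois(n * 20, 64), n, 20)  # 8-fold mean shift
  colnames(base) <- colnames(shifted) <- sprintf("g%02d", 1:60)
  res <- differential_expression(shifted, base)
  expect_gte(sum(res$direction[1:20] == "up"), 18)
  expect_true(all(res$direction[21:60] == "ns"))

  # identical groups: everything ns
  same <- differential_expression(base, base)
  expect_true(all(same$direction == "ns"))

  # swapping groups flips up and down exactly
  rev <- differential_expression(base, shifted)
  expect_identical(res$direction == "up", rev$direction == "down")
  expect_equal(res$log2_fold_change, -rev$log2_fold_change)

  expect_error(differential_expression(base[1:5, ], base), "at least 10")
})

test_that("DEG overlap percentages reproduce the printed accounting", {
  a_up <- sprintf("u%03d", 1:822)
  b_up <- c(a_up[1:159], sprintf("v%03d", 1:257))      # |B| = 416
  a_dn <- sprintf("d%03d", 1:578)
  b_dn <- c(a_dn[1:69], sprintf("e%03d", 1:311))       # |B| = 380
  tab <- overlap_fractions(a_up, b_up, a_dn, b_dn)
  expect_equal(tab$percent[tab$direction == "up"], c(19.3, 38.2))
  expect_equal(tab$percent[tab$direction == "down"], c(11.9, 18.2))
  expect_identical(tab$n_overlap, c(159L, 159L, 69L, 69L))

  disjoint <- overlap_fractions("a", "b", "c", "d")
  expect_true(all(disjoint$percent == 0))
  expect_true(all(tab$n_overlap <= pmin(tab$n_denominator, Inf)))
})
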