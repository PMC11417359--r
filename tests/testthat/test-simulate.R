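test_that("deterministic noiseless simulation reproduces the closed form", {
  genes <- list(kinetic_gene("a", 6, 4, 2, 0.3, "repression"),
                kinetic_gene("b", 8, 5, 3, 0.4, "induction"))
  cfg <- simulation_config(n_cells_per_sample = 30, noise_model = "none",
                           capture_efficiency = 1, round_counts = FALSE,
                           seed = 3)
  pair <- simulate_dataset(genes, cfg)
  wt <- subset_pair(pair, "WT")
  for (j in 1:2) {
    e <- kinetics_expected(genes[[j]], wt$cell_meta$true_time)
    expect_equal(unname(wt$unspliced[, j]), e$u)
    expect_equal(unname(wt$spliced[, j]), e$s)
  }
  # with rounding enabled the matrices are the rounded expectations
  cfg_r <- simulation_config(n_cells_per_sample = 30, noise_model = "none",
                             capture_efficiency = 1, round_counts = TRUE,
                             seed = 3)
  pair_r <- simulate_dataset(genes, cfg_r)
  expect_equal(pair_r$spliced, round(pair$spliced))
})

test_that("a fixed seed reproduces the dataset exactly", {
  genes <- default_kinetic_genes(6, 5, 4, 2, 1, seed = 9)
  cfg <- simulation_config(n_cells_per_sample = 40, seed = 10)
  p1 <- simulate_dataset(genes, cfg)
  p2 <- simulate_dataset(genes, cfg)
  expect_identical(p1$spliced, p2$spliced)
  expect_identical(p1$unspliced, p2$unspliced)
  expect_identical(p1$cell_meta, p2$cell_meta)
})

test_that("degenerate inputs are rejected", {
  cfg <- simulation_config(seed = 1)
  expect_error(simulate_dataset(list(), cfg), "empty gene list")
  expect_error(simulation_config(n_cells_per_sample = 0), "positive")
  expect_error(simulation_config(cluster_breakpoints = c(0.5, 0.2)),
               "strictly increasing")
  expect_error(simulation_config(ko_arrest_time = 1.5), "within")
})

test_that("WT unspliced means move in the direction of the gene class", {
  # 200 genes (80 repression, 60 induction, 60 steady), 500 cells, Poisson
  genes <- default_kinetic_genes(80, 60, 60, 0, 0, seed = 31)
  cfg <- simulation_config(n_cells_per_sample = 500, seed = 32)
  pair <- simulate_dataset(genes, cfg)
  wt <- subset_pair(pair, "WT")
  tt <- wt$cell_meta$true_time
  lo <- tt <= quantile(tt, 0.1)
  hi <- tt >= quantile(tt, 0.9)
  d <- colMeans(wt$unspliced[hi, , drop = FALSE]) -
    colMeans(wt$unspliced[lo, , drop = FALSE])
  cls <- pair$gene_meta$gene_class
  ok <- (cls == "repression" & d < 0) | (cls == "induction" & d > 0)
  expect_gte(mean(ok[cls != "steady"]), 0.95)
})

test_that("Poisson sampling is centred on the capture-scaled expectation", {
  # one steady gene: every cell shares the same expectation, so the mean
  # over many cells estimates capture_efficiency x expectation
  g <- kinetic_gene("g", 12, 4, 2, 0, "steady")
  cfg <- simulation_config(n_cells_per_sample = 5000,
                           capture_efficiency = 0.5, seed = 77)
  pair <- simulate_dataset(list(g), cfg)
  wt <- subset_pair(pair, "WT")
  lam_u <- 0.5 * 12 / 4
  lam_s <- 0.5 * 12 / 2
  se_u <- sqrt(lam_u / 5000)
  se_s <- sqrt(lam_s / 5000)
  expect_lt(abs(mean(wt$unspliced) - lam_u), 3 * se_u)
  expect_lt(abs(mean(wt$spliced) - lam_s), 3 * se_s)
})

test_that("cluster labels are a deterministic function of time and sample", {
  cfg <- simulation_config(seed = 1)
  tt <- c(0.1, 0.34, 0.5, 0.7, 0.95)
  expect_equal(cluster_from_time(tt, "WT", cfg),
               c("eP", "mP", "mP", "lP", "lP"))
  expect_equal(cluster_from_time(tt, "KO", cfg),
               c("eP", "mP", "P-like", "P-like", "P-like"))
  expect_identical(cluster_from_time(tt, "KO", cfg),
                   cluster_from_time(tt, "KO", cfg))
})

test_that("arrested KO cells stall except for frozen genes", {
  genes <- list(
    kinetic_gene("frz", 6, 4, 2, 0.2, "repression", ko_frozen = TRUE),
    kinetic_gene("nrm", 6, 4, 2, 0.2, "repression"))
  cfg <- simulation_config(n_cells_per_sample = 200, noise_model = "none",
                           capture_efficiency = 1, round_counts = FALSE,
                           seed = 8)
  pair <- simulate_dataset(genes, cfg)
  ko <- subset_pair(pair, "KO")
  arr <- ko$cell_meta$cluster == "P-like"
  # frozen repression gene: sustained at the ON steady state
  expect_true(all(abs(ko$unspliced[arr, "frz"] - 6 / 4) < 1e-9))
  # unfrozen gene: held at its arrest-time value
  e_arr <- kinetics_expected(genes[[2]], cfg$ko_arrest_time)
  expect_true(all(abs(ko$unspliced[arr, "nrm"] - e_arr$u) < 1e-9))
  # pre-arrest KO cells follow normal dynamics
  pre <- !arr
  e_pre <- kinetics_expected(genes[[1]], ko$cell_meta$true_time[pre])
  expect_equal(unname(ko$unspliced[pre, "frz"]), e_pre$u)
})
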