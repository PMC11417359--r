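noiseless_gene_data <- function(alpha, gamma, n = 300, seed = 1,
                                cls = "repression") {
  set.seed(seed)
  g <- kinetic_gene("g", alpha, 1, gamma, 4, cls)
  tt <- sort(runif(n, 0, 4 + 4 / min(1, gamma)))
  e <- kinetics_expected(g, tt)
  list(gene = g, t = tt, u = e$u, s = e$s)
}

test_that("a noiseless gene is recovered: gamma/beta within 5%, latent
           time rank-matching the truth", {
  d <- noiseless_gene_data(2, 0.5, n = 300)
  f <- fit_gene_kinetics(d$u, d$s, "g")
  expect_true(f$valid)
  expect_lt(abs(f$gamma - 0.5) / 0.5, 0.05)
  expect_gte(cor(f$latent_time, d$t, method = "spearman"), 0.95)
  expect_gt(f$fit_likelihood, 0.9)
})

test_that("the fit objective is non-increasing across iterations", {
  for (seed in 1:4) {
    d <- noiseless_gene_data(sample(1:5, 1), runif(1, 0.2, 1.8),
                             n = 150, seed = seed)
    u <- d$u + rnorm(150, 0, 0.05)
    s <- d$s + rnorm(150, 0, 0.05)
    f <- fit_gene_kinetics(pmax(u, 0), pmax(s, 0), "g")
    expect_true(all(diff(f$objective) <= 1e-10))
  }
})

test_that("degenerate genes yield an invalid fit with likelihood 0", {
  f <- fit_gene_kinetics(rep(0, 100), rep(0, 100), "zero")
  expect_false(f$valid)
  expect_identical(f$fit_likelihood, 0)
  f2 <- fit_gene_kinetics(c(rep(0, 95), 1, 1, 0, 0, 1), rep(0, 100), "thin")
  expect_false(f2$valid)   # fewer than 20 cells with signal
})

test_that("shuffling the cells strictly lowers the fit likelihood", {
  d <- noiseless_gene_data(3, 0.7, n = 200, seed = 7)
  f_true <- fit_gene_kinetics(d$u, d$s, "g")
  set.seed(8)
  idx <- sample.int(200)
  # break the (u, s) pairing so no curve explains the cloud
  f_shuf <- fit_gene_kinetics(d$u, d$s[idx], "g")
  expect_lt(f_shuf$fit_likelihood, f_true$fit_likelihood)
})

test_that("driver selection follows the likelihood threshold rule", {
  run <- small_run()
  fits <- run$fits_wt
  drv0 <- select_driver_genes(fits, threshold = 0)
  n_valid <- sum(vapply(fits, function(f) f$valid, TRUE))
  expect_identical(nrow(drv0), n_valid)     # any valid fit has lik > 0
  expect_identical(nrow(select_driver_genes(fits, threshold = 1.1)), 0L)

  drv3 <- select_driver_genes(fits, threshold = 0.3)
  gm <- run$pair$gene_meta
  nonsteady <- gm$gene_id[gm$gene_class != "steady"]
  expect_gte(mean(nonsteady %in% drv3$gene_id), 0.9)
  sel <- drv3[drv3$gene_id %in% nonsteady, ]
  truth <- gm$gene_class[match(sel$gene_id, gm$gene_id)]
  expect_gte(mean(sel$direction == truth), 0.9)
})

test_that("inferred cell time tracks the true trajectory", {
  run <- small_run()
  expect_gte(cor(run$time_wt, run$wt$cell_meta$true_time,
                 method = "spearman"), 0.9)
  # arrested KO cells are ordered after progressing ones
  arr <- run$ko$cell_meta$cluster == "P-like"
  expect_gt(mean(rank(run$time_ko)[arr]), mean(rank(run$time_ko)[!arr]))
})

test_that("inferred cell time is symmetric in its inputs and honest about
           degenerate gene sets", {
  run <- small_run()
  fits <- Filter(function(f) f$valid, run$fits_wt)
  t1 <- inferred_cell_time(fits, likelihood_quantile = 0)
  t2 <- inferred_cell_time(rev(fits), likelihood_quantile = 0)
  expect_equal(t1, t2)
  # a single contributing gene returns that gene's (scaled) latent time
  one <- fits[which.max(vapply(fits, `[[`, 1, "fit_likelihood"))]
  t_one <- inferred_cell_time(one, likelihood_quantile = 0, min_genes = 1)
  lt <- one[[1]]$latent_time
  expect_equal(t_one, (lt - min(lt)) / diff(range(lt)))
  expect_error(inferred_cell_time(one, likelihood_quantile = 0),
               "quantile cutoff")
})

test_that("projection onto a fitted curve reproduces the stored times", {
  run <- small_run()
  fits <- Filter(function(f) f$valid, run$fits_wt)
  f <- fits[[which.max(vapply(fits, `[[`, 1, "fit_likelihood"))]]
  self <- project_latent_time(f, run$mom_wt$Mu[, f$gene_id],
                              run$mom_wt$Ms[, f$gene_id])
  expect_gte(cor(self, f$latent_time, method = "spearman"), 0.99)
})
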