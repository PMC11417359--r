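test_that("velocity vanishes on the steady-state line and has the right
           sign off it", {
  run <- small_run()
  vel <- compute_velocity(run$fits_wt, run$mom_wt)
  gam <- vapply(Filter(function(f) f$valid, run$fits_wt), `[[`, 1, "gamma")
  for (g in colnames(vel)[c(1, 5)]) {
    resid <- run$mom_wt$Mu[, g] - gam[[g]] * run$mom_wt$Ms[, g]
    expect_equal(sign(vel[, g]), sign(resid))
  }
  # Mu exactly on the line -> zero
  f <- run$fits_wt[[colnames(vel)[1]]]
  mu_line <- f$gamma * run$mom_wt$Ms[, 1, drop = FALSE]
  mom2 <- run$mom_wt
  mom2$Mu[, 1] <- mu_line
  v2 <- compute_velocity(run$fits_wt, mom2)
  expect_true(all(abs(v2[, 1]) < 1e-10))
})

test_that("simulated repression-phase cells have negative median velocity", {
  run <- small_run()
  vel <- compute_velocity(run$fits_wt, run$mom_wt)
  gm <- run$pair$gene_meta
  late <- run$wt$cell_meta$true_time > 0.5   # past every repression switch
  rep_genes <- intersect(colnames(vel),
                         gm$gene_id[gm$gene_class == "repression"])
  med <- apply(vel[late, rep_genes], 2, median)
  expect_gte(mean(med < 0), 0.9)
})

test_that("the transition matrix is row-stochastic on kNN support with
           kernel weights monotone in the cosine", {
  run <- small_run()
  vel <- compute_velocity(run$fits_wt, run$mom_wt)
  tr <- velocity_graph(run$mom_wt, vel, kernel_scale = 0.1)
  expect_true(all(abs(Matrix::rowSums(tr) - 1) < 1e-9))
  expect_true(all(tr@x >= 0))
  expect_true(all(Matrix::diag(tr) == 0))

  # hand-built geometry: i's velocity points at j and away from k
  mom <- list(Ms = rbind(i = c(0, 0), j = c(1, 0), k = c(-1, 0)),
              Mu = rbind(c(0, 0), c(1, 0), c(-1, 0)),
              knn = rbind(c(1, 2, 3), c(2, 1, 3), c(3, 1, 2)),
              n_neighbors = 3L, n_pcs = 2L)
  colnames(mom$Ms) <- colnames(mom$Mu) <- c("a", "b")
  class(mom) <- "moments"
  v <- rbind(c(1, 0), c(1, 0), c(1, 0))
  colnames(v) <- c("a", "b")
  tr2 <- velocity_graph(mom, v, kernel_scale = 0.1)
  expect_gt(tr2[1, 2], tr2[1, 3])
  # a zero-velocity cell transitions uniformly
  v0 <- v; v0[1, ] <- 0
  tr3 <- velocity_graph(mom, v0, kernel_scale = 0.1)
  expect_equal(tr3[1, 2], tr3[1, 3])
})

test_that("a forward-pointing chain pushes transition mass forward", {
  # 3 cells on a line, velocities all pointing to larger coordinates
  mom <- list(Ms = cbind(x = c(0, 1, 2), y = 0),
              Mu = cbind(x = c(0, 1, 2), y = 0),
              knn = rbind(c(1, 2, 3), c(2, 1, 3), c(3, 2, 1)),
              n_neighbors = 3L, n_pcs = 2L)
  class(mom) <- "moments"
  v <- cbind(x = c(1, 1, 1), y = 0)
  tr <- velocity_graph(mom, v, kernel_scale = 0.1)
  expect_gt(tr[1, 2], tr[1, 3] * 0)     # row 1 mass forward
  expect_gt(tr[2, 3], tr[2, 1])         # interior cell: forward > backward
})

test_that("terminal states recover absorbing structure", {
  # chain with one absorbing cell
  T1 <- rbind(c(0, 1, 0), c(0, 0, 1), c(0, 0, 1))
  ts <- terminal_states(T1, c("a", "b", "c"))
  expect_equal(ts$cell_prob, c(0, 0, 1), tolerance = 1e-8)
  expect_equal(unname(ts$cluster_score[["c"]]), 1, tolerance = 1e-8)
  # doubly stochastic -> uniform stationary distribution
  T2 <- matrix(1 / 4, 4, 4)
  ts2 <- terminal_states(T2, rep(c("x", "y"), 2))
  expect_equal(ts2$cell_prob, rep(0.25, 4), tolerance = 1e-10)
  expect_equal(sum(ts2$cell_prob), 1, tolerance = 1e-6)
  expect_error(terminal_states(rbind(c(0.5, 0.4), c(0, 1)), c("a", "b")),
               "row-stochastic")
})

test_that("the KO arrest cluster carries the highest terminal score", {
  run <- small_run()
  vel <- compute_velocity(run$fits_wt, run$mom_ko,
                          likelihood_quantile = 0.5)
  tr <- velocity_graph(run$mom_ko, vel)
  ts <- terminal_states(tr, run$ko$cell_meta$cluster)
  expect_identical(names(which.max(ts$cluster_score)), "P-like")
})

test_that("cluster connectivity matches the expected-count oracle", {
  # two well-separated blobs: kNN sets never cross
  set.seed(21)
  a <- matrix(rnorm(40, 0), 20, 2)
  b <- matrix(rnorm(40, 50), 20, 2)
  pts <- rbind(a, b)
  d <- as.matrix(dist(pts)); diag(d) <- -1
  knn <- t(apply(d, 1, function(r) order(r)[1:6]))
  cl <- rep(c("A", "B"), each = 20)
  cg <- cluster_graph(knn, cl)
  expect_identical(unname(cg$connectivity["A", "B"]), 0)
  expect_true(all(diag(cg$connectivity) == 0))

  # one blob split arbitrarily in two: observed cross edges far exceed
  # the random-placement expectation m * 2 n_a n_b / (n (n-1))
  cl2 <- rep(c("L", "R"), 20)
  cg2 <- cluster_graph(knn, cl2)
  edges <- unique(t(apply(
    cbind(rep(1:40, 5), as.vector(knn[, -1])), 1, sort)))
  m <- nrow(edges)
  obs <- sum(cl2[edges[, 1]] != cl2[edges[, 2]])
  exp_cnt <- m * 2 * 20 * 20 / (40 * 39)
  expect_equal(unname(cg2$connectivity["L", "R"]), obs / exp_cnt,
               tolerance = 1e-10)
  expect_gt(cg2$connectivity["L", "R"], 1)
})

test_that("the KO cluster graph branches from eP with forward flux", {
  run <- small_run()
  vel <- compute_velocity(run$fits_wt, run$mom_ko,
                          likelihood_quantile = 0.5)
  tr <- velocity_graph(run$mom_ko, vel)
  cg <- cluster_graph(run$mom_ko$knn, run$ko$cell_meta$cluster, tr)
  conn <- cg$connectivity
  # successive normal stages are better connected than eP is to the
  # arrest branch, and the net velocity flux runs down the trajectory
  # and into the arrest state from both normal stages
  expect_gt(conn["eP", "mP"], conn["eP", "P-like"])
  expect_gt(cg$flux["eP", "mP"], 0)
  expect_gt(cg$flux["eP", "P-like"], 0)
  expect_gt(cg$flux["mP", "P-like"], 0)
})
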