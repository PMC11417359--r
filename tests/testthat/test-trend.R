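test_that("Mann-Kendall statistics match hand-derived cases", {
  r <- mann_kendall(1:5)
  expect_identical(r$S, 10)
  expect_equal(r$varS, 50 / 3, tolerance = 1e-6)
  expect_equal(r$z, 9 / sqrt(50 / 3), tolerance = 1e-4)
  expect_equal(r$p, 0.0275, tolerance = 1e-3)

  cst <- mann_kendall(rep(2, 10))
  expect_identical(cst$S, 0)
  expect_identical(cst$z, 0)
  expect_identical(cst$p, 1)

  expect_identical(mann_kendall(c(3, 1, 2))$S, -1)

  short <- mann_kendall(c(1, 2))
  expect_true(short$untestable)
  expect_identical(short$p, 1)
})

test_that("S and tie-corrected varS match exhaustive enumeration", {
  # all sequences of length 3..5 over {0,1,2} here; the acceptance test
  # extends the same oracle to length 8
  for (n in 3:5) {
    grid <- as.matrix(expand.grid(rep(list(0:2), n)))
    for (i in seq_len(nrow(grid))) {
      x <- grid[i, ]
      got <- mann_kendall(x)
      want <- mk_oracle(x)
      expect_identical(got$S, want$S)
      expect_equal(got$varS, want$varS, tolerance = 1e-12)
    }
  }
})

test_that("Mann-Kendall is antisymmetric under reversal and negation", {
  set.seed(13)
  for (i in 1:20) {
    x <- sample(0:5, 12, replace = TRUE)
    a <- mann_kendall(x)
    b <- mann_kendall(rev(x))
    d <- mann_kendall(-x)
    expect_identical(b$S, -a$S)
    expect_identical(d$S, -a$S)
    expect_equal(b$p, a$p)
    expect_equal(d$p, a$p)
  }
})

test_that("Kendall score agrees with the cor.test numerator", {
  set.seed(14)
  x <- rnorm(30)
  S <- mann_kendall(x)$S
  tau <- suppressWarnings(cor.test(seq_along(x), x, method = "kendall"))
  expect_equal(S, unname(tau$estimate) * choose(30, 2), tolerance = 1e-8)
})

test_that("trend slopes are ordinary least squares on [0,1] positions", {
  expect_equal(trend_slope(seq(0, 1, length.out = 11)), 1)
  expect_equal(trend_slope(rep(3, 9)), 0)
  expect_equal(trend_slope(c(0, 2, 4, 6)), 6)
  expect_error(trend_slope(1), "at least 2")
})

test_that("the anomaly rule fires on flattening and sign reversal only
           when the wild-type trend is significant", {
  # flattened: WT strongly decreasing, KO same sign but 1/6.7 the slope
  wt <- seq(1, 0, length.out = 20)
  ko <- seq(1, 0.85, length.out = 20)
  call <- classify_trend(wt, ko, gene_id = "g", direction = "repression")
  expect_gt(call$slope_ratio, 4)
  expect_identical(call$label, "repression_anomaly")

  # identical strictly increasing series: ratio 1, same sign
  up <- seq(0, 1, length.out = 20)
  expect_identical(classify_trend(up, up, direction = "induction")$label,
                   "unchanged")

  # sign reversal: WT increasing, KO strictly decreasing
  call3 <- classify_trend(up, rev(up), direction = "induction")
  expect_identical(call3$label, "induction_anomaly")

  # non-significant WT trend never fires
  set.seed(15)
  noise <- rnorm(20)
  call4 <- classify_trend(noise, rev(up), direction = "repression")
  expect_identical(call4$label, "unchanged")
  expect_false(call4$direction_defined)

  # untestable series map to unchanged with the audit flag
  call5 <- classify_trend(c(1, 2, 3), c(3, 2, 1), direction = "repression")
  expect_identical(call5$label, "unchanged")
  expect_true(call5$untestable)
})

test_that("the significance gate is configurable", {
  wt <- seq(1, 0, length.out = 30)
  set.seed(16)
  ko <- rnorm(30, 0.5, 0.01)  # flat noise: not significant on its own
  by_wt <- classify_trend(wt, ko, direction = "repression", gate = "wt")
  by_both <- classify_trend(wt, ko, direction = "repression", gate = "both")
  expect_identical(by_wt$label, "repression_anomaly")
  expect_identical(by_both$label, "unchanged")
})

test_that("classification summary reproduces the three-way accounting", {
  calls <- rep(c("repression_anomaly", "induction_anomaly", "unchanged"),
               c(35, 22, 50))
  tab <- summarize_classification(calls)
  expect_identical(attr(tab, "total"), 107L)
  expect_equal(tab$percent[tab$label == "repression_anomaly"], 32.7)
  expect_equal(tab$percent[tab$label == "induction_anomaly"], 20.6)
  expect_equal(tab$percent[tab$label == "unchanged"], 46.7)
  # order independence
  tab2 <- summarize_classification(sample(calls))
  expect_identical(tab, tab2)
  # single call and empty input
  one <- summarize_classification("unchanged")
  expect_equal(one$percent[one$label == "unchanged"], 100.0)
  zero <- summarize_classification(character())
  expect_identical(attr(zero, "total"), 0L)
  expect_true(all(zero$count == 0))
})
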