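#' Mann-Kendall trend test
#'
#' Nonparametric trend test on an ordered series. The Kendall score is
#' `S = sum_{i<j} sign(x_j - x_i)`; its variance under the null, with a
#' correction for tied groups of sizes t, is
#' `varS = [n(n-1)(2n+5) - sum_t t(t-1)(2t+5)] / 18`. The normal
#' approximation with continuity correction gives
#' `z = (S - sign(S)) / sqrt(varS)` (0 when S = 0) and a two-sided
#' p-value. Series shorter than 3 are flagged untestable with `p = 1` by
#' convention.
#'
#' @param values numeric series in its meaningful order.
#' @return object of class `mk_result`: list with `S`, `varS`, `z`, `p`,
#'   `n`, `untestable`.
#' @export
mann_kendall <- function(values) {
  n <- length(values)
  if (n < 3L || anyNA(values)) {
    return(structure(list(S = 0L, varS = NA_real_, z = 0, p = 1, n = n,
                          untestable = TRUE), class = "mk_result"))
  }
  d <- outer(values, values, `-`)
  S <- sum(sign(d[lower.tri(d)]))      # pairs (i < j): x_j - x_i
  ties <- table(values)
  ties <- ties[ties > 1]
  varS <- (n * (n - 1) * (2 * n + 5) -
             sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  z <- if (S == 0 || varS <= 0) 0 else (S - sign(S)) / sqrt(varS)
  p <- if (z == 0) 1 else 2 * stats::pnorm(-abs(z))
  structure(list(S = S, varS = varS, z = z, p = p, n = n,
                 untestable = FALSE), class = "mk_result")
}

#' @export
print.mk_result <- function(x, ...) {
  cat(sprintf("<mk_result> n=%d S=%d varS=%.4g z=%.4g p=%.4g%s\n",
              x$n, x$S, x$varS, x$z, x$p,
              if (x$untestable) " (untestable)" else ""))
  invisible(x)
}

#' Linear-regression slope over ordinal position
#'
#' Ordinary least-squares slope of the values on their position scaled to
#' `[0, 1]`, so the slope reads as total change across the series.
#'
#' @param values numeric series (length >= 2).
#' @return slope (numeric scalar).
#' @export
trend_slope <- function(values) {
  n <- length(values)
  if (n < 2L) stop("need at least 2 values")
  x <- seq(0, 1, length.out = n)
  stats::cov(x, values) / stats::var(x)
}

#' Classify a gene's trend change between two samples
#'
#' Implements the anomaly rule: a driver gene is abnormal if its
#' wild-type series shows a significant trend (Mann-Kendall `p < alpha`)
#' and either the trend changes between samples (the sign of the Kendall
#' score differs) or the slope ratio from linear regression exceeds
#' `ratio_threshold`. Abnormal repression drivers are labelled
#' `repression_anomaly`, abnormal induction drivers
#' `induction_anomaly`; everything else (no change, or p above alpha) is
#' `unchanged`.
#'
#' The slope ratio is oriented as `|slope_WT| / max(|slope_KO|, eps)`
#' with `eps` defaulting to `1e-6` times the WT value range, capturing
#' dynamics that flatten in the KO sample. The significance gate defaults
#' to the WT series (it establishes the trend the KO may deviate from);
#' `gate = "ko"` or `"both"` are available. `trend_change = "significance"`
#' replaces the sign-reversal criterion by loss of significance in KO.
#'
#' @param series_wt,series_ko unspliced values of cells sorted by
#'   inferred cell time in each sample.
#' @param gene_id identifier carried through.
#' @param direction `"repression"` or `"induction"` (the WT driver
#'   direction); if NULL, taken from the sign of the WT Kendall score.
#' @param alpha significance level of the gate.
#' @param ratio_threshold slope-ratio cutoff.
#' @param eps floor for the KO slope magnitude (NULL = 1e-6 * WT range).
#' @param gate which sample's p-value gates the rule.
#' @param trend_change `"sign"` (Kendall score sign reversal) or
#'   `"significance"` (KO trend no longer significant).
#' @return one-row data.frame (a trend call) with the MK statistics,
#'   slopes, ratio, label and audit flags.
#' @export
classify_trend <- function(series_wt, series_ko, gene_id = NA_character_,
                           direction = NULL, alpha = 0.01,
                           ratio_threshold = 4, eps = NULL,
                           gate = c("wt", "ko", "both"),
                           trend_change = c("sign", "significance")) {
  gate <- match.arg(gate)
  trend_change <- match.arg(trend_change)
  mk_wt <- mann_kendall(series_wt)
  mk_ko <- mann_kendall(series_ko)
  untestable <- mk_wt$untestable || mk_ko$untestable ||
    length(series_wt) < 8L || length(series_ko) < 8L
  slope_wt <- if (length(series_wt) >= 2L) trend_slope(series_wt) else NA_real_
  slope_ko <- if (length(series_ko) >= 2L) trend_slope(series_ko) else NA_real_
  if (is.null(eps)) eps <- 1e-6 * max(diff(range(series_wt)), 1e-12)
  slope_ratio <- abs(slope_wt) / max(abs(slope_ko), eps)
  if (is.null(direction))
    direction <- if (mk_wt$S < 0) "repression" else "induction"

  gate_p <- switch(gate, wt = mk_wt$p, ko = mk_ko$p,
                   both = max(mk_wt$p, mk_ko$p))
  changed <- switch(trend_change,
                    sign = sign(mk_wt$S) != sign(mk_ko$S),
                    significance = mk_ko$p >= alpha)
  direction_defined <- !untestable && mk_wt$p < alpha
  anomaly <- direction_defined && gate_p < alpha &&
    (changed || slope_ratio > ratio_threshold)
  label <- if (!anomaly) "unchanged"
           else if (direction == "repression") "repression_anomaly"
           else "induction_anomaly"
  data.frame(gene_id = gene_id, direction = direction,
             S_wt = mk_wt$S, p_wt = mk_wt$p,
             S_ko = mk_ko$S, p_ko = mk_ko$p,
             slope_wt = slope_wt, slope_ko = slope_ko,
             slope_ratio = slope_ratio, label = label,
             untestable = untestable,
             direction_defined = direction_defined,
             stringsAsFactors = FALSE)
}

#' Trend calls for a set of genes across two ordered samples
#'
#' Sorts each sample's cells by its inferred cell time (ties broken by
#' cell index, stable) and applies [classify_trend()] to the smoothed
#' unspliced series of each requested gene.
#'
#' @param mu_wt,mu_ko cells x genes matrices of smoothed unspliced
#'   values.
#' @param time_wt,time_ko per-cell inferred times.
#' @param drivers data.frame from [select_driver_genes()] (needs
#'   `gene_id` and `direction`), restricted to the genes to test.
#' @param ... passed to [classify_trend()].
#' @return data.frame of trend calls, one row per gene.
#' @export
trend_calls <- function(mu_wt, mu_ko, time_wt, time_ko, drivers, ...) {
  ord_wt <- order(time_wt, seq_along(time_wt))
  ord_ko <- order(time_ko, seq_along(time_ko))
  calls <- lapply(seq_len(nrow(drivers)), function(i) {
    g <- drivers$gene_id[i]
    classify_trend(mu_wt[ord_wt, g], mu_ko[ord_ko, g], gene_id = g,
                   direction = drivers$direction[i], ...)
  })
  do.call(rbind, calls)
}

TREND_LABELS <- c("repression_anomaly", "induction_anomaly", "unchanged")

#' Summarize trend calls into the three-way classification table
#'
#' @param calls data.frame of trend calls (or any vector/data.frame with
#'   a `label` column).
#' @return data.frame with one row per label plus counts, percentages
#'   (rounded to 1 decimal) and an attached `total` attribute.
#' @export
summarize_classification <- function(calls) {
  labels <- if (is.data.frame(calls)) calls$label else as.character(calls)
  tab <- table(factor(labels, levels = TREND_LABELS))
  total <- sum(tab)
  pct <- if (total > 0) round(100 * as.numeric(tab) / total, 1)
         else rep(0, length(tab))
  out <- data.frame(label = TREND_LABELS, count = as.integer(tab),
                    percent = pct, stringsAsFactors = FALSE)
  attr(out, "total") <- total
  out
}
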