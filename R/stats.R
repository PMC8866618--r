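# Paired nonparametric statistics and paper-shaped report assembly.

#' Two-tailed Wilcoxon signed-rank test
#'
#' Paired test on `x - y`.  Zero differences are dropped (Wilcoxon
#' convention); tied absolute differences receive mid-ranks.  For up to
#' `exactLimit` nonzero differences the exact two-tailed p-value is computed
#' from the full sign-flip null distribution (dynamic programme over the
#' 2^n assignments, valid under ties); above it, the normal approximation
#' with continuity and tie correction is used.  The two-tailed p is
#' `min(1, 2 * min(P(W <= w), P(W >= w)))`.
#'
#' @param x,y paired numeric vectors of equal length
#' @param exactLimit maximum n for the exact null (default 20)
#' @return list(p_value, statistic = W+ (rank sum of positive differences),
#'   n = nonzero differences, exact = logical)
#' @examples
#' wilcoxonSignedRank(c(2, 3, 4, 5, 6), c(1, 2, 3, 4, 5))$p_value  # 0.0625
#' @export
wilcoxonSignedRank <- function(x, y, exactLimit = 20L) {
  stopifnot(length(x) == length(y), length(x) > 0)
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("all paired differences are zero; the test is undefined")
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= exactLimit) {
    r2 <- as.integer(round(2 * r))       # mid-ranks are multiples of 1/2
    tot <- sum(r2)
    dp <- numeric(tot + 1L)
    dp[1L] <- 1
    for (rr in r2) {
      shifted <- c(numeric(rr), dp[seq_len(tot + 1L - rr)])
      dp <- dp + shifted
    }
    cdf <- cumsum(dp)
    w2 <- as.integer(round(2 * w))
    pLe <- cdf[w2 + 1L] / 2^n
    pGe <- (2^n - if (w2 == 0L) 0 else cdf[w2]) / 2^n
    p <- min(1, 2 * min(pLe, pGe))
    return(list(p_value = p, statistic = w, n = n, exact = TRUE))
  }
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(p_value = max(p, .Machine$double.xmin), statistic = w, n = n,
       exact = FALSE)
}

#' Median and interquartile range
#'
#' Quartiles by the inclusive linear-interpolation convention
#' (`stats::quantile` type 7, the R default).
#'
#' @param values non-empty numeric vector
#' @return named numeric `c(median, q1, q3)`
#' @examples
#' medianIQR(1:5)  # 3, 2, 4
#' @export
medianIQR <- function(values) {
  if (!length(values)) stop("medianIQR needs at least one value")
  q <- stats::quantile(values, c(0.5, 0.25, 0.75), type = 7, names = FALSE)
  c(median = q[1], q1 = q[2], q3 = q[3])
}

.safeIQR <- function(values) {
  values <- values[is.finite(values)]
  if (!length(values)) c(median = NA_real_, q1 = NA_real_, q3 = NA_real_)
  else medianIQR(values)
}

#' Assemble the study-shaped summary report
#'
#' Combines artifact quantification summaries and detection metrics into
#' median/IQR tables (the shapes of the study's CNR and detection tables),
#' per-parameter width data for boxplots, and two-tailed Wilcoxon
#' signed-rank comparisons of per-frame widths against the first (baseline)
#' entry, flagged at `alpha`.  Frames are paired by their order within each
#' dataset (truncated to the common length).  No multiple-testing
#' correction is applied.
#'
#' @param quant named list of [ArtifactQuant-class] results, baseline first
#' @param detect named list of [DetectionMetrics-class] results (may be
#'   empty)
#' @param alpha significance level
#' @param outDir optional directory; if given, writes `widths.csv`,
#'   `cnr_table.csv`, `detection_table.csv`, `comparisons.csv` and
#'   `summary.json`
#' @return list(cnrTable, detectionTable, comparisons, widths)
#' @export
buildReport <- function(quant = list(), detect = list(), alpha = 0.05,
                        outDir = NULL) {
  cnrTable <- data.frame(parameter = character(), width_median = numeric(),
                         width_q1 = numeric(), width_q3 = numeric(),
                         cnr_blood_median = numeric(), cnr_blood_q1 = numeric(),
                         cnr_blood_q3 = numeric(), cnr_agar_median = numeric(),
                         cnr_agar_q1 = numeric(), cnr_agar_q3 = numeric(),
                         p_vs_baseline = numeric(), significant = logical(),
                         stringsAsFactors = FALSE)
  widths <- data.frame(parameter = character(), frame = integer(),
                       width_mm = numeric(), stringsAsFactors = FALSE)
  compTable <- data.frame(comparison = character(), n = integer(),
                          p_value = numeric(), significant = logical(),
                          stringsAsFactors = FALSE)
  baseWidths <- NULL
  for (nm in names(quant)) {
    q <- quant[[nm]]
    pf <- q@perFrame[!q@perFrame$excluded, , drop = FALSE]
    wv <- pf$width_mm
    s <- q@summary
    p <- NA_real_
    if (is.null(baseWidths)) baseWidths <- wv
    else {
      n <- min(length(baseWidths), length(wv))
      p <- tryCatch(wilcoxonSignedRank(wv[seq_len(n)],
                                       baseWidths[seq_len(n)])$p_value,
                    error = function(e) NA_real_)
      compTable <- rbind(compTable, data.frame(
        comparison = paste0(nm, " vs ", names(quant)[1]), n = n, p_value = p,
        significant = is.finite(p) && p < alpha))
    }
    cnrTable <- rbind(cnrTable, data.frame(
      parameter = nm, width_median = s$width_median, width_q1 = s$width_q1,
      width_q3 = s$width_q3, cnr_blood_median = s$cnr_blood_median,
      cnr_blood_q1 = s$cnr_blood_q1, cnr_blood_q3 = s$cnr_blood_q3,
      cnr_agar_median = s$cnr_agar_median, cnr_agar_q1 = s$cnr_agar_q1,
      cnr_agar_q3 = s$cnr_agar_q3, p_vs_baseline = p,
      significant = is.finite(p) && p < alpha))
    if (length(wv))
      widths <- rbind(widths, data.frame(parameter = nm,
                                         frame = pf$frame,
                                         width_mm = wv))
  }
  detectionTable <- data.frame(parameter = character(),
                               tp_median = numeric(), tp_q1 = numeric(),
                               tp_q3 = numeric(), fp_median = numeric(),
                               fp_q1 = numeric(), fp_q3 = numeric(),
                               stringsAsFactors = FALSE)
  for (nm in names(detect)) {
    s <- detect[[nm]]@summary
    detectionTable <- rbind(detectionTable, data.frame(
      parameter = nm, tp_median = s$tp_median, tp_q1 = s$tp_q1,
      tp_q3 = s$tp_q3, fp_median = s$fp_median, fp_q1 = s$fp_q1,
      fp_q3 = s$fp_q3))
  }
  out <- list(cnrTable = cnrTable, detectionTable = detectionTable,
              comparisons = compTable, widths = widths)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(cnrTable, file.path(outDir, "cnr_table.csv"),
                     row.names = FALSE)
    utils::write.csv(detectionTable, file.path(outDir, "detection_table.csv"),
                     row.names = FALSE)
    utils::write.csv(compTable, file.path(outDir, "comparisons.csv"),
                     row.names = FALSE)
    utils::write.csv(widths, file.path(outDir, "widths.csv"),
                     row.names = FALSE)
    jsonlite::write_json(out[c("cnrTable", "detectionTable", "comparisons")],
                         file.path(outDir, "summary.json"),
                         dataframe = "rows", digits = NA, auto_unbox = TRUE)
  }
  out
}
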