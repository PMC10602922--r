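## Discrimination-factor (DF) statistics: background-subtracted fluorescence
## ratio of perfectly matched (PM) to mismatched (MM) activator conditions,
## DF = (F_PM - background) / (F_MM - background). The background series is a
## matched no-activator control, which carries the uncleaved-reporter signal.

.seriesAt <- function(series, t) {
  if (t < series@times[1] || t > series@times[length(series@times)])
    stop("evaluation time outside the series range")
  stats::approx(series@times, series@values, xout = t)$y
}

.dfOf <- function(fPm, fMm, fBg, epsilonAu) {
  denom <- fMm - fBg
  if (denom <= epsilonAu) {
    list(df = Inf, flagged = TRUE)
  } else {
    list(df = (fPm - fBg) / denom, flagged = FALSE)
  }
}

#' Discrimination factor at a given time
#'
#' Evaluates `DF = (F_PM - F_bg) / (F_MM - F_bg)` at time `t`, interpolating
#' each series linearly onto `t`. When the MM signal is within `epsilonAu` of
#' background (the best case: the mismatch is indistinguishable from no
#' activator), the DF is reported as `Inf` and flagged rather than clipped.
#'
#' @param pm,mm,bg [FluorescenceSeries-class] objects for the perfectly
#'   matched, mismatched, and no-activator background conditions.
#' @param t Evaluation time, s.
#' @param epsilonAu Guard on the MM-minus-background denominator, AU;
#'   typically about 3x the estimated noise SD.
#' @return A [DFResult-class].
#' @examples
#' s <- function(v) FluorescenceSeries(c(0, 600, 1200), c(1, v, v))
#' dfValue(discriminationFactorAt(s(10), s(2), s(1), t = 1200))  # 9
#' @export
discriminationFactorAt <- function(pm, mm, bg, t, epsilonAu = 1e-9) {
  stopifnot(is(pm, "FluorescenceSeries"), is(mm, "FluorescenceSeries"),
            is(bg, "FluorescenceSeries"))
  fPm <- .seriesAt(pm, t); fMm <- .seriesAt(mm, t); fBg <- .seriesAt(bg, t)
  d <- .dfOf(fPm, fMm, fBg, epsilonAu)
  new("DFResult", df = d$df, timeS = t, fPm = fPm, fMm = fMm, fBg = fBg,
      replicateDfs = d$df, medianDf = if (is.finite(d$df)) d$df else NA_real_,
      nInfinite = if (is.finite(d$df)) 0L else 1L, flagged = d$flagged)
}

#' DF time course
#'
#' DF evaluated at every time of the PM grid (restricted to the overlap of
#' the three series). The 20-min value, the usual reporting convention, is
#' returned as an attribute `df_at_20min` when 1200 s is inside the grid.
#'
#' @inheritParams discriminationFactorAt
#' @return data.frame with columns `time_s`, `df`, `flagged`.
#' @export
dfTimecourse <- function(pm, mm, bg, epsilonAu = 1e-9) {
  stopifnot(is(pm, "FluorescenceSeries"), is(mm, "FluorescenceSeries"),
            is(bg, "FluorescenceSeries"))
  lo <- max(pm@times[1], mm@times[1], bg@times[1])
  hi <- min(pm@times[length(pm@times)], mm@times[length(mm@times)],
            bg@times[length(bg@times)])
  tt <- pm@times[pm@times >= lo & pm@times <= hi]
  if (!length(tt)) stop("series time ranges do not overlap")
  res <- lapply(tt, function(t)
    .dfOf(.seriesAt(pm, t), .seriesAt(mm, t), .seriesAt(bg, t), epsilonAu))
  out <- data.frame(time_s = tt,
                    df = vapply(res, `[[`, numeric(1), "df"),
                    flagged = vapply(res, `[[`, logical(1), "flagged"))
  if (1200 >= lo && 1200 <= hi)
    attr(out, "df_at_20min") <- .dfOf(.seriesAt(pm, 1200), .seriesAt(mm, 1200),
                                      .seriesAt(bg, 1200), epsilonAu)$df
  out
}

#' Median DF across replicates
#'
#' Computes the DF of each replicate (PM, MM, background) triple at time `t`
#' and the median across replicates; infinite (flagged) replicates are
#' excluded from the median and counted.
#'
#' @param replicates List of replicate triples; each element a list with
#'   components `pm`, `mm`, `bg` ([FluorescenceSeries-class]).
#' @inheritParams discriminationFactorAt
#' @return A [DFResult-class] whose `df` is the median; if every replicate is
#'   flagged infinite the result carries `df = Inf` and the flag.
#' @export
medianDf <- function(replicates, t, epsilonAu = 1e-9) {
  if (!length(replicates)) stop("at least one replicate is required")
  dfs <- vapply(replicates, function(rep) {
    dfValue(discriminationFactorAt(rep$pm, rep$mm, rep$bg, t, epsilonAu))
  }, numeric(1))
  finite <- dfs[is.finite(dfs)]
  nInf <- sum(!is.finite(dfs))
  med <- if (length(finite)) stats::median(finite) else Inf
  new("DFResult", df = med, timeS = t, fPm = NA_real_, fMm = NA_real_,
      fBg = NA_real_, replicateDfs = dfs,
      medianDf = if (length(finite)) med else NA_real_,
      nInfinite = as.integer(nInf), flagged = nInf == length(dfs))
}

#' Fold change between two DF results
#'
#' Ratio of two discrimination factors, e.g. to express how much a
#' toehold-exchange design improves on plain strand displacement.
#'
#' @param dfA,dfB [DFResult-class] objects with finite DFs.
#' @return `dfValue(dfA) / dfValue(dfB)`.
#' @examples
#' a <- new("DFResult", df = 14.1, timeS = 1200, fPm = 1, fMm = 1, fBg = 0)
#' b <- new("DFResult", df = 1.0, timeS = 1200, fPm = 1, fMm = 1, fBg = 0)
#' foldChange(a, b)  # 14.1
#' @export
foldChange <- function(dfA, dfB) {
  stopifnot(is(dfA, "DFResult"), is(dfB, "DFResult"))
  if (!is.finite(dfA@df) || !is.finite(dfB@df))
    stop("fold change requires finite DFs")
  if (dfB@df == 0) stop("fold change undefined for a zero denominator DF")
  dfA@df / dfB@df
}
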