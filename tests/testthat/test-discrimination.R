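mkSeries <- function(vals, t = seq(0, by = 20, length.out = length(vals)))
  FluorescenceSeries(t, vals)

test_that("DF arithmetic matches its definition and boundary cases", {
  t <- c(0, 600, 1200)
  pm <- mkSeries(c(1, 10, 10), t); mm <- mkSeries(c(1, 2, 2), t)
  bg <- mkSeries(c(1, 1, 1), t)
  expect_equal(dfValue(discriminationFactorAt(pm, mm, bg, 1200)), 9)
  ## identical PM and MM: no discrimination
  expect_equal(dfValue(discriminationFactorAt(pm, pm, bg, 1200)), 1)
  ## MM at background: infinite sentinel, flagged
  res <- discriminationFactorAt(pm, bg, bg, 1200, epsilonAu = 1e-6)
  expect_true(is.infinite(dfValue(res)))
  expect_true(res@flagged)
  expect_error(discriminationFactorAt(pm, mm, bg, 1e6), "outside")
})

test_that("DF is invariant under a common affine rescaling", {
  t <- seq(0, 1200, by = 20)
  pm <- mkSeries(1 + 0.02 * t, t); mm <- mkSeries(1 + 0.004 * t, t)
  bg <- mkSeries(rep(1, length(t)), t)
  d0 <- dfValue(discriminationFactorAt(pm, mm, bg, 1000))
  gain <- 3.7; offset <- 11
  scale <- function(s) mkSeries(gain * fluorValues(s) + offset, t)
  d1 <- dfValue(discriminationFactorAt(scale(pm), scale(mm), scale(bg), 1000))
  expect_equal(d1, d0, tolerance = 1e-12)
})

test_that("early-time DF approaches the effective-rate ratio", {
  cr <- crrna22()
  act <- designActivator(cr)
  era <- designEra(cr, "5prime", 4)
  layPm <- buildDuplexLayout(cr, era, act)
  actMm <- designActivator(cr, mismatchPositions = layPm@bmStart + 1L)
  layMm <- buildDuplexLayout(cr, era, actMm)
  rp <- RateParams()
  ratio <- effectiveRate(layPm, rp) / effectiveRate(layMm, rp)
  sys <- ReactionSystem()
  cal <- refCalib(bg = 1)
  trPm <- simulateActivationCleavage(sys, layPm, rp, tEnd = 400)
  trMm <- simulateActivationCleavage(sys, layMm, rp, tEnd = 400)
  trBg <- simulateActivationCleavage(ReactionSystem(cActivator0 = 0), layPm,
                                     rp, tEnd = 400)
  ## both trajectories still in the linear (< 10% cleaved) regime
  expect_lt(max(speciesMatrix(trPm)[, "reporter_cleaved"]) / sys@cReporter0,
            0.1)
  d <- dfValue(discriminationFactorAt(
    observeFluorescence(trPm, cal, 0), observeFluorescence(trMm, cal, 0),
    observeFluorescence(trBg, cal, 0), 400))
  expect_equal(d, ratio, tolerance = 0.05)
})

test_that("uncontrolled Cas12a loses discrimination at the plateau", {
  ## both PM and MM saturate; DF tends to 1
  sysPm <- ReactionSystem(eraRatio = 0)
  trPm <- simulateActivationCleavage(sysPm, layoutF(7), tEnd = 4000)
  actMm <- designActivator(crrna22(), mismatchPositions = 10L)
  layMm <- buildDuplexLayout(crrna22(), designEra(crrna22(), "5prime", 7),
                             actMm)
  trMm <- simulateActivationCleavage(ReactionSystem(eraRatio = 0), layMm,
                                     tEnd = 4000)
  trBg <- simulateActivationCleavage(ReactionSystem(cActivator0 = 0),
                                     layoutF(7), tEnd = 4000)
  cal <- refCalib()
  d <- dfValue(discriminationFactorAt(
    observeFluorescence(trPm, cal, 0), observeFluorescence(trMm, cal, 0),
    observeFluorescence(trBg, cal, 0), 4000))
  expect_equal(d, 1, tolerance = 0.01)
})

test_that("median DF follows the stated replicate rules", {
  t <- c(0, 1200)
  trip <- function(pmv, mmv) list(pm = mkSeries(c(0, pmv), t),
                                  mm = mkSeries(c(0, mmv), t),
                                  bg = mkSeries(c(0, 0), t))
  reps <- list(trip(8, 1), trip(9, 1), trip(10, 1))
  res <- medianDf(reps, 1200)
  expect_equal(dfValue(res), 9)
  expect_equal(medianDf(reps[2], 1200)@df, 9)
  ## infinite replicates are excluded and counted
  repsInf <- list(trip(8, 1), trip(9, 1), trip(5, 0))
  resInf <- medianDf(repsInf, 1200, epsilonAu = 1e-6)
  expect_equal(dfValue(resInf), 8.5)
  expect_equal(resInf@nInfinite, 1L)
  ## identical stochastic replicates (same seed) give DF exactly 1
  tr <- simulateActivationCleavage(ReactionSystem(), layoutF(5), tEnd = 600)
  cal <- refCalib()
  a <- observeFluorescence(tr, cal, 0.2, seed = 11)
  b <- observeFluorescence(tr, cal, 0.2, seed = 11)
  bg <- mkSeries(rep(0, length(times(a))), times(a))
  expect_equal(dfValue(discriminationFactorAt(a, b, bg, 600)), 1)
})

test_that("fold change is a plain DF ratio with guards", {
  mk <- function(v) new("DFResult", df = v, timeS = 1200, fPm = 1, fMm = 1,
                        fBg = 0)
  expect_equal(foldChange(mk(14.1), mk(1.0)), 14.1)
  expect_equal(foldChange(mk(3), mk(3)), 1)
  expect_equal(foldChange(mk(105.2), mk(50.0)), 2.104)
  expect_error(foldChange(mk(Inf), mk(1)), "finite")
  expect_error(foldChange(mk(1), mk(0)), "zero")
})

test_that("DF time course tracks the grid and reports the 20-min value", {
  t <- seq(0, 1800, by = 20)
  pm <- mkSeries(0.02 * t, t); mm <- mkSeries(0.004 * t, t)
  bg <- mkSeries(rep(0, length(t)), t)
  tc <- dfTimecourse(pm, mm, bg, epsilonAu = 1e-9)
  expect_equal(nrow(tc), length(t))
  expect_true(all(is.finite(tc$df[-1])))
  expect_equal(attr(tc, "df_at_20min"), 5, tolerance = 1e-12)
})
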