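test_that("effective rate reproduces the toehold rate law", {
  rp <- RateParams()
  r <- function(f, dirn = "5prime", ...) effectiveRate(layoutF(f, dirn, ...), rp)
  ## 10-fold per nt below saturation: 6 nt vs 1 nt spans five orders
  expect_equal(r(6) / r(1), 1e5, tolerance = 1e-12)
  ## saturation at/above 7 nt (5')
  expect_equal(r(7), rp@kMax)
  expect_equal(r(9), rp@kMax)
  expect_gte(r(7) / rp@kMax, 0.8)
  ## nondecreasing in f
  rates <- vapply(1:10, r, numeric(1))
  expect_true(all(diff(rates) >= 0))
  ## direction rule: equal unsaturated f is slower 3' by perNtFactor^offset
  for (f in 3:6)
    expect_equal(r(f) / r(f, "3prime"), rp@perNtFactor^rp@dirOffset3p)
  ## no toehold, no activation
  cr <- crrna22()
  lay0 <- buildDuplexLayout(cr, designEra(cr, "5prime", 0), designActivator(cr))
  expect_message(expect_equal(effectiveRate(lay0, rp), 0), "no forward toehold")
  ## 3' toehold at or below the direction offset cannot nucleate
  expect_equal(r(2, "3prime"), 0)
})

test_that("mismatch factors modulate the rate as specified", {
  rp <- RateParams()
  expect_equal(alphaFactor(0, rp), 1)
  expect_equal(alphaFactor(rp@dStar, rp), rp@alphaMax)
  expect_lt(alphaFactor(10, rp), rp@alphaMax)
  expect_equal(betaFactor(0, rp), rp@betaMax)
  expect_true(all(diff(betaFactor(0:10, rp)) < 0))

  cr <- crrna22()
  act <- designActivator(cr)
  base <- buildDuplexLayout(cr, designEra(cr, "5prime", 4), act)
  ## ERA mismatch at d* boosts the rate by alphaMax exactly
  mmPos <- base@bmStart + rp@dStar
  boosted <- buildDuplexLayout(cr, designEra(cr, "5prime", 4,
                                             eraMismatches = mmPos), act)
  expect_equal(effectiveRate(boosted, rp) / effectiveRate(base, rp),
               rp@alphaMax)
  ## activator mismatch at distance d divides by beta(d)
  actMm <- designActivator(cr, mismatchPositions = base@bmStart + 1L)
  slowed <- buildDuplexLayout(cr, designEra(cr, "5prime", 4), actMm)
  expect_equal(effectiveRate(base, rp) / effectiveRate(slowed, rp),
               betaFactor(1, rp))
  ## ds activator scales by gammaDs
  dsAct <- designActivator(cr, strandedness = "ds")
  dsLay <- buildDuplexLayout(cr, designEra(cr, "5prime", 4), dsAct)
  expect_equal(effectiveRate(dsLay, rp) / effectiveRate(base, rp), rp@gammaDs)
})

test_that("closed-form low-substrate solution has the right anchors", {
  expect_equal(closedFormLowSubstrate(1, 1, 1, 500, 0), 0)
  expect_equal(closedFormLowSubstrate(1, 1, 1, 500, 500 * log(2)), 0.5)
  expect_equal(closedFormLowSubstrate(1, 1, 1, 500, 1e9), 1)
})

test_that("no activator and no background means no cleavage", {
  sys <- ReactionSystem(cActivator0 = 0, eBackground = 0)
  tr <- simulateActivationCleavage(sys, layoutF(7), tEnd = 600)
  expect_true(all(speciesMatrix(tr)[, "reporter_cleaved"] == 0))
})

test_that("ODE matches the first-order closed form when S0 << K_M", {
  sys <- cleavageOnlySystem(S0 = 1, e0 = 1)
  tr <- simulateActivationCleavage(sys, NULL, tEnd = 1000, dt = 20)
  p <- speciesMatrix(tr)[, "reporter_cleaved"][-1]
  cf <- closedFormLowSubstrate(1, 1, 1, 500, times(tr)[-1])
  expect_lt(max(abs(p - cf) / cf), 0.01)
})

test_that("trajectories conserve mass and are monotone in cleavage", {
  sys <- ReactionSystem()
  tr <- simulateActivationCleavage(sys, layoutF(5), tEnd = 2000)
  sp <- speciesMatrix(tr)
  expect_equal(sp[, "reporter_cleaved"] + sp[, "reporter_uncleaved"],
               rep(sys@cReporter0, nrow(sp)), tolerance = 1e-6)
  expect_equal(sp[, "inactive_complex"] + sp[, "active_enzyme"],
               rep(sys@cComplex0, nrow(sp)), tolerance = 1e-6)
  expect_true(all(diff(sp[, "reporter_cleaved"]) >= -1e-9))
  expect_true(all(sp >= -1e-6))
})

test_that("eraRatio controls the unprotected active fraction", {
  ## eraRatio = 0: all complexes active at t = 0, like uncontrolled Cas12a
  sys0 <- ReactionSystem(eraRatio = 0)
  tr0 <- simulateActivationCleavage(sys0, layoutF(4), tEnd = 200)
  expect_equal(unname(speciesMatrix(tr0)[1, "active_enzyme"]),
               sys0@cComplex0)
  ## eraRatio = 0.5 leaves half active immediately
  sysH <- ReactionSystem(eraRatio = 0.5)
  trH <- simulateActivationCleavage(sysH, layoutF(4), tEnd = 200)
  expect_equal(unname(speciesMatrix(trH)[1, "active_enzyme"]),
               sysH@cComplex0 / 2)
})

test_that("TE-equilibrated mode relaxes to the thermodynamic extent", {
  cr <- crrna22()
  te <- designTeEra(cr, "5prime", 7, 4)
  lay <- buildDuplexLayout(cr, te$era, te$activator)
  em <- EnergyModel()
  rp <- RateParams(kRevMode = "te_equilibrated")
  ## cleavage negligible: vanishing reporter
  sys <- ReactionSystem(cReporter0 = 1e-9, eraRatio = 1)
  tr <- simulateActivationCleavage(sys, lay, rp, em, tEnd = 3000)
  eEnd <- unname(speciesMatrix(tr)[length(times(tr)), "active_enzyme"])
  xEq <- as.numeric(equilibriumExtent(reactionDeltaG(lay, em),
                                      sys@cComplex0, sys@cActivator0, em))
  expect_equal(eEnd, xEq, tolerance = 0.02)
})

test_that("fluorescence observation is linear, offset and reproducible", {
  cal <- refCalib(bg = 2)
  sys <- cleavageOnlySystem(S0 = 125)
  tr <- simulateActivationCleavage(sys, NULL, tEnd = 600)
  ## noise-free, no cleavage: constant uncleaved signal plus background
  none <- simulateActivationCleavage(
    ReactionSystem(cActivator0 = 0, cReporter0 = 125), layoutF(7),
    tEnd = 600)
  f0 <- observeFluorescence(none, cal, 0)
  expect_equal(fluorValues(f0), rep(0.00007 * 125 + 2, length(times(f0))))
  ## fully cleaved 125 nM: F - background = 0.14466 * 125 = 18.0825 AU
  full <- new("Trajectory", times = 0,
              species = matrix(c(0, 0, 1, 0, 125, 0, 0, 0), 1,
                               dimnames = list(NULL, eraCas12a:::.TRAJ_SPECIES)))
  expect_equal(fluorValues(observeFluorescence(full, cal, 0)) - 2, 18.0825)
  ## seed contract
  a <- observeFluorescence(tr, cal, 0.1, seed = 7)
  b <- observeFluorescence(tr, cal, 0.1, seed = 7)
  c <- observeFluorescence(tr, cal, 0.1, seed = 8)
  expect_identical(fluorValues(a), fluorValues(b))
  expect_false(identical(fluorValues(a), fluorValues(c)))
})

test_that("one-pot scenarios honor the trivial limits", {
  sys <- ReactionSystem(cActivator0 = 0, cReporter0 = 500)
  ## no amplification, no target: nothing happens
  tr <- simulateOnePot(sys, list(kAmp = 0, targetPresent = FALSE),
                       layoutF(5), tEnd = 2000)
  sp <- speciesMatrix(tr)
  expect_true(all(sp[, "reporter_cleaved"] == 0))
  expect_true(all(sp[, "free_activator"] == 0))
  ## zero leak: the no-target run equals the background-only endpoint
  trL <- simulateOnePot(sys, list(leakFrac = 0, targetPresent = FALSE),
                        layoutF(5), tEnd = 2000)
  expect_equal(tail(speciesMatrix(trL)[, "reporter_cleaved"], 1), 0)
  expect_equal(speciesMatrix(trL)[, "template"],
               rep(10, length(times(trL))))
})
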