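CAL_CONCS <- c(31.25, 62.5, 125, 250, 500, 1000, 2000)

titration <- function(slope, sigma = 0, bg = 0, reps = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  do.call(rbind, lapply(seq_len(reps), function(r)
    data.frame(concentration_nM = CAL_CONCS,
               fluorescence_au = slope * CAL_CONCS + bg +
                 if (sigma > 0) rnorm(length(CAL_CONCS), 0, sigma) else 0,
               replicate = r)))
}

test_that("noise-free titrations recover the generating slopes exactly", {
  cal <- fitCalibration(titration(0.14466), titration(0.00007))
  expect_equal(mCl(cal), 0.14466, tolerance = 1e-12)
  expect_equal(mUcl(cal), 0.00007, tolerance = 1e-12)
  expect_equal(cal@r2Cl, 1)
})

test_that("noisy titrations recover the cleaved slope within 2 percent", {
  cl <- titration(0.14466, sigma = 0.05, bg = 1, reps = 3, seed = 42)
  ucl <- titration(0.00007, sigma = 0.05, bg = 1, reps = 3, seed = 43)
  cal <- fitCalibration(cl, ucl, bufferSignal = 1)
  expect_equal(mCl(cal), 0.14466, tolerance = 0.02)
  ## the uncleaved slope is below the noise floor of a 0.05-AU instrument;
  ## it must still come out non-negative and near zero
  expect_lt(abs(mUcl(cal) - 0.00007), 5e-5)
  expect_equal(background(cal), 1)
})

test_that("degenerate titrations are rejected", {
  expect_error(fitCalibration(titration(0.14466)[1:2, ], titration(0.00007)),
               "at least 3")
  bad <- titration(0.14466)
  bad$fluorescence_au <- -bad$fluorescence_au
  expect_error(fitCalibration(bad, titration(0.00007)),
               "titration inconsistent")
})

test_that("inversion reproduces the worked offsets and full-scale values", {
  cal <- refCalib()
  ## offset term m_ucl * c0 for 125 nM reporter
  expect_equal(cal@mUcl * 125, 0.00875)
  expect_equal(cal@mCl - cal@mUcl, 0.14459)
  ## fully cleaved 125 nM
  s <- FluorescenceSeries(c(0, 20), rep(18.0825 + 0.00875, 2))
  inv <- invertFluorescence(s, cal, 125)
  expect_equal(inv@cCl, c(125, 125))
  ## offset-only signal maps to zero cleaved
  s0 <- FluorescenceSeries(c(0, 20), rep(0.00875, 2))
  expect_equal(invertFluorescence(s0, cal, 125)@cCl, c(0, 0))
})

test_that("inversion is affine and clamps out-of-range points", {
  cal <- refCalib()
  f <- c(-1, 0.00875, 5, 0.14459 * 120 + 0.00875, 30)
  s <- FluorescenceSeries(seq(0, 80, by = 20), f)
  inv <- invertFluorescence(s, cal, 125)
  expect_identical(inv@clamped, c(TRUE, FALSE, FALSE, FALSE, TRUE))
  expect_true(all(inv@cCl >= 0 & inv@cCl <= 125))
  expect_equal(inv@cCl + inv@cUcl, rep(125, 5))
  ## doubling (F - offset) doubles c_cl
  s1 <- FluorescenceSeries(0, 0.00875 + 2)
  s2 <- FluorescenceSeries(0, 0.00875 + 4)
  expect_equal(invertFluorescence(s2, cal, 125)@cCl,
               2 * invertFluorescence(s1, cal, 125)@cCl)
})

test_that("degenerate calibration is rejected at inversion", {
  cal <- new("CalibrationModel", mCl = 0.1, mUcl = 0, background = 0,
             r2Cl = NA_real_, r2Ucl = NA_real_)
  cal@mUcl <- 0.1  # bypass the validity check to exercise the guard
  s <- FluorescenceSeries(0, 1)
  expect_error(invertFluorescence(s, cal, 125), "degenerate calibration")
})

test_that("cleavage velocity converts AU/s through 1/(mCl - mUcl)", {
  cal <- refCalib()
  t <- seq(0, 200, by = 20)
  ramp <- FluorescenceSeries(t, 0.14459 * t)
  v <- cleavageVelocity(ramp, cal)
  expect_equal(v$velocity_nM_s, rep(1, length(t)))
  flat <- FluorescenceSeries(t, rep(3, length(t)))
  expect_equal(cleavageVelocity(flat, cal)$velocity_nM_s, rep(0, length(t)))
})

test_that("inversion round-trips a noise-free observation of the simulator", {
  cal <- refCalib(bg = 1.5)
  sys <- ReactionSystem()
  tr <- simulateActivationCleavage(sys, layoutF(6), tEnd = 1200)
  fs <- observeFluorescence(tr, cal, 0)
  inv <- invertFluorescence(fs, cal, sys@cReporter0)
  expect_equal(inv@cCl, unname(speciesMatrix(tr)[, "reporter_cleaved"]),
               tolerance = 1e-9)
  ## velocity of the inverted series equals the numeric derivative
  v <- cleavageVelocity(fs, cal)
  dcdt <- diff(inv@cCl) / diff(times(fs))
  expect_equal(v$velocity_nM_s[1], dcdt[1], tolerance = 1e-9)
})
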