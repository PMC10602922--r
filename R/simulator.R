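## ODE simulator of toehold-gated Cas12a activation and Michaelis-Menten
## trans-cleavage. Concentrations are in nM and time in seconds; effective
## displacement rates are in /M/s and converted internally (x 1e-9).

#' ERA-mismatch acceleration factor
#'
#' Fold-acceleration of displacement contributed by one ERA mismatch at
#' distance `d` from the toehold:
#' `alpha(d) = 1 + (alphaMax - 1) * (d / dStar) * exp(1 - d / dStar)`,
#' a bump that equals 1 at `d = 0` (a mismatch eliminated immediately gives
#' no boost) and peaks at `alphaMax` when the mismatch is eliminated early,
#' at `d = dStar`.
#'
#' @param d Distance in nt from the forward-toehold-proximal bm boundary.
#' @param params A [RateParams-class].
#' @return Dimensionless factor >= 1.
#' @export
alphaFactor <- function(d, params = RateParams()) {
  1 + (params@alphaMax - 1) * (d / params@dStar) * exp(1 - d / params@dStar)
}

#' Activator-mismatch penalty factor
#'
#' Fold-slowdown contributed by one activator mismatch at distance `d`:
#' `beta(d) = 1 + (betaMax - 1) * exp(-d / lambdaM)`; strongest next to the
#' toehold, decaying with distance (the kinetic origin of toehold-proximal
#' single-base discrimination).
#'
#' @inheritParams alphaFactor
#' @return Dimensionless factor >= 1.
#' @export
betaFactor <- function(d, params = RateParams()) {
  1 + (params@betaMax - 1) * exp(-d / params@lambdaM)
}

#' Effective displacement/activation rate of a layout
#'
#' Computes the effective second-order rate at which the activator displaces
#' the ERA and activates Cas12a. The effective toehold is
#' `n_eff = f - dirOffset3p` for 3' toeholds (f otherwise); the base rate is
#' `kMax * perNtFactor^min(0, n_eff - nSat5p)`: exponential in the toehold
#' length below saturation, exactly `kMax` at or above it. Each ERA mismatch
#' multiplies the rate by [alphaFactor()], each activator mismatch divides it
#' by [betaFactor()], and double-stranded activators are scaled by `gammaDs`.
#' A layout with no bindable forward toehold (f = 0, or an effective toehold
#' of zero or less) cannot nucleate displacement and returns 0.
#'
#' @param layout A [DuplexLayout-class].
#' @param params A [RateParams-class].
#' @return Rate in /M/s.
#' @examples
#' lay <- function(f) DuplexLayout("5prime", f, 15, 30)
#' effectiveRate(lay(6)) / effectiveRate(lay(1))  # 1e5
#' effectiveRate(lay(7))                          # kMax
#' @export
effectiveRate <- function(layout, params = RateParams()) {
  stopifnot(is(layout, "DuplexLayout"))
  f <- layout@toeholdLengthF
  if (f == 0L) {
    message("no forward toehold: activation rate is 0")
    return(0)
  }
  nEff <- f - if (layout@toeholdDirection == "3prime") params@dirOffset3p else 0
  if (nEff <= 0) return(0)
  rate <- params@kMax * params@perNtFactor^(min(0, nEff - params@nSat5p))
  for (d in layout@eraMismatchDistances)
    rate <- rate * alphaFactor(d, params)
  for (d in layout@activatorMismatchDistances)
    rate <- rate / betaFactor(d, params)
  if (layout@dsActivator) rate <- rate * params@gammaDs
  rate
}

#' Closed-form product curve in the low-substrate limit
#'
#' When `S << K_M` the Michaelis-Menten law reduces to first order,
#' `d[P]/dt = (k_cat E0 / K_M)(S0 - [P])`, whose solution is
#' `P(t) = S0 (1 - exp(-k_cat E0 t / K_M))`.
#'
#' @param E0 Activated enzyme, nM.
#' @param S0 Initial substrate (reporter), nM.
#' @param kCat /s.
#' @param KM nM.
#' @param t Time(s), s.
#' @return Cleaved product concentration(s), nM.
#' @examples
#' closedFormLowSubstrate(1, 1, 1, 500, 500 * log(2))  # 0.5
#' @export
closedFormLowSubstrate <- function(E0, S0, kCat, KM, t) {
  stopifnot(E0 > 0, S0 > 0, kCat > 0, KM > 0)
  S0 * (1 - exp(-kCat * E0 * t / KM))
}

## shared RHS for the activation + cleavage ODE; one-pot terms optional
.odeRhs <- function(t, y, p) {
  C <- y[["C"]]; A <- y[["A"]]; E <- y[["E"]]; P <- y[["P"]]
  S <- max(p$S0 - P, 0)
  fwd <- p$k * C * A
  rel <- max(E - p$Einit, 0)            # enzyme activated by displacement,
  rev <- p$krev * rel * rel             # paired 1:1 with released free ERA
  dC <- -fwd + rev
  dA <- -fwd + rev
  dE <- fwd - rev
  dP <- p$kcat * E * S / (p$KM + S)
  if (p$onePot) {
    Tm <- y[["T"]]; Pr <- y[["Pr"]]
    prod <- p$kAmp * Tm * p$targetGain
    dA <- dA + prod
    kill <- if (p$templateCleavage) p$kcatOverKM * E else 0
    dT <- -kill * Tm
    dPr <- -kill * Pr
    dM <- prod
    list(c(dC, dA, dE, dP, dT, dPr, dM))
  } else {
    list(c(dC, dA, dE, dP))
  }
}

.integrate <- function(y0, tEnd, dt, p) {
  grid <- seq(0, tEnd, by = dt)
  out <- deSolve::ode(y = y0, times = grid, func = .odeRhs, parms = p,
                      method = "lsoda", rtol = 1e-8, atol = 1e-12)
  if (attr(out, "istate")[1] < 0)
    stop("ODE solver failed; parameters: ",
         paste(names(p), vapply(p, function(z) format(z[1]), ""),
               sep = "=", collapse = ", "))
  out <- as.data.frame(out)
  if (min(as.matrix(out[-1])) < -1e-6)
    stop("negative concentrations beyond tolerance in ODE solution")
  out
}

.asTrajectory <- function(out, p) {
  n <- nrow(out)
  sp <- matrix(0, n, length(.TRAJ_SPECIES),
               dimnames = list(NULL, .TRAJ_SPECIES))
  sp[, "inactive_complex"] <- pmax(out$C, 0)
  sp[, "free_activator"] <- pmax(out$A, 0)
  sp[, "active_enzyme"] <- pmax(out$E, 0)
  sp[, "reporter_cleaved"] <- pmin(pmax(out$P, 0), p$S0)
  sp[, "reporter_uncleaved"] <- p$S0 - sp[, "reporter_cleaved"]
  if (!is.null(out$T)) {
    sp[, "template"] <- pmax(out$T, 0)
    sp[, "primer"] <- pmax(out$Pr, 0)
    sp[, "amplicon"] <- pmax(out$M, 0)
  }
  new("Trajectory", times = out$time, species = sp, params = p)
}

.rateAndInit <- function(system, layout, rateParams, energy) {
  kEff <- if (is.null(layout)) rateParams@kMax
          else effectiveRate(layout, rateParams)
  ## without a protector the complex is activatable (binds activator at the
  ## saturated rate) but not yet active; with sub-stoichiometric ERA the
  ## unprotected fraction of complexes is active from t = 0
  unprot <- if (is.null(layout)) 0 else max(0, 1 - system@eraRatio)
  Einit <- system@eBackground + unprot * system@cComplex0
  krev <- 0
  if (!is.null(layout) && rateParams@kRevMode == "te_equilibrated") {
    K <- exp(max(min(-reactionDeltaG(layout, energy) / rt(energy), 700), -700))
    krev <- kEff * 1e-9 / K
  }
  list(k = kEff * 1e-9, krev = krev, Einit = Einit,
       C0 = system@cComplex0 - unprot * system@cComplex0)
}

#' Simulate ERA-gated activation and trans-cleavage
#'
#' Integrates mass-action activation (`dC/dt = -k_eff C A`, plus the reverse
#' displacement when `kRevMode = "te_equilibrated"`, with
#' `k_rev = k_eff / K_eq`) coupled to Michaelis-Menten reporter cleavage by
#' the active enzyme. With a sub-stoichiometric ERA ratio the unprotected
#' fraction `max(0, 1 - eraRatio)` of complexes starts active; `eraRatio = 0`
#' (or `layout = NULL` with activator pre-bound) reproduces uncontrolled
#' Cas12a.
#'
#' @param system A [ReactionSystem-class].
#' @param layout A [DuplexLayout-class], or `NULL` for uncontrolled Cas12a
#'   (activator binds at the saturated rate, no protector).
#' @param rateParams A [RateParams-class].
#' @param energy An [EnergyModel-class] (used only in TE-equilibrated mode).
#' @param tEnd End time, s.
#' @param dt Output grid step, s (default 20, the plate-reader interval).
#' @return A [Trajectory-class]; cleaved + uncleaved reporter is conserved at
#'   every time point, as is complex + active enzyme.
#' @export
simulateActivationCleavage <- function(system, layout, rateParams = RateParams(),
                                       energy = EnergyModel(), tEnd = 1200,
                                       dt = 20) {
  stopifnot(is(system, "ReactionSystem"), tEnd > 0, dt > 0)
  ri <- .rateAndInit(system, layout, rateParams, energy)
  p <- list(k = ri$k, krev = ri$krev, Einit = ri$Einit, S0 = system@cReporter0,
            kcat = system@kCat, KM = system@kM, onePot = FALSE)
  y0 <- c(C = ri$C0, A = system@cActivator0, E = ri$Einit, P = 0)
  .asTrajectory(.integrate(y0, tEnd, dt, p), p)
}

#' Simulate a one-pot amplification plus CRISPR readout
#'
#' Adds a coarse isothermal-amplification program to the activation/cleavage
#' system: templates produce activator at `kAmp` per second (scaled by
#' `leakFrac` when the target is absent), while the active enzyme's
#' indiscriminate trans-cleavage destroys templates and primers at the
#' second-order rate `k_cat/K_M * E` (the negative feedback that cripples
#' uncontrolled one-pot assays). A slow (short-toehold) layout delays the
#' rise of active enzyme, preserving templates and letting amplification run.
#'
#' @inheritParams simulateActivationCleavage
#' @param per Named list of amplification parameters: `kAmp` (/s per
#'   template), `leakFrac` (dimensionless), `template0` (nM), `primer0` (nM),
#'   `targetPresent` (logical).
#' @param templateCleavage Logical; set `FALSE` to decouple trans-cleavage
#'   from the amplification species (a physically separated, two-step-like
#'   reference).
#' @return A [Trajectory-class] including template/primer/amplicon columns.
#' @export
simulateOnePot <- function(system, per = list(), layout = NULL,
                           rateParams = RateParams(), energy = EnergyModel(),
                           tEnd = 10800, dt = 20, templateCleavage = TRUE) {
  stopifnot(is(system, "ReactionSystem"), tEnd > 0, dt > 0)
  per <- utils::modifyList(list(kAmp = 3e-5, leakFrac = 0.05, template0 = 10,
                                primer0 = 200, targetPresent = TRUE), per)
  if (per$kAmp < 0 || per$leakFrac < 0 || per$template0 < 0 || per$primer0 < 0)
    stop("per parameters must be >= 0")
  ri <- .rateAndInit(system, layout, rateParams, energy)
  p <- list(k = ri$k, krev = ri$krev, Einit = ri$Einit, S0 = system@cReporter0,
            kcat = system@kCat, KM = system@kM, onePot = TRUE,
            kAmp = per$kAmp,
            targetGain = if (isTRUE(per$targetPresent)) 1 else per$leakFrac,
            kcatOverKM = system@kCat / system@kM,
            templateCleavage = isTRUE(templateCleavage))
  y0 <- c(C = ri$C0, A = system@cActivator0, E = ri$Einit, P = 0,
          T = per$template0, Pr = per$primer0, M = 0)
  .asTrajectory(.integrate(y0, tEnd, dt, p), p)
}

#' Observe a trajectory as a fluorescence series
#'
#' Applies the linear fluorescence model
#' `F(t) = mCl * c_cl(t) + mUcl * c_ucl(t) + background + noise` with i.i.d.
#' Gaussian noise of SD `sigmaAu`, reproducible under `seed` (the caller's
#' RNG state is left untouched).
#'
#' @param traj A [Trajectory-class].
#' @param calib A [CalibrationModel-class].
#' @param sigmaAu Noise SD in AU (>= 0).
#' @param seed Integer seed, or `NULL` to use (and advance) the session RNG.
#' @param metadata Named list attached to the result.
#' @return A [FluorescenceSeries-class] on the trajectory grid.
#' @export
observeFluorescence <- function(traj, calib, sigmaAu = 0, seed = NULL,
                                metadata = list()) {
  stopifnot(is(traj, "Trajectory"), is(calib, "CalibrationModel"),
            sigmaAu >= 0)
  sp <- traj@species
  f <- calib@mCl * sp[, "reporter_cleaved"] +
       calib@mUcl * sp[, "reporter_uncleaved"] + calib@background
  if (sigmaAu > 0) {
    eps <- .withSeed(seed, stats::rnorm(length(f), 0, sigmaAu))
    f <- f + eps
  }
  FluorescenceSeries(traj@times, f, background = calib@background,
                     metadata = metadata)
}

## evaluate expr under a temporary RNG state when seed is non-NULL
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  expr <- substitute(expr)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval(expr, envir = parent.frame())
}
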