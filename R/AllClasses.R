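#' @importClassesFrom Biostrings RNAString DNAString
#' @import methods
NULL

## gas constant in kcal/mol/K, used wherever RT is needed
.R_KCAL <- 0.0019872

#' crRNA specification
#'
#' Holds the spacer (target-recognition) region of a Cas12a crRNA as an RNA
#' sequence. Spacer positions are 1-based from the spacer 5' end; the 5' side
#' faces the protein's PI domain, the 3' side the Nuc domain.
#'
#' @slot spacer An [Biostrings::RNAString-class] with the spacer sequence.
#' @slot name Character label.
#' @export
setClass("CrRNASpec",
  representation(spacer = "RNAString", name = "character"),
  prototype(name = "crRNA"))

setValidity("CrRNASpec", function(object) {
  if (length(object@spacer) < 10L)
    return("spacer must be at least 10 nt")
  TRUE
})

#' Construct a crRNA specification
#'
#' @param spacer RNA spacer sequence: a character string over `ACGU` (a `T` is
#'   accepted and normalized to `U`) or an [Biostrings::RNAString-class].
#' @param name Label for the record.
#' @return A [CrRNASpec-class] object.
#' @examples
#' CrRNASpec("ACGUACGUACGUACGUACGUAC")
#' @export
CrRNASpec <- function(spacer, name = "crRNA") {
  if (is.character(spacer))
    spacer <- Biostrings::RNAString(gsub("T", "U", toupper(spacer)))
  new("CrRNASpec", spacer = spacer, name = name)
}

#' ERA (external RNA accessory) specification
#'
#' An ERA is an RNA protector strand pairing with a contiguous span of the
#' crRNA spacer, optionally with declared mismatches. The unpaired spacer
#' positions on one side of the span form the displacement toehold.
#'
#' @slot sequence [Biostrings::RNAString-class]; the ERA written 5' to 3'.
#' @slot pairedSpan Integer length-2 vector; 1-based closed interval of spacer
#'   positions the ERA pairs with (5' to 3' of the spacer).
#' @slot mismatchPositions Integer vector of spacer positions (inside
#'   `pairedSpan`) at which the ERA is deliberately non-complementary.
#' @slot name Character label.
#' @export
setClass("ERASpec",
  representation(sequence = "RNAString", pairedSpan = "integer",
                 mismatchPositions = "integer", name = "character"),
  prototype(mismatchPositions = integer(0), name = "ERA"))

setValidity("ERASpec", function(object) {
  sp <- object@pairedSpan
  if (length(sp) != 2L || sp[1] > sp[2] || sp[1] < 1L)
    return("pairedSpan must be a valid 1-based closed interval")
  if (length(object@sequence) != sp[2] - sp[1] + 1L)
    return("ERA length must equal the paired-span length")
  mm <- object@mismatchPositions
  if (length(mm) && (any(mm < sp[1]) || any(mm > sp[2])))
    return("mismatch positions must lie inside the paired span")
  TRUE
})

#' @rdname ERASpec-class
#' @param sequence,pairedSpan,mismatchPositions,name See slots.
#' @return An [ERASpec-class] object.
#' @export
ERASpec <- function(sequence, pairedSpan, mismatchPositions = integer(0),
                    name = "ERA") {
  if (is.character(sequence))
    sequence <- Biostrings::RNAString(gsub("T", "U", toupper(sequence)))
  new("ERASpec", sequence = sequence, pairedSpan = as.integer(pairedSpan),
      mismatchPositions = as.integer(sort(mismatchPositions)), name = name)
}

#' Activator specification
#'
#' The single- or double-stranded DNA whose binding to the crRNA spacer
#' switches Cas12a on. Deletions are declared in spacer coordinates: the
#' number of spacer positions left uncovered at the spacer 5' or 3' end
#' (a deletion at the spacer 3' end corresponds to a truncation of the
#' activator strand's own 5' end, since the strands pair antiparallel).
#'
#' @slot sequence [Biostrings::DNAString-class]; activator written 5' to 3'.
#' @slot strandedness `"ss"` or `"ds"`.
#' @slot mismatchPositions Integer spacer positions mismatched to the crRNA.
#' @slot deletion5p,deletion3p Integer nt of spacer left uncovered at the
#'   spacer 5' / 3' end.
#' @slot name Character label.
#' @export
setClass("ActivatorSpec",
  representation(sequence = "DNAString", strandedness = "character",
                 mismatchPositions = "integer", deletion5p = "integer",
                 deletion3p = "integer", name = "character"),
  prototype(strandedness = "ss", mismatchPositions = integer(0),
            deletion5p = 0L, deletion3p = 0L, name = "activator"))

setValidity("ActivatorSpec", function(object) {
  if (!object@strandedness %in% c("ss", "ds"))
    return("strandedness must be 'ss' or 'ds'")
  if (object@deletion5p < 0L || object@deletion3p < 0L)
    return("deletions must be >= 0")
  TRUE
})

#' @rdname ActivatorSpec-class
#' @param sequence,strandedness,mismatchPositions,deletion5p,deletion3p,name
#'   See slots.
#' @return An [ActivatorSpec-class] object.
#' @export
ActivatorSpec <- function(sequence, strandedness = "ss",
                          mismatchPositions = integer(0),
                          deletion5p = 0L, deletion3p = 0L,
                          name = "activator") {
  if (is.character(sequence))
    sequence <- Biostrings::DNAString(gsub("U", "T", toupper(sequence)))
  new("ActivatorSpec", sequence = sequence, strandedness = strandedness,
      mismatchPositions = as.integer(sort(mismatchPositions)),
      deletion5p = as.integer(deletion5p), deletion3p = as.integer(deletion3p),
      name = name)
}

#' Geometric layout of an ERA-crRNA duplex
#'
#' Describes the strand-displacement geometry implied by a crRNA, ERA and
#' activator: direction and length of the forward toehold, length of the
#' reverse toehold (toehold exchange), branch-migration (bm) domain length and
#' position, and the distances of declared mismatches from the
#' forward-toehold-proximal end of the bm domain (0 = immediately adjacent to
#' the toehold).
#'
#' @slot toeholdDirection `"5prime"` or `"3prime"`: the spacer end carrying
#'   the forward toehold.
#' @slot toeholdLengthF Integer nt; forward toehold exposed before
#'   displacement.
#' @slot toeholdLengthR Integer nt; reverse toehold exposed after toehold
#'   exchange (0 for plain strand displacement).
#' @slot bmLength Integer nt; branch-migration domain length.
#' @slot bmStart Integer; 1-based spacer position where the bm domain begins.
#' @slot spacerLength Integer nt.
#' @slot eraMismatchDistances,activatorMismatchDistances Integer distances of
#'   each mismatch from the forward-toehold-proximal bm boundary.
#' @slot dsActivator Logical; whether the activator is double-stranded.
#' @export
setClass("DuplexLayout",
  representation(toeholdDirection = "character", toeholdLengthF = "integer",
                 toeholdLengthR = "integer", bmLength = "integer",
                 bmStart = "integer", spacerLength = "integer",
                 eraMismatchDistances = "integer",
                 activatorMismatchDistances = "integer",
                 dsActivator = "logical"),
  prototype(toeholdLengthR = 0L, eraMismatchDistances = integer(0),
            activatorMismatchDistances = integer(0), dsActivator = FALSE))

setValidity("DuplexLayout", function(object) {
  if (!object@toeholdDirection %in% c("5prime", "3prime"))
    return("toeholdDirection must be '5prime' or '3prime'")
  if (object@toeholdLengthF < 0L || object@toeholdLengthR < 0L)
    return("toehold lengths must be >= 0")
  if (object@bmLength < 1L)
    return("bmLength must be >= 1")
  d <- c(object@eraMismatchDistances, object@activatorMismatchDistances)
  if (length(d) && (any(d < 0L) || any(d >= object@bmLength)))
    return("mismatch distances must lie in [0, bmLength - 1]")
  if (object@toeholdLengthF + object@bmLength > object@spacerLength)
    return("toeholdLengthF + bmLength must not exceed spacerLength")
  TRUE
})

#' @rdname DuplexLayout-class
#' @param toeholdDirection,toeholdLengthF,toeholdLengthR,bmLength,bmStart
#'   See slots.
#' @param spacerLength,eraMismatchDistances,activatorMismatchDistances,dsActivator
#'   See slots.
#' @return A [DuplexLayout-class] object.
#' @export
DuplexLayout <- function(toeholdDirection, toeholdLengthF, bmLength,
                         spacerLength, toeholdLengthR = 0L,
                         bmStart = NA_integer_,
                         eraMismatchDistances = integer(0),
                         activatorMismatchDistances = integer(0),
                         dsActivator = FALSE) {
  toeholdDirection <- match.arg(toeholdDirection, c("5prime", "3prime"))
  if (is.na(bmStart)) {
    ## default: bm domain flush against the forward toehold
    bmStart <- if (toeholdDirection == "5prime")
      as.integer(toeholdLengthF) + 1L else 1L
  }
  new("DuplexLayout", toeholdDirection = toeholdDirection,
      toeholdLengthF = as.integer(toeholdLengthF),
      toeholdLengthR = as.integer(toeholdLengthR),
      bmLength = as.integer(bmLength), bmStart = as.integer(bmStart),
      spacerLength = as.integer(spacerLength),
      eraMismatchDistances = as.integer(sort(eraMismatchDistances)),
      activatorMismatchDistances = as.integer(sort(activatorMismatchDistances)),
      dsActivator = dsActivator)
}

#' Simplified duplex free-energy model
#'
#' Sequence-averaged per-nucleotide stacking model: every paired nucleotide
#' contributes a fixed negative free energy (different for RNA-RNA and
#' RNA-DNA hybrids), every forward-toehold nucleotide a fixed stabilization
#' of the displacement reaction, and every mismatch a fixed positive penalty.
#' All energies are in kcal/mol at `temperatureK`.
#'
#' @slot dgBpRnaRna,dgBpRnaDna kcal/mol per paired nt (negative).
#' @slot dgToeholdPerNt kcal/mol per forward-toehold nt (negative; the default
#'   is -RT ln 10, i.e. one order of magnitude of equilibrium per nt).
#' @slot ddgMismatch kcal/mol destabilization per mismatch (positive).
#' @slot temperatureK Temperature in kelvin.
#' @export
setClass("EnergyModel",
  representation(dgBpRnaRna = "numeric", dgBpRnaDna = "numeric",
                 dgToeholdPerNt = "numeric", ddgMismatch = "numeric",
                 temperatureK = "numeric"))

setValidity("EnergyModel", function(object) {
  if (object@dgBpRnaRna >= 0 || object@dgBpRnaDna >= 0)
    return("per-nt pairing free energies must be negative")
  if (object@dgToeholdPerNt >= 0)
    return("dgToeholdPerNt must be negative")
  if (object@ddgMismatch <= 0)
    return("ddgMismatch must be positive")
  if (object@temperatureK <= 0)
    return("temperatureK must be positive")
  TRUE
})

#' @rdname EnergyModel-class
#' @param dgBpRnaRna,dgBpRnaDna,dgToeholdPerNt,ddgMismatch,temperatureK
#'   See slots.
#' @return An [EnergyModel-class] object.
#' @examples
#' em <- EnergyModel()
#' rt(em)  # ~0.5925 kcal/mol at 298.15 K
#' @export
EnergyModel <- function(dgBpRnaRna = -2.1, dgBpRnaDna = -1.8,
                        dgToeholdPerNt = -.R_KCAL * 298.15 * log(10),
                        ddgMismatch = 3.0, temperatureK = 298.15) {
  new("EnergyModel", dgBpRnaRna = dgBpRnaRna, dgBpRnaDna = dgBpRnaDna,
      dgToeholdPerNt = dgToeholdPerNt, ddgMismatch = ddgMismatch,
      temperatureK = temperatureK)
}

#' Kinetic parameters of toehold-mediated activation
#'
#' Governs the effective second-order displacement/activation rate derived
#' from a [DuplexLayout-class]. In the unsaturated regime each additional
#' forward-toehold nucleotide speeds the reaction by `perNtFactor`; the rate
#' saturates at `kMax` once the effective toehold reaches `nSat5p` nt. A 3'
#' toehold is penalized by `dirOffset3p` effective nucleotides. ERA mismatches
#' accelerate displacement (peak factor `alphaMax` at distance `dStar` from
#' the toehold); activator mismatches slow it (factor up to `betaMax`,
#' decaying with distance over `lambdaM` nt).
#'
#' @slot kMax /M/s saturated effective rate.
#' @slot perNtFactor Fold-change per forward-toehold nt (unsaturated).
#' @slot nSat5p nt at which the 5'-toehold rate saturates.
#' @slot dirOffset3p Effective-toehold penalty (nt) for 3' toeholds.
#' @slot alphaMax Peak fold-acceleration from an ERA mismatch.
#' @slot dStar Distance (nt) of peak acceleration.
#' @slot betaMax Maximal fold-penalty for an activator mismatch at distance 0.
#' @slot lambdaM Decay length (nt) of the activator-mismatch penalty.
#' @slot gammaDs Rate multiplier for double-stranded activators.
#' @slot kRevMode `"irreversible"` or `"te_equilibrated"` (adds the reverse
#'   displacement reaction with rate set by the layout's reaction free energy).
#' @export
setClass("RateParams",
  representation(kMax = "numeric", perNtFactor = "numeric", nSat5p = "numeric",
                 dirOffset3p = "numeric", alphaMax = "numeric",
                 dStar = "numeric", betaMax = "numeric", lambdaM = "numeric",
                 gammaDs = "numeric", kRevMode = "character"))

setValidity("RateParams", function(object) {
  if (object@kMax <= 0) return("kMax must be > 0")
  if (object@perNtFactor <= 1) return("perNtFactor must be > 1")
  if (object@alphaMax < 1) return("alphaMax must be >= 1")
  if (object@betaMax < 1) return("betaMax must be >= 1")
  if (object@gammaDs <= 0 || object@gammaDs > 1)
    return("gammaDs must be in (0, 1]")
  if (!object@kRevMode %in% c("irreversible", "te_equilibrated"))
    return("kRevMode must be 'irreversible' or 'te_equilibrated'")
  TRUE
})

#' @rdname RateParams-class
#' @param kMax,perNtFactor,nSat5p,dirOffset3p,alphaMax,dStar,betaMax,lambdaM
#'   See slots.
#' @param gammaDs,kRevMode See slots.
#' @return A [RateParams-class] object.
#' @export
RateParams <- function(kMax = 1e6, perNtFactor = 10, nSat5p = 7,
                       dirOffset3p = 2, alphaMax = 100, dStar = 2,
                       betaMax = 50, lambdaM = 3, gammaDs = 0.3,
                       kRevMode = c("irreversible", "te_equilibrated")) {
  kRevMode <- match.arg(kRevMode)
  new("RateParams", kMax = kMax, perNtFactor = perNtFactor, nSat5p = nSat5p,
      dirOffset3p = dirOffset3p, alphaMax = alphaMax, dStar = dStar,
      betaMax = betaMax, lambdaM = lambdaM, gammaDs = gammaDs,
      kRevMode = kRevMode)
}

#' Reaction system composition
#'
#' Concentrations and enzymatic constants of a trans-cleavage assay. Defaults
#' follow the standard reaction mix: 20 nM ERA-crRNA-Cas12a complex, 40 nM
#' activator, 250 nM fluorogenic reporter, ERA annealed at a 2:1 ratio to the
#' crRNA.
#'
#' @slot cComplex0 nM ERA-crRNA-Cas12a complex.
#' @slot cActivator0 nM activator.
#' @slot cReporter0 nM uncleaved reporter (the substrate S0).
#' @slot eBackground nM pre-activated enzyme (leak).
#' @slot kCat Turnover number, /s.
#' @slot kM Michaelis constant, nM.
#' @slot eraRatio ERA:crRNA stoichiometric ratio; values below 1 leave the
#'   unprotected fraction of complexes active from t = 0.
#' @slot temperatureK Temperature in kelvin.
#' @export
setClass("ReactionSystem",
  representation(cComplex0 = "numeric", cActivator0 = "numeric",
                 cReporter0 = "numeric", eBackground = "numeric",
                 kCat = "numeric", kM = "numeric", eraRatio = "numeric",
                 temperatureK = "numeric"))

setValidity("ReactionSystem", function(object) {
  if (object@cComplex0 < 0 || object@cActivator0 < 0 ||
      object@cReporter0 < 0 || object@eBackground < 0)
    return("concentrations must be >= 0")
  if (object@kCat <= 0) return("kCat must be > 0")
  if (object@kM <= 0) return("kM must be > 0")
  if (object@eraRatio < 0) return("eraRatio must be >= 0")
  TRUE
})

#' @rdname ReactionSystem-class
#' @param cComplex0,cActivator0,cReporter0,eBackground,kCat,kM,eraRatio
#'   See slots.
#' @param temperatureK See slots.
#' @return A [ReactionSystem-class] object.
#' @export
ReactionSystem <- function(cComplex0 = 20, cActivator0 = 40, cReporter0 = 250,
                           eBackground = 0, kCat = 1.0, kM = 500,
                           eraRatio = 2.0, temperatureK = 298.15) {
  new("ReactionSystem", cComplex0 = cComplex0, cActivator0 = cActivator0,
      cReporter0 = cReporter0, eBackground = eBackground, kCat = kCat,
      kM = kM, eraRatio = eraRatio, temperatureK = temperatureK)
}

.TRAJ_SPECIES <- c("inactive_complex", "free_activator", "active_enzyme",
                   "reporter_uncleaved", "reporter_cleaved", "template",
                   "primer", "amplicon")

#' Time-resolved species concentrations
#'
#' Output of the simulator: a uniform time grid and per-time concentrations
#' (nM) of the tracked species: inactive complex, free activator, active
#' enzyme, uncleaved/cleaved reporter, and (for one-pot runs) template, primer
#' and cumulative amplicon.
#'
#' @slot times Seconds, uniform grid.
#' @slot species Numeric matrix, one column per species.
#' @slot params List echoing the generating parameters.
#' @export
setClass("Trajectory",
  representation(times = "numeric", species = "matrix", params = "list"),
  prototype(params = list()))

setValidity("Trajectory", function(object) {
  if (nrow(object@species) != length(object@times))
    return("species must have one row per time point")
  if (!all(.TRAJ_SPECIES %in% colnames(object@species)))
    return("species matrix is missing required columns")
  if (min(object@species) < -1e-6)
    return("species concentrations must be >= 0 (within solver tolerance)")
  TRUE
})

#' Observed fluorescence time series
#'
#' A plate-reader-style series in arbitrary units (AU) on a strictly
#' increasing time grid, with an associated background (buffer-only) level,
#' either scalar or per time point.
#'
#' @slot times Seconds.
#' @slot values AU.
#' @slot background AU; scalar or same length as `times`.
#' @slot metadata Named list of condition labels.
#' @export
setClass("FluorescenceSeries",
  representation(times = "numeric", values = "numeric",
                 background = "numeric", metadata = "list"),
  prototype(background = 0, metadata = list()))

setValidity("FluorescenceSeries", function(object) {
  if (length(object@values) != length(object@times))
    return("times and values must have equal length")
  if (length(object@times) > 1 && any(diff(object@times) <= 0))
    return("times must be strictly increasing")
  if (!length(object@background) %in% c(1L, length(object@times)))
    return("background must be scalar or match the time grid")
  TRUE
})

#' @rdname FluorescenceSeries-class
#' @param times,values,background,metadata See slots.
#' @return A [FluorescenceSeries-class] object.
#' @export
FluorescenceSeries <- function(times, values, background = 0,
                               metadata = list()) {
  new("FluorescenceSeries", times = as.numeric(times),
      values = as.numeric(values), background = as.numeric(background),
      metadata = metadata)
}

#' Cleaved/uncleaved reporter concentration series
#'
#' Result of inverting a fluorescence series through a calibration model:
#' cleaved and uncleaved reporter concentrations on the same grid, summing to
#' the initial reporter concentration `c0` pointwise. Values falling outside
#' `[0, c0]` are clamped and flagged.
#'
#' @slot times Seconds.
#' @slot cCl,cUcl nM cleaved / uncleaved reporter.
#' @slot c0 nM initial reporter.
#' @slot clamped Logical per-point clamp flags.
#' @export
setClass("ConcentrationSeries",
  representation(times = "numeric", cCl = "numeric", cUcl = "numeric",
                 c0 = "numeric", clamped = "logical"))

setValidity("ConcentrationSeries", function(object) {
  n <- length(object@times)
  if (length(object@cCl) != n || length(object@cUcl) != n ||
      length(object@clamped) != n)
    return("all series must share the time grid")
  if (any(abs(object@cCl + object@cUcl - object@c0) > 1e-6 * max(object@c0, 1)))
    return("cCl + cUcl must equal c0 pointwise")
  TRUE
})

#' @rdname ConcentrationSeries-class
#' @param times,cCl,cUcl,c0,clamped See slots.
#' @return A [ConcentrationSeries-class] object.
#' @export
ConcentrationSeries <- function(times, cCl, cUcl, c0,
                                clamped = rep(FALSE, length(times))) {
  new("ConcentrationSeries", times = as.numeric(times), cCl = as.numeric(cCl),
      cUcl = as.numeric(cUcl), c0 = c0, clamped = clamped)
}

#' Fluorescence-per-concentration calibration
#'
#' Linear calibration mapping reporter concentrations to fluorescence:
#' `F = mCl * cCl + mUcl * cUcl + background`. The uncleaved slope is nonzero
#' because quenching in the intact reporter is imperfect.
#'
#' @slot mCl AU/nM slope for cleaved reporters.
#' @slot mUcl AU/nM slope for uncleaved reporters.
#' @slot background AU buffer-only signal.
#' @slot r2Cl,r2Ucl Goodness of fit of the two titration lines.
#' @export
setClass("CalibrationModel",
  representation(mCl = "numeric", mUcl = "numeric", background = "numeric",
                 r2Cl = "numeric", r2Ucl = "numeric"),
  prototype(r2Cl = NA_real_, r2Ucl = NA_real_))

setValidity("CalibrationModel", function(object) {
  if (object@mUcl < 0) return("mUcl must be >= 0")
  if (object@mCl <= object@mUcl) return("mCl must exceed mUcl")
  TRUE
})

#' @rdname CalibrationModel-class
#' @param mCl,mUcl,background,r2Cl,r2Ucl See slots.
#' @return A [CalibrationModel-class] object.
#' @examples
#' ## the reference calibration used throughout the package documentation
#' CalibrationModel(mCl = 0.14466, mUcl = 0.00007)
#' @export
CalibrationModel <- function(mCl = 0.14466, mUcl = 0.00007, background = 0,
                             r2Cl = NA_real_, r2Ucl = NA_real_) {
  new("CalibrationModel", mCl = mCl, mUcl = mUcl, background = background,
      r2Cl = r2Cl, r2Ucl = r2Ucl)
}

#' Michaelis-Menten fit result
#'
#' @slot kCat /s turnover number.
#' @slot kM nM Michaelis constant.
#' @slot kcatOverKM /M/s catalytic efficiency.
#' @slot e0 nM activated enzyme used in the fit.
#' @slot velocities data.frame of (S nM, v nM/s) points fitted.
#' @slot se Named numeric standard errors for kCat and kM.
#' @slot diagnostics List of fit diagnostics (convergence, residual SS, flags).
#' @export
setClass("MMFit",
  representation(kCat = "numeric", kM = "numeric", kcatOverKM = "numeric",
                 e0 = "numeric", velocities = "data.frame", se = "numeric",
                 diagnostics = "list"),
  prototype(se = c(kCat = NA_real_, kM = NA_real_), diagnostics = list()))

#' Discrimination-factor result
#'
#' DF = (F_PM - background) / (F_MM - background) at a stated evaluation time,
#' where PM/MM are the perfectly matched and mismatched activator conditions.
#' When the MM signal is indistinguishable from background (denominator below
#' `epsilon`), DF is reported as `Inf` and flagged rather than clipped.
#'
#' @slot df Dimensionless DF (possibly `Inf`).
#' @slot timeS Evaluation time, s.
#' @slot fPm,fMm,fBg AU values entering the formula.
#' @slot replicateDfs Numeric vector of per-replicate DFs.
#' @slot medianDf Median across finite replicate DFs.
#' @slot nInfinite Number of replicates excluded as infinite.
#' @slot flagged Logical; TRUE when the MM denominator fell below epsilon.
#' @export
setClass("DFResult",
  representation(df = "numeric", timeS = "numeric", fPm = "numeric",
                 fMm = "numeric", fBg = "numeric", replicateDfs = "numeric",
                 medianDf = "numeric", nInfinite = "integer",
                 flagged = "logical"),
  prototype(replicateDfs = numeric(0), medianDf = NA_real_, nInfinite = 0L,
            flagged = FALSE))
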