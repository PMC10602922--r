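#' @describeIn accessors Spacer sequence of a crRNA.
setMethod("spacer", "CrRNASpec", function(x) x@spacer)

#' @describeIn accessors Spacer length (nt) of a crRNA.
setMethod("spacerLength", "CrRNASpec", function(x) length(x@spacer))

#' @describeIn accessors Spacer length (nt) recorded in a layout.
setMethod("spacerLength", "DuplexLayout", function(x) x@spacerLength)

#' @describeIn accessors Forward-toehold direction of a layout.
setMethod("toeholdDirection", "DuplexLayout", function(x) x@toeholdDirection)

#' @describeIn accessors Forward-toehold length (nt).
setMethod("toeholdLengthF", "DuplexLayout", function(x) x@toeholdLengthF)

#' @describeIn accessors Reverse-toehold length (nt).
setMethod("toeholdLengthR", "DuplexLayout", function(x) x@toeholdLengthR)

#' @describeIn accessors Branch-migration domain length (nt).
setMethod("bmLength", "DuplexLayout", function(x) x@bmLength)

#' @describeIn accessors Time grid (s) of a trajectory.
setMethod("times", "Trajectory", function(x) x@times)

#' @describeIn accessors Time grid (s) of a fluorescence series.
setMethod("times", "FluorescenceSeries", function(x) x@times)

#' @describeIn accessors Time grid (s) of a concentration series.
setMethod("times", "ConcentrationSeries", function(x) x@times)

#' @describeIn accessors Species concentration matrix (nM) of a trajectory.
setMethod("speciesMatrix", "Trajectory", function(x) x@species)

#' @describeIn accessors Observed values (AU) of a fluorescence series.
setMethod("fluorValues", "FluorescenceSeries", function(x) x@values)

#' @describeIn accessors Background level (AU) of a fluorescence series.
setMethod("background", "FluorescenceSeries", function(x) x@background)

#' @describeIn accessors Background level (AU) of a calibration model.
setMethod("background", "CalibrationModel", function(x) x@background)

#' @describeIn accessors Cleaved-reporter slope (AU/nM).
setMethod("mCl", "CalibrationModel", function(x) x@mCl)

#' @describeIn accessors Uncleaved-reporter slope (AU/nM).
setMethod("mUcl", "CalibrationModel", function(x) x@mUcl)

#' @describeIn accessors Turnover number (/s) of a Michaelis-Menten fit.
setMethod("kCat", "MMFit", function(x) x@kCat)

#' @describeIn accessors Michaelis constant (nM) of a fit.
setMethod("kM", "MMFit", function(x) x@kM)

#' @describeIn accessors Catalytic efficiency (/M/s) of a fit.
setMethod("kcatOverKM", "MMFit", function(x) x@kcatOverKM)

#' @describeIn accessors Discrimination factor of a DF result.
setMethod("dfValue", "DFResult", function(x) x@df)

#' @describeIn accessors Median DF across replicates.
setMethod("medianDfValue", "DFResult", function(x) x@medianDf)

#' @describeIn rt RT (kcal/mol) at the model temperature.
setMethod("rt", "EnergyModel", function(x) .R_KCAL * x@temperatureK)

setMethod("show", "CrRNASpec", function(object) {
  cat("CrRNASpec '", object@name, "': ", length(object@spacer), "-nt spacer 5'-",
      as.character(object@spacer), "-3'\n", sep = "")
})

setMethod("show", "ERASpec", function(object) {
  cat("ERASpec '", object@name, "': ", length(object@sequence),
      " nt pairing spacer [", object@pairedSpan[1], ",", object@pairedSpan[2],
      "]", sep = "")
  if (length(object@mismatchPositions))
    cat("; mismatches at spacer position(s)",
        paste(object@mismatchPositions, collapse = ", "))
  cat("\n  5'-", as.character(object@sequence), "-3'\n", sep = "")
})

setMethod("show", "ActivatorSpec", function(object) {
  cat("ActivatorSpec '", object@name, "' (", object@strandedness, "): ",
      length(object@sequence), " nt", sep = "")
  if (object@deletion5p || object@deletion3p)
    cat("; spacer-end deletions 5':", object@deletion5p,
        " 3':", object@deletion3p, sep = "")
  if (length(object@mismatchPositions))
    cat("; mismatches at spacer position(s)",
        paste(object@mismatchPositions, collapse = ", "))
  cat("\n")
})

setMethod("show", "DuplexLayout", function(object) {
  cat("DuplexLayout: ", object@toeholdDirection, " forward toehold f = ",
      object@toeholdLengthF, " nt, reverse r = ", object@toeholdLengthR,
      " nt, bm = ", object@bmLength, " nt (spacer ", object@spacerLength,
      " nt)\n", sep = "")
  if (length(object@eraMismatchDistances))
    cat("  ERA mismatch distance(s):",
        paste(object@eraMismatchDistances, collapse = ", "), "nt\n")
  if (length(object@activatorMismatchDistances))
    cat("  activator mismatch distance(s):",
        paste(object@activatorMismatchDistances, collapse = ", "), "nt\n")
  if (object@dsActivator) cat("  double-stranded activator\n")
})

setMethod("show", "EnergyModel", function(object) {
  cat("EnergyModel (", object@temperatureK, " K, RT = ",
      signif(rt(object), 4), " kcal/mol)\n", sep = "")
  cat("  dG/bp RNA-RNA ", object@dgBpRnaRna, ", RNA-DNA ", object@dgBpRnaDna,
      ", toehold/nt ", signif(object@dgToeholdPerNt, 4), ", ddG mismatch +",
      object@ddgMismatch, " kcal/mol\n", sep = "")
})

setMethod("show", "Trajectory", function(object) {
  n <- length(object@times)
  cat("Trajectory: ", n, " time points over ", object@times[n], " s\n",
      sep = "")
  cat("  final cleaved reporter: ",
      signif(object@species[n, "reporter_cleaved"], 4), " nM of ",
      signif(object@species[1, "reporter_uncleaved"] +
             object@species[1, "reporter_cleaved"], 4), " nM\n", sep = "")
})

setMethod("show", "FluorescenceSeries", function(object) {
  n <- length(object@times)
  cat("FluorescenceSeries: ", n, " points, ", object@times[1], "-",
      object@times[n], " s, final ", signif(object@values[n], 5), " AU\n",
      sep = "")
  if (length(object@metadata))
    cat("  ", paste(names(object@metadata), unlist(object@metadata),
                    sep = "=", collapse = ", "), "\n", sep = "")
})

setMethod("show", "CalibrationModel", function(object) {
  cat("CalibrationModel: F = ", signif(object@mCl, 5), " * c_cl + ",
      signif(object@mUcl, 5), " * c_ucl + ", signif(object@background, 5),
      " AU\n", sep = "")
  if (!is.na(object@r2Cl))
    cat("  R^2 cleaved ", signif(object@r2Cl, 4), ", uncleaved ",
        signif(object@r2Ucl, 4), "\n", sep = "")
})

setMethod("show", "MMFit", function(object) {
  cat("MMFit: k_cat = ", signif(object@kCat, 4), " /s, K_M = ",
      signif(object@kM, 4), " nM, k_cat/K_M = ",
      signif(object@kcatOverKM, 4), " /M/s (E0 = ", object@e0, " nM)\n",
      sep = "")
})

setMethod("show", "DFResult", function(object) {
  cat("DFResult at t = ", object@timeS, " s: DF = ",
      if (is.finite(object@df)) signif(object@df, 4) else "Inf", sep = "")
  if (object@flagged) cat(" [MM indistinguishable from background]")
  cat("\n")
  if (length(object@replicateDfs) > 1)
    cat("  ", length(object@replicateDfs), " replicates, median DF = ",
        signif(object@medianDf, 4), " (", object@nInfinite,
        " infinite excluded)\n", sep = "")
})
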