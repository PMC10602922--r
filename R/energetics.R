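## Simplified, sequence-averaged free-energy model for protector duplexes and
## the displacement reaction. Deliberately not a nearest-neighbor engine: one
## per-nt stacking term per hybrid type keeps results deterministic and
## dataset-free while preserving the qualitative dependencies that matter here
## (duplex length, mismatch count, forward/reverse toehold balance).

#' Free energy of a protector duplex
#'
#' `dG = pairedNt * dG_bp(hybrid) + mismatches * ddG_mismatch`; more
#' mismatches make the duplex strictly less stable.
#'
#' @param pairedNt Number of paired nucleotides (>= 0).
#' @param mismatches Number of mismatches (>= 0, at most `pairedNt`).
#' @param model An [EnergyModel-class].
#' @param hybrid `"RNA_RNA"` (ERA-crRNA) or `"RNA_DNA"` (activator-crRNA).
#' @return Free energy in kcal/mol.
#' @examples
#' duplexDeltaG(15, 0, EnergyModel())  # -31.5
#' duplexDeltaG(15, 1, EnergyModel())  # -28.5
#' @export
duplexDeltaG <- function(pairedNt, mismatches = 0, model = EnergyModel(),
                         hybrid = c("RNA_RNA", "RNA_DNA")) {
  hybrid <- match.arg(hybrid)
  stopifnot(pairedNt >= 0, mismatches >= 0)
  if (mismatches > pairedNt)
    stop("mismatches cannot exceed the number of paired nucleotides")
  dgBp <- if (hybrid == "RNA_RNA") model@dgBpRnaRna else model@dgBpRnaDna
  pairedNt * dgBp + mismatches * model@ddgMismatch
}

#' Net free energy of the displacement reaction
#'
#' For `activator + ERA.crRNA -> activator.crRNA + ERA`, the net free energy
#' under the simplified model is
#' `dG = (r - f) * |dG_toehold/nt| + ddG * n_activator_mm - ddG * n_ERA_mm`:
#' each forward-toehold nucleotide drives the reaction forward, each
#' reverse-toehold nucleotide (toehold exchange) holds it back, activator
#' mismatches destabilize the product and ERA mismatches destabilize the
#' substrate. Plain strand displacement (r = 0, no mismatches) is downhill.
#'
#' @param layout A [DuplexLayout-class].
#' @param model An [EnergyModel-class].
#' @return Free energy in kcal/mol.
#' @examples
#' lay <- DuplexLayout("5prime", 5, 15, 22, toeholdLengthR = 5)
#' reactionDeltaG(lay)  # 0: symmetric toehold exchange
#' @export
reactionDeltaG <- function(layout, model = EnergyModel()) {
  stopifnot(is(layout, "DuplexLayout"))
  (layout@toeholdLengthR - layout@toeholdLengthF) * abs(model@dgToeholdPerNt) +
    model@ddgMismatch * length(layout@activatorMismatchDistances) -
    model@ddgMismatch * length(layout@eraMismatchDistances)
}

#' Equilibrium extent of displacement
#'
#' Solves for the extent `x` of `A + C -> products` with equilibrium constant
#' `K = exp(-dG/RT)` and mass-action quotient `x^2 / ((cComplex - x)
#' (cActivator - x))`, taking the physical root in
#' `(0, min(cComplex, cActivator))`. The quadratic is solved in a numerically
#' stable form (small root via `c/q`), so extreme `K` behaves smoothly:
#' yields tend to 1 as `dG -> -Inf` and to 0 as `dG -> +Inf`.
#'
#' @param deltaG Reaction free energy, kcal/mol.
#' @param cComplex,cActivator Initial concentrations, nM (> 0).
#' @param model An [EnergyModel-class] (supplies RT).
#' @return The extent `x` in nM, with attribute `yield` =
#'   `x / min(cComplex, cActivator)`.
#' @examples
#' equilibriumExtent(0, 20, 20)                    # 10 nM, yield 0.5
#' em <- EnergyModel()
#' equilibriumExtent(-rt(em) * log(100), 20, 20)   # 200/11 ~ 18.18 nM
#' @export
equilibriumExtent <- function(deltaG, cComplex, cActivator,
                              model = EnergyModel()) {
  stopifnot(cComplex > 0, cActivator > 0)
  ## cap the exponent so K stays finite; beyond this the yield is 0/1 anyway
  expo <- max(min(-deltaG / rt(model), 700), -700)
  K <- exp(expo)
  s <- cComplex + cActivator
  if (K == 0) {
    x <- 0
    warning("equilibrium constant numerically zero; extent clamped to 0")
  } else {
    disc <- K * K * s * s - 4 * K * (K - 1) * cComplex * cActivator
    q <- (K * s + sqrt(disc)) / 2
    x <- K * cComplex * cActivator / q
    hi <- min(cComplex, cActivator)
    if (!is.finite(x) || x <= 0 || x >= hi) {
      xc <- min(max(x, 0), hi)
      if (!isTRUE(all.equal(x, xc, tolerance = 1e-12)))
        warning("no interior root; extent clamped to [0, min(c)]")
      x <- xc
    }
  }
  structure(x, yield = x / min(cComplex, cActivator))
}
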