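# Shared builders for the test suite. Everything is generated in code; the
# spacer is synthetic (no public wet-lab strand sequences exist for this
# system).

SPACER22 <- "ACGUACGUACGUACGUACGUAC"
SPACER35 <- "ACGUACGUACGUACGUACGUACACGUACGUACGUA"

crrna22 <- function() CrRNASpec(SPACER22)
crrna35 <- function() CrRNASpec(SPACER35)

# layout with a plain 5'/3' toehold of length f against the 22-nt spacer
layoutF <- function(f, direction = "5prime", ...) {
  cr <- crrna22()
  buildDuplexLayout(cr, designEra(cr, direction, f),
                    designActivator(cr, ...))
}

refCalib <- function(bg = 0) CalibrationModel(0.14466, 0.00007,
                                                background = bg)

# fully pre-activated enzyme system for pure-cleavage runs
cleavageOnlySystem <- function(S0, e0 = 1, kCat = 1, kM = 500) {
  ReactionSystem(cComplex0 = 0, cActivator0 = 0, cReporter0 = S0,
                 eBackground = e0, kCat = kCat, kM = kM)
}

# independent oracle: equilibrium extent by interval bisection on the
# mass-action balance, never via the package's quadratic solution
bisectExtent <- function(K, cC, cA, tol = 1e-15) {
  g <- function(x) x * x - K * (cC - x) * (cA - x)
  lo <- 0; hi <- min(cC, cA)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}
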