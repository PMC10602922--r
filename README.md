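# eraCas12a

Toehold-gated control of CRISPR-Cas12a: simulation and kinetic analysis.

## The problem

Cas12a switches on when a DNA activator pairs with its crRNA spacer, and
then cleaves single-stranded DNA indiscriminately — read out with a
fluorophore–quencher reporter. That activation is essentially one-touch:
fast, hard to tune, and tolerant of near-matched (off-target) activators.
An **external RNA accessory (ERA)** is a protector strand that pre-pairs
with part of the spacer, so the activator must displace it by
**toehold-mediated strand displacement (TMSD)** before the nuclease turns
on. The toehold's length and direction, mismatch placement, ERA
stoichiometry, and toehold-exchange (TE) designs then become continuous
dials on Cas12a's activity, speed, single-base specificity, and
compatibility with one-pot isothermal amplification.

This package is for people modeling or analyzing such assays. It provides:

* S4 classes for crRNA/ERA/activator strands (`Biostrings`-backed) and
  their duplex geometry (`buildDuplexLayout`), plus designers with the
  empirical feasibility rules (`designEra`, `designTeEra`);
* an effective displacement-rate law
  `k_eff(n) = k_max * 10^min(0, n_eff - 7)` with mismatch
  acceleration/penalty factors, and a simplified duplex free-energy model
  with equilibrium displacement yields;
* an ODE simulator of activation plus Michaelis–Menten trans-cleavage
  (`simulateActivationCleavage`, `simulateOnePot`) and a noisy
  plate-reader observer (`observeFluorescence`);
* the analysis pipeline: calibration `F = m_cl c_cl + m_ucl c_ucl + b`
  fitting and inversion (`fitCalibration`, `invertFluorescence`),
  initial velocities and Michaelis–Menten fits (`initialVelocity`,
  `fitMichaelisMenten`), and discrimination factors
  `DF = (F_PM − bg)/(F_MM − bg)` (`discriminationFactorAt`, `medianDf`);
* a deterministic synthetic-study generator (`generateFixtureStudy`).

## Worked example

```r
library(eraCas12a)

cr  <- CrRNASpec("ACGUACGUACGUACGUACGUAC")      # 22-nt synthetic spacer
era <- designEra(cr, "5prime", 7)                # protector leaving a 7-nt toehold
era
#> ERASpec 'ERA_5prime_t7': 15 nt pairing spacer [8,22]
#>   5'-GUACGUACGUACGUA-3'

lay <- buildDuplexLayout(cr, era, designActivator(cr))
lay
#> DuplexLayout: 5prime forward toehold f = 7 nt, reverse r = 0 nt, bm = 15 nt (spacer 22 nt)
effectiveRate(lay)                               # saturated: 1e6 /M/s
#> [1] 1e+06
```

A 7-nt 5' toehold displaces at the saturated rate; each nucleotide less
costs a factor of 10 (`effectiveRate` on f = 6 vs f = 1 spans 1e5).

Simulate the standard assay (20 nM complex, 40 nM activator, 250 nM
reporter) and observe it through the reference calibration
(m_cl = 0.14466, m_ucl = 0.00007 AU/nM):

```r
cal <- CalibrationModel(0.14466, 0.00007)
tr  <- simulateActivationCleavage(ReactionSystem(), lay, tEnd = 1200)
fs  <- observeFluorescence(tr, cal, sigmaAu = 0.18, seed = 1)
fs
#> FluorescenceSeries: 61 points, 0-1200 s, final 36.597 AU
```

36.6 AU is full cleavage of 250 nM reporter (0.14466 x 250 = 36.2 AU plus
noise). A Michaelis–Menten titration with 1 nM pre-activated enzyme
recovers the generating constants (k_cat = 1 /s, K_M = 500 nM):

```r
S <- c(31.25, 62.5, 125, 250, 500, 1000, 2000)
pts <- do.call(rbind, lapply(S, function(s) {
  sys <- ReactionSystem(cComplex0 = 0, cActivator0 = 0, cReporter0 = s,
                        eBackground = 1)
  fs <- observeFluorescence(simulateActivationCleavage(sys, NULL, tEnd = 620),
                            cal, sigmaAu = 0.1, seed = round(s))
  data.frame(S = s, v = initialVelocity(fs, cal, method = "quadratic"))
}))
fitMichaelisMenten(pts, e0 = 1)
#> MMFit: k_cat = 1.017 /s, K_M = 522.7 nM, k_cat/K_M = 1945000 /M/s (E0 = 1 nM)
```

Single-base discrimination: with a short (4-nt) toehold, an activator
mismatch next to the toehold slows displacement ~36-fold, and the
background-subtracted fluorescence ratio reports it:

```r
era4  <- designEra(cr, "5prime", 4)
layPM <- buildDuplexLayout(cr, era4, designActivator(cr))
layMM <- buildDuplexLayout(cr, era4, designActivator(cr, mismatchPositions = 6))
pm <- observeFluorescence(simulateActivationCleavage(ReactionSystem(), layPM,
                                                     tEnd = 1200), cal, 0)
mm <- observeFluorescence(simulateActivationCleavage(ReactionSystem(), layMM,
                                                     tEnd = 1200), cal, 0)
bg <- observeFluorescence(simulateActivationCleavage(
  ReactionSystem(cActivator0 = 0), layPM, tEnd = 1200), cal, 0)
discriminationFactorAt(pm, mm, bg, t = 1200)
#> DFResult at t = 1200 s: DF = 26.94
```

DF = 26.9 at 20 min: the mismatched activator is strongly suppressed
(uncontrolled Cas12a would give DF ≈ 1 at the plateau).

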