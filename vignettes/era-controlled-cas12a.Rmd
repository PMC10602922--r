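---
title: "Modeling toehold-gated control of CRISPR-Cas12a"
author: "eraCas12a"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling toehold-gated control of CRISPR-Cas12a}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eraCas12a)
```

## The system being modeled

Cas12a is activated when a DNA *activator* pairs with the spacer region of
its crRNA; once activated it indiscriminately cleaves single-stranded DNA,
which is read out by a fluorophore–quencher reporter. An *external RNA
accessory* (ERA) is a protector strand that pre-pairs with part of the
spacer, so that the activator must first displace it by toehold-mediated
strand displacement (TMSD): it nucleates at the single-stranded *toehold*
left by the ERA and then migrates branch by branch through the duplex. The
geometry of that duplex — which spacer end carries the toehold, how long the
toehold is, where mismatches sit — then sets the activation kinetics and
thermodynamics, and with them the nuclease's effective activity, speed and
single-base specificity.

The package models this chain end to end:

1. **Geometry** (`CrRNASpec`, `ERASpec`, `ActivatorSpec` →
   `buildDuplexLayout`): spacer positions are 1-based from the spacer 5'
   end; a "5' toehold" is unpaired spacer at the 5' (PI-domain-facing) end.
   Activator deletions are declared in spacer coordinates; note that a
   truncation of the activator strand's own 5' end uncovers the spacer *3'*
   end, because the strands pair antiparallel.
2. **Kinetics** (`effectiveRate`): an effective second-order displacement
   rate derived from the layout.
3. **Thermodynamics** (`reactionDeltaG`, `equilibriumExtent`): a
   sequence-averaged free-energy model and the equilibrium displacement
   yield.
4. **Dynamics** (`simulateActivationCleavage`, `simulateOnePot`): mass-action
   activation coupled to Michaelis–Menten trans-cleavage, integrated with a
   stiff-capable solver.
5. **Observation and analysis** (`observeFluorescence`, `fitCalibration`,
   `invertFluorescence`, `initialVelocity`, `fitMichaelisMenten`,
   `discriminationFactorAt`): the plate-reader analysis pipeline.

## The effective rate law

TMSD rates grow roughly tenfold per toehold nucleotide until they saturate.
`effectiveRate` encodes this as

$$k_\mathrm{eff}(n) = k_\mathrm{max}\, \phi^{\min(0,\; n_\mathrm{eff} - n_\mathrm{sat})},
\qquad n_\mathrm{eff} = f - \Delta_{3'}\,[\text{3' toehold}]$$

with defaults $k_\mathrm{max} = 10^6\ \mathrm{M^{-1}s^{-1}}$, per-nt factor
$\phi = 10$, saturation at $n_\mathrm{sat} = 7$ nt and a 3'-direction
penalty of $\Delta_{3'} = 2$ effective nucleotides. The exponential-with-
hard-saturation form is deliberate: it reproduces the canonical $10^5$ ratio
between 6-nt and 1-nt toeholds exactly, which a soft (logistic) shoulder
would blur, and it makes a 7-nt 5' toehold sit exactly at the saturated
rate. The 3' penalty is an integer effective-toehold offset calibrated to
the observation that 3' toeholds barely activate below 7 nt; the reported
(and mechanistically surprising) extra speed of 3' toeholds with
double-stranded activators is *not* modeled — we flag it rather than guess a
mechanism.

Mismatches modulate the rate multiplicatively:

* an **ERA mismatch** at distance $d$ from the toehold accelerates
  displacement by $\alpha(d) = 1 + (\alpha_{\max}-1)\,(d/d^*)\,e^{1-d/d^*}$,
  a bump with $\alpha(0) = 1$ and peak $\alpha(d^*) = \alpha_{\max} = 100$
  at $d^* = 2$ nt. The peak value (two orders of magnitude) and its
  qualitative position ("eliminated early rather than immediately") are the
  anchored facts; the gamma-like functional form is our choice.
* an **activator mismatch** at distance $d$ slows displacement by
  $\beta(d) = 1 + (\beta_{\max}-1)\,e^{-d/\lambda}$ with
  $\beta_{\max} = 50$, $\lambda = 3$ nt — the kinetic origin of
  toehold-proximal single-base discrimination.
* double-stranded activators are scaled by $\gamma_{ds} = 0.3$.

## Energetics and toehold exchange

The free-energy model is sequence-averaged on purpose: $-2.1$ kcal/mol per
RNA–RNA pair, $-1.8$ per RNA–DNA pair, $-RT\ln 10$ per forward-toehold
nucleotide and $+3.0$ kcal/mol per mismatch (a mid-range single-mismatch
destabilization; configurable). A nearest-neighbor engine would add
sequence detail that none of the package's qualitative dependencies need,
at the cost of determinism and an external dependency. Enthalpy is not
separated from free energy; toehold-exchange (TE) "ΔH ≈ 0" tuning is
represented at the ΔG level by balancing forward against reverse toeholds
($f = r$).

For the displacement reaction the net free energy is
$(r - f)\,|\Delta G_\mathrm{toe}| + \Delta\Delta G_\mathrm{mm}\,(n_\mathrm{act} - n_\mathrm{ERA})$,
so a symmetric exchange is thermoneutral and a single activator mismatch
pushes it uphill — the thermodynamic, position-independent discrimination
that TE adds. `equilibriumExtent` solves the mass-action balance
$K = x^2/((C_0-x)(A_0-x))$ with the numerically stable quadratic root, and
the simulator's `te_equilibrated` mode adds the reverse displacement with
$k_\mathrm{rev} = k_\mathrm{eff}/K$ so that long-time activation matches
that extent.

The TE designer enforces the empirical feasibility rules: for a 22-nt
spacer, activation survives terminal activator deletions below 5 nt
(`rLength < 5`); extending the spacer to 35 nt relaxes the bound at the
spacer 3' end — the activator's own 5' end — to 19 nt.

## Simulation and observation

`simulateActivationCleavage` integrates, in nM and seconds,

$$\dot C = -k\,C\,A + k_\mathrm{rev} E_r^2,\quad \dot E = -\dot C,\quad
\dot P = k_\mathrm{cat} E \frac{S}{K_M + S},\quad S = S_0 - P$$

with `deSolve::lsoda` at relative tolerance $10^{-8}$ and absolute
$10^{-12}$ nM, on a fixed 20-s output grid (the plate-reader interval).
Defaults mirror the standard assay mix: 20 nM complex, 40 nM activator,
250 nM reporter, ERA annealed at 2:1 over crRNA. With a sub-stoichiometric
ERA ratio the unprotected fraction $\max(0, 1-\rho)$ of complexes starts
active (a linear model of partial protection; the alternative —
partially active protected complexes — is not distinguishable at this
level and the ratio is configurable). `layout = NULL` means uncontrolled
Cas12a: the complex starts inactive and binds activator at the saturated
rate. Excess ERA beyond 1:1 is treated as kinetically inert.

Fluorescence is observed as $F = m_{cl} c_{cl} + m_{ucl} c_{ucl} + b +
\varepsilon$: quenching of the intact reporter is imperfect, so the
uncleaved slope is small but nonzero. The reference calibration used
throughout the documentation is $m_{cl} = 0.14466$, $m_{ucl} = 0.00007$
AU/nM, which makes the inversion denominator $m_{cl} - m_{ucl} = 0.14459$
AU/nM and the 125-nM offset term $m_{ucl} c_0 = 0.00875$ AU. A tempting
shortcut is to divide by a rounded denominator such as 0.14446, but that is
arithmetically inconsistent with the two slopes it derives from; the
package uses $m_{cl}-m_{ucl}$ consistently. Background is the buffer-only
signal, subtracted before fitting; zero-intercept regression is the default
and a free-intercept variant is available. For discrimination factors the
background series is a matched no-activator control (which carries the
uncleaved-reporter signal), not buffer alone.

## Parameter estimation and a known bias

`initialVelocity` follows the standard protocol — linear regression of the
first 600 s, converted to nM/s by $1/(m_{cl}-m_{ucl})$. That chord is
biased low whenever $k_\mathrm{cat}E_0/(K_M+S)\times 600\,\mathrm{s}$ is
not small: at the fixture truth ($k_\mathrm{cat} = 1/\mathrm{s}$,
$K_M = 500$ nM, $E_0 = 1$ nM) the lowest reporter level loses ~40% of its
true initial velocity to substrate depletion, which inflates a naive
Michaelis–Menten fit of $K_M$ by ~70%. The package therefore also provides
`method = "quadratic"`, the slope at $t = 0$ of a second-order polynomial
over the same window, which recovers $(k_\mathrm{cat}, K_M)$ within ~3.5%
noise-free; the recovery tests use it. This is a property of progress-curve
analysis generally, not of the simulator.

`fitMichaelisMenten` uses unweighted Levenberg–Marquardt least squares with
starting values $k_\mathrm{cat} \leftarrow v_{\max}/E_0$,
$K_M \leftarrow \mathrm{median}(S)$, and flags a fitted $K_M$ beyond
$100\times$ the largest substrate level as poorly constrained. For slow
layouts whose 600-s signal change is negligible, assays are generated at
$E_0 = 5$ nM instead of 1 nM, and the fixture bundle includes both.

## The one-pot scenario

In a one-pot assay the amplification program (modeled coarsely as templates
producing activator at $k_\mathrm{amp}$ per second, times a leak fraction
without target) shares the tube with the nuclease, whose trans-cleavage
destroys templates and primers at the second-order rate $(k_\mathrm{cat}/K_M)E$
— a negative feedback that caps the uncontrolled assay's signal. A
short-toehold ERA delays the rise of $E$, preserving templates through the
amplification phase.

The fixture scenario uses 37 °C one-pot conditions: $k_\mathrm{cat} = 0.2$
/s and $K_M = 100$ nM (keeping $k_\mathrm{cat}/K_M$ at the same
$2\times10^6\ \mathrm{M^{-1}s^{-1}}$ as the standard assay, so the feedback
term is unchanged), reporter at the 2 µM titration maximum, 10 nM template
producing $3\times10^{-5}$ of its concentration per second, 5% leak, and a
4-h window with a 5'-toehold-5 ERA as the delayed layout. In this regime
the delayed one-pot endpoint exceeds the uncontrolled one by ~13%, and
coupling trans-cleavage to the amplification species lowers the no-target
leak signal by ~10%. With a *linear* (primer-exchange-like) amplification
law this ordering margin is structurally modest — the uncontrolled system
converts its (smaller) activator pool earlier — and that is a known
limitation of the coarse amplification model; an autocatalytic
amplification law would sharpen the separation but is out of scope.

```{r onepot-demo, eval = FALSE}
cr  <- CrRNASpec("ACGUACGUACGUACGUACGUAC")
lay <- buildDuplexLayout(cr, designEra(cr, "5prime", 5), designActivator(cr))
sys <- ReactionSystem(cActivator0 = 0, cReporter0 = 2000, kCat = 0.2,
                      kM = 100, temperatureK = 310.15)
tr  <- simulateOnePot(sys, list(targetPresent = TRUE), lay, tEnd = 14400)
tail(speciesMatrix(tr)[, "reporter_cleaved"], 1)
```

## Synthetic data: what it does and does not emulate

`generateFixtureStudy` writes a complete study — calibration titrations,
toehold panels, mismatch panels, TE panels, MM titrations, DF replicate
triplets and one-pot scenarios — as CSV/FASTA plus a JSON manifest, all
reproducible byte-for-byte from one seed. The generator emulates 20-s
sampling, imperfect quenching, additive Gaussian noise (default 0.18 AU,
about 0.5% of the 250-nM full scale) and replicate structure. It does
**not** emulate sequence-specific thermodynamics, pipetting or plate
effects, photobleaching, temperature drift, or enzyme lot variability — so
green tests demonstrate that the *pipeline* is correct and self-consistent
on data obeying the model, not that the model captures every feature of
real plate-reader data. The spacer sequences are synthetic — no public
wet-lab strand sequences exist for this system — and every fixture file is
labelled accordingly.

## Numerical choices and degenerate inputs

* ODE: `lsoda`, rtol $10^{-8}$, atol $10^{-12}$ nM; mass conservation is
  enforced to solver tolerance and asserted in tests.
* `equilibriumExtent`: stable quadratic root ($x = c/q$ form); the
  equilibrium-constant exponent is capped at $\pm 700$ before
  exponentiation, and out-of-interval roots are clamped with a warning.
* Inversion clamps $c_{cl}$ to $[0, c_0]$ and flags each clamped point
  rather than failing.
* Velocity differentiation uses central differences on the 20-s grid with
  no smoothing by default.
* A DF whose mismatch signal is within epsilon (default $3\times$ the noise
  SD in analysis code, $10^{-9}$ AU in the pure arithmetic) of background
  is reported as `Inf` and flagged, never silently clipped; medians exclude
  and count such replicates.
* Designed mismatches use a fixed transversion-partner substitution
  (A↔C, G↔U) so designs are deterministic and never create wobble pairs.
* A full-span ERA has no toehold; its layout reports $f = 0$ with direction
  `"5prime"` by convention, and its activation rate is 0.

## Problem sizes

The test suite and the fixture bundle are sized for interactive use: single
trajectories are 31–721 points, the recovery study uses 7 substrate levels
x 3 replicates x 3 seeds, and the complete fixture bundle generates in a
couple of seconds on one CPU.
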