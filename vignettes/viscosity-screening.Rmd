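---
title: "Physics-based antibody viscosity screening with abvisc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Physics-based antibody viscosity screening with abvisc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abvisc)
```

## The problem

Therapeutic monoclonal antibodies (mAbs) are often dosed at 100–200 mg/mL
for subcutaneous injection, and at those concentrations many otherwise
promising candidates become too viscous to manufacture or inject.
Rheological measurements require gram quantities of material and are
therefore only feasible late in development. `abvisc` implements a
physics-based route from two dilute-solution assays — AC-SINS
(affinity-capture self-interaction nanoparticle spectroscopy, read out as
the nanoparticle diffusion coefficient $D_{np}$) and DLS (the diffusion
interaction parameter $k_D$) — to a predicted concentration–viscosity
curve and a binary developability call, so that viscous molecules can be
deselected at the candidate-screening stage.

## The model

The physical picture is that mAb self-association is dominated by
CDR-mediated, head-to-head (HH) contacts. Because each molecule carries
two CDR arms, HH binding produces *linear* chains, and at high
concentration those elongated chains entangle. Three ingredients follow:

**1. Isodesmic chain statistics.** With a single stepwise association
constant $K = C_2/C_1^2$ (mL/mg; $C_1$, $C_2$ the monomer and dimer mass
concentrations), the number-average chain length at total concentration
$C$ is

$$\langle L \rangle \;=\; \frac{2KC}{\sqrt{1+4KC}-1}
 \;=\; \frac{1+\sqrt{1+4KC}}{2}.$$

The two forms are algebraically identical; the package evaluates the
second, which is stable as $KC \to 0$ (where $\langle L\rangle \to 1$).
`mean_chain_length()` is verified in the test suite against
`chain_length_mass_balance()`, an independent bisection solve of the
defining mass balance $C = C_1/(1-KC_1)^2$,
$\langle L\rangle = 1/(1-KC_1)$, to $10^{-9}$ relative over
$KC \in [10^{-6}, 10^{3}]$.

**2. Reptation.** Entangled elongated objects can only diffuse snake-like
along their own contour, which gives the scaling
$\eta \sim C^{3/(3\nu-1)} L^3$ with $\nu = 3/5$ the Flory exponent, so
the concentration power is $3/(3\nu-1) = 3.75$. Combining with the chain
statistics:

$$\eta(K, C) \;=\; A\, C^{3.75} \left(\frac{1+\sqrt{1+4KC}}{2}\right)^{3},
\qquad A = 5.4\times10^{-8}\ \mathrm{cP\,(mg/mL)^{-3.75}}.$$

$A$ captures the lateral ("slithering") friction between complexes and is
treated as constant within an IgG scaffold. The log–log concentration
slope runs from 3.75 in the weak-binding limit to 5.25 when
$\langle L\rangle \sim \sqrt{KC}$, and both limits are checked
numerically in the tests. Note the units of $A$: the exponent is written
with a *negative* power of (mg/mL) so that $\eta$ comes out in cP.

**3. Linear calibrations.** Both dilute readouts decrease with stronger
self-association, and across a training cohort they are empirically
linear in the fitted $K$:

$$D_{np} = 4.9 - 2045\,K, \qquad k_D = 56.03 - 15000\,K,$$

with $D_{np}$ in µm²/s, $k_D$ in mL/g and $K$ in mL/mg (the slope of the
$k_D$ line absorbs the mL/g vs mL/mg factor). These published
coefficients ship as `reference_lines()` so prediction works without a
training cohort; `calibrate_cohort()` refits them from any cohort with
measured viscosity profiles.

Prediction is then a chain of closed forms: measurement → $K$ (invert the
line) → $\eta(K, C)$ along a grid (default 10 mg/mL steps over 70–250
mg/mL) → classification at 150 mg/mL.

## Where the model is *not* applicable, and the exclusion rules

Each assumption fails somewhere, and the package encodes the failure
modes as explicit, configurable rules (`exclusion_config()`):

* **Non-entangled molecules.** A viscosity profile at or below the
  monomer baseline $A C^{3.75}$ inverts to $K \le 0$. That is not a
  physical affinity — it signals that the molecule never entangles, and a
  colloidal (non-reptative) theory would be needed instead. Such
  molecules are flagged `non_entangled`, reported, and excluded from
  calibration. At the model layer the signed $K$ is preserved so
  calibration can see it; only `k_from_measurement()` clamps negative
  raw $K$ to 0 (flag `clamped_to_zero`) for prediction, since
  extrapolating the entanglement law to $K<0$ has no meaning.
* **AC-SINS sensitivity floor.** Below $D_{np} = 1$ µm²/s the Stokes
  radius of large nanoparticle clusters grows too slowly with cluster
  size for diffusion to resolve affinity, so the $D_{np}$–$K$
  correlation breaks down. Readings strictly below the floor are flagged
  `low_sensitivity_dnp`; readings at or below it are excluded from
  calibration.
* **Head-to-tail (HT) binders.** A CDR-to-framework contact increases
  the binding valence, producing branched complexes that cannot reptate,
  and the nanoparticle tether can sterically hide the HT site so that
  AC-SINS under-reports the association DLS sees. Suspected HT binders
  show anomalously high $D_{np}$ for their $k_D$ and are flagged by
  `detect_ht_outliers()` against a separator line in $(k_D, D_{np})$
  space. The separator's two coefficients are deliberately
  user-supplied: they must be placed by inspecting the cohort's scatter,
  and no published coefficients exist. Unset, the function warns and
  flags nothing.
* **Branching cutoff.** $K > 0.01$ mL/mg implies complexes long and
  sticky enough that branching is likely; such points are excluded from
  the DLS calibration and flagged `above_branching_cutoff` in
  prediction.
* **$k_D$ plausibility.** The published analysis dropped a single
  molecule at $k_D = 84$ mL/g as outside the range expected for
  antibodies. The package generalizes this to a symmetric configurable
  bound $|k_D| > 60$ mL/g (`kd_abs_max`).
* **Entanglement floor.** Measured points below 100 mg/mL show a
  distinctly weaker power law (the solution is too dilute to entangle)
  and are excluded from profile fits with a warning; predicted points
  below the floor are flagged.

Every calibration reports an exclusion ledger: each input molecule
appears exactly once, either in the fit or with its exclusion reason, a
property asserted in the tests.

## Classification and performance labels

At 150 mg/mL the developability cutoff is 20 cP, boundary-inclusive:
$\eta \le 20$ cP is "good", $>20$ cP "bad". The boundary orientation is
forced by the published panels (a molecule at exactly 20.0 cP is counted
low, one at 20.1 cP high). The combined call is conservative — a
molecule is flagged when *either* assay predicts above the cutoff.

Performance labels follow the molecule-centric convention of the source
panels: "False positive" means both assays predicted low viscosity but
the molecule is experimentally viscous; "False negative" means at least
one assay predicted high viscosity for an experimentally fluid molecule.
Because that is the reverse of the usual screening/detection convention,
`standard_label()` emits the detection-convention alias alongside
(`false_negative` for a missed viscous molecule, etc.).

## Fitting choices

* **Profile fits minimize squared log-viscosity residuals.** Viscosity
  spans an order of magnitude over the measured range; log residuals
  weight all concentrations evenly rather than letting the highest
  concentration dominate. The published analysis does not state its
  loss; this is the package's choice. The 1-D optimum is found by
  root-finding on the analytic gradient (machine-precision tolerance),
  seeded and bracketed by the exact per-point inversions, so noise-free
  profiles are recovered to better than $10^{-8}$ relative.
* **Calibration is ordinary least squares of the measurement on $K$** —
  the orientation in which the lines are written. No weighting; the
  fitting procedure behind the published coefficients is not stated, and
  plain OLS on noise-free collinear cohorts reproduces them exactly, as
  the tests require.
* **Numerical tolerances.** The mass-balance oracle bisects to
  $10^{-15}$ relative on the monomer fraction; the profile-fit gradient
  root is solved to machine epsilon; the closed-form inversion
  $K = (L^2 - L)/C$, $L = (\eta/(AC^{3.75}))^{1/3}$ is exact. Inversion
  is refused when the implied $L \le 1/2$ (below the range the square
  root can represent).

## The synthetic cohort generator

No per-molecule data are published for the 89-mAb cohort behind the
reference lines (63 training / 17 validation / 9 test molecules), so the
package ships a generator (`generate_cohort()`) that emulates its
statistical structure and makes the calibration and screening stages
testable end-to-end:

* true $K$ log-uniform over $10^{-5}$–$10^{-2}$ mL/mg, spanning
  non-entangled to branching-prone molecules;
* $D_{np}$ and $k_D$ placed on the reference lines plus Gaussian noise
  (defaults 0.3 µm²/s and 3 mL/g — the scale of scatter visible in
  published correlation plots; the error model itself is an artifact
  choice, as none is reported);
* viscosity from the reptation law at each configured concentration
  (default ~70 and ~150 mg/mL, the panel's design) times lognormal noise
  (default 5%);
* HT binders: $D_{np}$ drawn from the head-to-head $K$ but $k_D$ and
  viscosity from `ht_K_multiplier` × $K$ (default 5), mimicking a
  tether-occluded site;
* strong binders: noise-free $D_{np}$ uniform in (0.1, 0.9) µm²/s,
  below the sensitivity floor.

Ground truth is returned as a separate table so pipeline tests cannot
leak it. All randomness flows from one required seed; two runs with the
same config are byte-identical.

What passing these tests shows — and does not. The generator draws from
the *same* linear + reptation model the pipeline fits, so parameter
recovery demonstrates the estimators are consistent and correctly
implemented (no attenuation beyond what measurement noise causes), not
that real antibodies obey the model. Structure the generator does not
emulate: plasmon-shift optics (the field is carried but inert),
three-body nanoparticle "bridging", many-body electrostatics, and any
curvature in the measurement–$K$ relations.

On HT detection power: the displacement of an HT binder from the
$(k_D, D_{np})$ trend is proportional to its $K$ (about $8180\,K$ µm²/s
vertically at the default multiplier), while measurement noise
contributes ~0.4 µm²/s. Weak HT binders ($K \lesssim 10^{-4}$ mL/mg) are
therefore *physically* indistinguishable from the main population, and
no separator can recover them. The detection test accordingly draws HT
binders from the moderate-to-strong range ($K \in 10^{-3.5}$–$10^{-2.5}$
mL/mg), where the two populations genuinely separate and a midway
separator recovers essentially all of them; this mirrors practice, where
only clearly displaced molecules are called HT suspects.

## Problem sizes used in the checks

The bundled validation (17 molecules) and test (9 molecules) panels are
evaluated in full. Synthetic checks use cohorts of 50 (noise-free
round-trips, exact to $10^{-6}$), 63 × 20 replicates (noisy slope
recovery, median relative error under 10%), 89 (splitting) and 200 (HT
detection); these sizes match the cohort the method was built around
while keeping the whole suite fast.

## Known limitations

* Predictions degrade above ~40 cP: strong binders sit below the
  AC-SINS sensitivity floor, and very large fitted $K$ values likely
  reflect branched complexes forced through a linear-chain law.
* $A$ is scaffold-dependent; hinge engineering or strongly non-specific
  solution conditions require refitting it.
* The head-to-tail chain-statistics model is not implemented — HT
  physics enters only as outlier detection — and no uncertainty is
  attached to predictions (none is available for the published
  coefficients).
* The 63/17/9 split utility exists for reproducing cohort workflows;
  with no per-molecule public data, refitting the published coefficients
  themselves is out of reach, and the package instead demonstrates
  recovery on synthetic cohorts.
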