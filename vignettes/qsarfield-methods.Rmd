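---
title: "Field-based 3D-QSAR with qsarfield: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Field-based 3D-QSAR with qsarfield: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsarfield)
```

## The modelling problem

A congeneric series of enzyme inhibitors — here, a tetrahydroquinoline
series targeting lysine-specific demethylase 1 (LSD1) — shares a common
scaffold and varies in its substituents. The working hypothesis of
field-based 3D-QSAR is that differences in inhibitory potency (pIC50)
are explained by differences in the interaction fields the molecules
project into the space around them. The pipeline is:

1. convert activities (IC50, micromolar) to pIC50 and split compounds
   into training and test sets under a nested activity-range constraint;
2. superpose every molecule's scaffold onto a template (the most active
   compound) by least-squares rigid-body fitting;
3. evaluate probe-based fields on a rectangular lattice around the
   aligned set — either Lennard-Jones/Coulomb probe energies (the CoMFA
   formulation) or Gaussian-attenuated similarity indices for steric,
   electrostatic, hydrophobic, hydrogen-bond donor and acceptor
   properties (the CoMSIA formulation);
4. regress pIC50 on the resulting wide, collinear descriptor block with
   partial least squares (PLS), selecting the number of latent
   components by leave-one-out cross-validation (LOO);
5. judge the model by the internal q², by external prediction of the
   held-out test set (Rpred² and the Golbraikh–Tropsha through-origin
   battery), and by Y-randomization;
6. visualize the model as StDev×Coeff volumes contoured at contribution
   levels.

## Field models

**CoMFA probe energies.** At every lattice node the steric field is the
Lennard-Jones 12-6 energy of an sp³-carbon probe (radius 1.70 Å, well
depth 0.107 kcal/mol),

$$E_s = \sum_i \varepsilon_i\!\left[\left(\tfrac{r_{m,i}}{r_i}\right)^{12}
  - 2\left(\tfrac{r_{m,i}}{r_i}\right)^{6}\right],\qquad
  r_{m,i} = r_{\mathrm{probe}} + r_{\mathrm{vdw},i},\;
  \varepsilon_i = \sqrt{\varepsilon_{\mathrm{probe}}\varepsilon_{\mathrm{atom}}},$$

truncated at +30 kcal/mol, and the electrostatic field is the Coulomb
energy of a +1 e probe with distance-dependent dielectric
$\epsilon(r)=r$,

$$E_e = \sum_i \frac{332.0637\, q_i q_{\mathrm{probe}}}{r_i^2},$$

truncated to ±30 kcal/mol. At nodes where the steric energy sits at its
truncation ceiling — inside a molecule — the electrostatic value is
physically meaningless; it is replaced by the column mean over the
non-clashed compounds during block assembly, the conventional treatment.

**CoMSIA similarity indices.** The similarity formulation replaces the
singular LJ/Coulomb forms with a Gaussian attenuation,

$$A_k(\mathbf{x}) = -\sum_i w_{\mathrm{probe},k}\, w_{i,k}\,
  e^{-\alpha\, r_i^2},\qquad \alpha = 0.3\ \text{Å}^{-2},$$

for five property kinds: steric (atom weight $r_{\mathrm{vdw}}^3$),
electrostatic (partial charge), hydrophobic, donor and acceptor (rule
assigned weights). These fields are smooth everywhere, which is why no
truncation is needed.

**Partial charges.** Gasteiger partial equalization of orbital
electronegativities (PEOE), iterated 6 sweeps with damping $0.5^k$,
using the published per-element quadratic electronegativity polynomials.
Charge is conserved exactly by construction. The π-system correction
some modelling suites layer on top is deliberately omitted: its
parameters are not openly documented, and a reproducible, fully
published scheme was preferred. When a MOL2 file supplies charges, those
take precedence.

**Atom typing for property weights.** No standard defines these
unambiguously, so the rules are deliberately minimal and documented:
donor weight 1 on N/O atoms bearing at least one hydrogen; acceptor
weight 1 on any oxygen and on nitrogens with at most three connections;
hydrophobic weights from a per-element fragmental-lipophilicity lookup
(C and halogens positive, N/O negative). The rules live in
`default_property_rules()` and can be replaced wholesale.

## Grid, filtering, scaling

The lattice is the bounding box of the aligned set extended by a margin
on every side. Defaults: spacing 2.0 Å, margin 4.0 Å — the customary
lattice for this model class; the field values change smoothly under
both, and the PLS stage is insensitive to modest variations because
neighboring columns are strongly correlated.

Columns with standard deviation below a *minimum sigma* threshold are
removed before regression: they are numerically constant, carry no
signal, and inflate the column count. The default threshold is 2.0 in
field units for CoMFA energies. CoMSIA similarity indices are
dimensionless and roughly an order of magnitude smaller in dynamic
range, so the pipeline default there is 0.05, chosen as a comparable
fraction of the typical column spread. Both are configurable, and the
filter decision is always computed on training compounds only, so test
compounds never influence descriptor selection.

With several field kinds in one block, the kind with the largest numeric
range would dominate the PLS covariance. Block scaling (the
"CoMFA-STD" convention) rescales each field's kept columns so all
fields carry equal total column variance. The scale factors are
recorded, and contour volumes are reported back in original field units
— the StDev×Coeff product is invariant to the scaling, since the factor
cancels between the standard deviation and the coefficient.

## PLS, component selection, validation

The regression engine is NIPALS PLS1 with deterministic initialization
(the first weight vector is $X^\top y$, normalized), written natively:
the latent-variable regression is the analytic core of the method, not
a call-out. At full rank its fitted values coincide with least squares
— one of the test-suite oracles. Scores are mutually orthogonal;
coefficients are recovered for every truncation $1..c$, so LOO needs
one fit per held-out sample rather than one per component.

Cross-validation is leave-one-out on the training set:
$\mathrm{PRESS}_c = \sum_i (\hat y_{(-i),c} - y_i)^2$, $\mathrm{TSS} =
\sum_i (y_i - \bar y)^2$, $q^2_c = 1 - \mathrm{PRESS}_c/\mathrm{TSS}$.
(The formula sheet this battery descends from labels the PRESS vectors
"test set" while simultaneously calling the statistic cross-validated;
the LOO-on-training reading is the standard one and is what is
implemented.) The optimal number of components is the smallest $c$
whose $q^2$ reaches 95% of the profile maximum — a parsimony rule,
since the source tables report component counts without stating a rule.
The 5% tolerance is configurable.

The non-cross-validated statistics follow the usual definitions with
$n - c - 1$ residual degrees of freedom:
$\mathrm{SEE} = \sqrt{\mathrm{SS}_{res}/(n-c-1)}$ and
$F = (r^2/c)/((1-r^2)/(n-c-1))$. Recomputing $F$ from a published table
row ($n=30$, $c=2$, $r^2=0.877$) reproduces the printed 96.151 within
0.5% — the residual discrepancy is exactly what 3-decimal rounding of
$r^2$ causes, which validates the degrees-of-freedom convention.

External validation on the held-out set computes $R^2_{pred} =
(SD - \mathrm{PRESS})/SD$ with $SD$ the squared deviations of test
activities from the *training* mean, plus the through-origin battery:
slopes $k$ and $k'$, through-origin determination coefficients $R_0^2$
and $R_0'^2$ (the two role assignments of experimental and predicted),
and $r_m^2 = R^2(1 - \sqrt{R^2 - R_0^2})$. The difference under the
root is clamped at zero: a through-origin fit can numerically edge out
the centered fit, and the clamp keeps $r_m^2$ real, matching published
usage. Condition inequalities are strict, as tabulated:
$R^2 > 0.6$; $0.85 < k, k' < 1.15$; $(R^2 - R_0^2)/R^2 < 0.1$ (either
role); $|R_0^2 - R_0'^2| < 0.3$; $r_m^2 > 0.5$.

Y-randomization permutes the response (a true shuffle, not a
resample), refits with the full recipe including component
re-selection, and records each scrambled model's $q^2$ and $r^2$. A
sound model shows scrambled $q^2$ scattering around zero and every
scrambled $r^2$ below the true fit.

## The synthetic congeneric series

The compound structures behind the published series exist only as
figures, so the package carries a generator that emulates the *shape*
of such a dataset rather than its chemistry: a fixed carbon scaffold
(hexagonal ring plus chain, identical and pre-aligned in every
molecule), two substituent sites growing 1–4 carbon-like pseudo-atoms
with seeded random placement, partial charges U(−0.5, 0.5) e,
hydrophobic weights U(0, 1), and donor/acceptor flags Bernoulli(0.3) —
ranges wide enough to exercise all five similarity kinds. Activities
are planted linearly in true similarity-field values at named grid
nodes near the substituent sites, plus Gaussian noise:

$$\mathrm{pIC50}_i = b + \sum_e \beta_e A_{k_e}(\mathbf{x}_e; i)
  + \mathcal{N}(0, \sigma).$$

Defaults mirror the study conditions: 40 molecules, 75/25 split under
the nested-range constraint, noise 0.3 pIC50 units, base 6.5 (the
resulting activity span, roughly 4.6–8.8, matches the span of the
published series), and four planted effects of mixed sign across
steric, hydrophobic, donor and acceptor kinds. A single integer seed
drives structure generation, noise and split through fixed offsets, so
any stage can be re-run stably.

What passing the recovery checks shows: that the pipeline's descriptor
space contains the planted truth, that PLS finds it at realistic noise,
that the recovered StDev×Coeff values at the effect nodes carry the
planted signs, and that scrambling destroys the signal. What it does
*not* show: anything about conformational error, alignment ambiguity,
charge-model fidelity, or activity cliffs in real chemistry — the
generator plants its truth in exactly the descriptor space the model
searches, which real data never does. Numerical parity with any
commercial implementation of the field models is likewise not claimed;
probe parameters and grid conventions are documented defaults, not
reverse-engineered settings.

## Contour volumes

The model is visualized per field kind as StDev×Coeff values: training
standard deviation of each kept column times its (back-scaled)
regression coefficient, zero at filtered nodes. Contour levels follow
the contribution-mass convention: node values are sorted ascending, the
absolute values accumulated, and the favored/disfavored levels are the
values where the cumulative mass crosses the chosen fractions (defaults
0.8 and 0.2). Published maps for this model family quote "80% favored /
20% disfavored" without defining the quantile; the cumulative-|value|
mass reading is the convention implemented, and the levels plus the
convention name are written into the export headers. Volumes export as
OpenDX scalar fields; the in-memory x-fastest linearization is permuted
to the DX-canonical z-fastest order on write, so files load correctly
in standard viewers.

## Numerical and design notes

* pIC50 convention: IC50 is read in micromolar, pIC50 $= 6 -
  \log_{10}(\mathrm{IC50}_{\mu M})$. Every printed IC50/pIC50 pair in
  the bundled activity table reproduces to 1e-4 (one row differs by
  1e-5 at the fifth decimal — printed rounding).
* The split re-draws with an incremented sub-seed until the nested
  range condition holds (default budget 100 attempts); an explicit test
  id list bypasses randomization but is still checked.
* Skeleton correspondences are explicit index maps, not substructure
  searches; superposition is unweighted Kabsch via SVD with the
  determinant correction, so reflections are never returned; degenerate
  (collinear) skeletons are rejected.
* Node-atom distances are clamped below at $10^{-6}$ Å before the LJ
  singularity; truncation makes the clamp unobservable.
* LOO sub-fits that lose rank fall back to the largest extractable
  component count for that fold.
* A q² profile that is negative everywhere selects its argmax; ties in
  the parsimony rule resolve to the smallest component count.
* Problem sizes used by the tests and simulations: 40 molecules on
  grids of roughly 10×8×6 nodes (spacing 2 Å), five-seed null batteries
  at 16 molecules, 10-shuffle randomization — the full suite runs in a
  few seconds on one core.

## Known limitations

* Pseudo-molecule generation is geometric, not chemical: no valence
  model, no conformers, no tautomers or protonation states.
* Hydrophobic/donor/acceptor typing is element-level; real atom-type
  schemes condition on hybridization and environment.
* The PEOE implementation parameterizes the common organic elements
  (H, C, N, O, F, Cl, Br, I, S, P) at the sp³ level.
* Region focusing, anisotropic grids, SAMPLS acceleration and bootstrap
  coefficient errors are out of scope.
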