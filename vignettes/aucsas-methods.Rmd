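---
title: "Reconstructing monomer scattering profiles from aggregate-contaminated SAS data"
author: "aucsas package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing monomer scattering profiles from aggregate-contaminated SAS data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Small-angle X-ray and neutron scattering (SAXS/SANS) measure the
solution structure of a biomacromolecule through its orientation-averaged
intensity $I(q)$.  Oligomeric aggregates -- dimers, trimers, tetramers
formed during purification or storage -- contaminate this measurement
insidiously: at aggregate weight fractions of a few per cent the Guinier
plot still looks perfectly linear, but its slope reports an *ensemble*
gyration radius larger than the monomer's.  Without an independent
species census there is no way to tell a swollen monomer from a slightly
aggregated sample.

Sedimentation-velocity analytical ultracentrifugation (AUC) provides that
census.  A $c(s)$ analysis of the same solution resolves the species by
sedimentation coefficient and yields, per $j$-mer, a weight fraction
$r_j$ and a peak position $s_{20,w,j}$, plus a frictional ratio $f/f_0$.
This package implements the combination of the two measurements: it
removes the aggregate contribution from $I(q)$ and returns the scattering
profile of the monomer alone, $I_1(q)$, with its gyration radius
$R_{g1}$, forward intensity $i_1(0)$, and pair distance distribution
$P_1(r)$.

The method presumes a well-behaved sample: residual aggregates of at
most tetramer order ($j \le 4$) and a total aggregate weight fraction
$r_a = 1 - r_1 \le 0.2$.  Both conditions are checked and violations are
reported as warnings, not errors -- the analysis proceeds, flagged.

## The mixture model

The measured profile of a dilute mixture (no interparticle interference)
is the concentration-weighted sum

$$ I(q) = c \sum_j r_j\, i_j(q), $$

with $i_j = I_j/c_j$ the concentration-normalized profile of the
$j$-mer.  Two pieces of physics make this solvable for $i_1$:

1. **High-q identity.**  Aggregation preserves local internal structure,
   so $i_j(q) \simeq i_1(q)$ at sufficiently high $q$
   ($qR_{g1} \gtrsim 3$).  There $I_1(q) = r_1 I(q)$.
2. **Forward-intensity share.**  $I_j(0) \propto c_j M_j$, so
   $$ I_1(0) = I(0)\,\frac{r_1 M_1}{\sum_j r_j M_j}, $$
   with $I(0)$ from a Guinier fit of the measured profile and the molar
   masses from AUC.

The *first* reconstruction (`firstAUCSAS()`) uses exactly these two
facts, bridging the region between them with a Guinier curve
$I_1(0)\exp(-q^2R_{g1}^2/3)$ joined smoothly to $r_1 I(q)$ at a joint
point $q_c$.  It works well up to $r_a \approx 0.1$.  Beyond that, the
aggregates' inter-subunit interference still inflates $r_1 I(q)$ in the
*middle* $q$ region ($1 \lesssim qR_{g1} \lesssim 3$), the smooth joint
is pushed outside the Guinier region ($q_cR_{g1} > 1.3$), and $R_{g1}$
comes out biased high.

The *improved* reconstruction (`improvedAUCSAS()`) models that
interference explicitly.  Under the decoupling approximation -- subunit
orientations independent of their positions -- the $j$-mer profile
factorizes as

$$ i_j(q) = i_1(q)\,\bigl[\,1 + \beta(q)\,(T_j(q) - 1)\,\bigr], $$

where $T_j(q)$ is the inter-subunit structure factor and
$\beta(q) = \langle F(q)\rangle^2 / \langle |F(q)|^2\rangle \in (0, 1]$
measures the subunit's shape anisotropy.  Substituting into the mixture
sum gives the *mixture factor*

$$ S(q) = \sum_j r_j\,[\,1 + \beta(q)(T_j(q) - 1)\,], \qquad
   I_1(q) = \frac{r_1\,I(q)}{S(q)}, $$

which reduces to the high-q identity as $S \to 1$ and to the
forward-intensity share at $q = 0$ (exactly so when $M_j = jM_1$; the
package asserts this identity to $10^{-10}$).

### The aggregate model

Two structural assumptions close the model:

* **Random-flight arrangement.**  Subunit centres of mass form a freely
  jointed chain with fixed neighbor distance $D$, giving the closed form
  $$ T_j(q) = 1 + \frac{2}{j}\sum_{m=1}^{j-1}(j-m)
     \left[\frac{\sin qD}{qD}\right]^m $$
  (`randomFlightStructureFactor()`).  This *is* the ensemble average of
  the Debye double sum over such chains; the test suite verifies the
  identity against $10^5$ simulated chains.  Note $T_j$ is *not*
  bounded below by 1: the sinc oscillation takes $T_2$ down to
  $\approx 0.78$ near $qD = 4.49$, which is physical interference, not
  an error.
* **Ellipsoidal subunit.**  The subunit is an ellipsoid of revolution
  with semi-axes $r$ and $pr$.  The axial ratio $p$ comes from the AUC
  frictional ratio: the hydration contribution is stripped as
  $(f/f_0)_{\text{shape}} = (f/f_0)\,/\,(1 + \delta/(\bar v\rho))^{1/3}$
  and the Perrin translational friction factor of a prolate ellipsoid is
  inverted numerically (`axialRatioFromFriction()`).  The semi-axis is
  set so the ellipsoid's gyration radius equals $R_{g1}$.

$R_{g1}$ itself appears inside $T_j$ (through $D$) and $\beta$ (through
$r$), so the improved method iterates: the first reconstruction seeds
$R_{g1}^{(0)}$, then $S(q)$ is rebuilt and the connection repeated until
the relative change falls below `tol` (default $10^{-3}$, typically 4-7
iterations).  Later iterations are damped (successive averaging) because
the joint point moves on the discrete $q$ grid and the plain fixed-point
map can two-cycle.  $I_1(0)$ does not depend on $R_{g1}$ and is computed
once.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `hydration` | 0.3 g/g | hydration stripped from $f/f_0$ before the Perrin inversion; the textbook value for globular proteins |
| $D$ | $2R_{g1}$ | neighbor centre distance: touching subunits of effective radius $R_{g1}$; overridable in `aggregateModel()` for sensitivity analysis |
| `guinier_cap` | 1.3 | upper validity limit of $qR_g$ for Guinier analysis |
| `ctol` | 0.02 | relative slope-discontinuity tolerance defining the smooth joint |
| `fail_tol` | 0.15 | discontinuity beyond which the inputs are declared inconsistent |
| `max_iter`, `tol` | 20, $10^{-3}$ | $R_{g1}$ iteration control; `max_iter = 1` gives a single-pass reconstruction |
| `n_basis` | 30 | sine-series size of the $P(r)$ transform |
| quadrature order | 128 | Gauss-Legendre points for orientational averages; exact to $\sim 10^{-10}$ for $qr \le 50$ |

The prolate branch of the Perrin inversion is used throughout.  For
globular proteins the oblate and prolate branches give similar
$\beta(q)$ at the mild anisotropies encountered ($p \lesssim 2$), and
the prolate inversion is single-valued on $p \in [1, 100]$; this is a
documented modelling choice, as is the single shared $f/f_0$ for all
species (what a standard $c(s)$ analysis delivers).

## The smooth joint, in detail

The connection step (`guinierConnect()`) is where the method's output
quality is decided, and its exact construction matters:

1. For every data point $(q_i, I_i)$ of the high-q branch, force the
   Guinier curve through the fixed $I_1(0)$ *and* through that point.
   This determines a candidate radius per point:
   $R_i^2 = 3\,[\ln I_1(0) - \ln I_i]/q_i^2$.
2. The joint $q_c$ is the smallest $q_i$ at which the branch's local
   slope of $\ln I$ versus $q^2$ (rolling 7-point weighted fit) also
   agrees with $-R_i^2/3$, within a tolerance that grants allowances for
   the propagated noise of both value and slope.  Points whose forced
   radius is itself undetermined to better than 15% can never certify a
   joint.
3. $R_{g1}$ is then refined by an error-weighted *fixed-intercept* fit
   of $\ln I_1(0) - \ln I$ against $q^2$ over the maximal contiguous
   slope-continuous run starting at $q_c$.  Long runs extend past the
   strict Guinier region, where every globular shape deviates from the
   pure Gaussian; a quadratic ($q^4$) correction term absorbs that
   leading deviation so the linear coefficient stays an unbiased
   estimate of $R_{g1}^2/3$.  (A plain Guinier-window fit of the
   ellipsoids used here is biased by $+1.2\%$ -- larger than the
   aggregate bias the improved method is meant to remove, so this choice
   is not cosmetic.)  Short runs -- the signature of a late,
   out-of-Guinier joint -- fall back to the one-parameter fit, which
   preserves the first method's documented failure mode instead of
   papering over it.
4. The reported standard deviation of $R_{g1}$ comes from the covariance
   of that final weighted fit; the reconstructed profile follows the
   Guinier curve below $q_c$ and the (corrected) branch above it.

An earlier design -- scanning $R_g$ candidates on a grid and scoring a
combined value+slope gap -- was abandoned: with realistic noise
allowances many $(R_g, q_c)$ pairs tie at zero score and the selection
becomes arbitrary, which destroys the bias structure the method is
supposed to exhibit.  The value-matching construction has no such
degeneracy because value continuity is enforced exactly by construction
and only slope continuity is scored.

## Real-space analysis

`indirectTransform()` expands $P(r)$ in a sine series on $[0, d_{max}]$
(vanishing at both ends by construction), solves the error-weighted
linear system mapping $P(r)$ to $I(q) = 4\pi\int P(r)\,\mathrm{sinc}(qr)\,dr$
with a second-derivative smoothness penalty, and projects negative
excursions to zero.  The regularization weight is chosen by the
discrepancy principle -- the smoothest solution whose *projected*
reduced $\chi^2$ stays within 5% of the best attainable, and at most 1
when reachable.  An L-curve corner criterion was tried first and
over-smoothed clean high-SNR profiles (reduced $\chi^2 \sim 16$ on an
ideal sphere); selecting on the projected solution also prevents the
projection step from silently degrading the fit.

`estimateDmax()` scans candidate dimensions and takes the smallest whose
reduced $\chi^2$ reaches the scan's plateau with a cleanly decaying
$P(r)$ tail.  An intrinsic limitation is documented here deliberately:
for particles whose pair-distance density vanishes *smoothly* at the
maximum dimension (any ellipsoid), truncating the faint outer tail
perturbs $I(q)$ by less than $10^{-5}$ relative -- below any realistic
error band -- so the estimate sits 10-15% below the geometric maximum.
Sharp-cornered distributions (spheres) are recovered to grid resolution.
Maximum-dimension values from scattering are soft for everything else,
and comparisons between software packages should expect
method-dependent differences at this level.

## The synthetic-data generator

`makeDataset()` produces the complete input set the method consumes,
with known ground truth:

* the monomer is the model ellipsoid itself (analytic
  $\langle|F|^2\rangle$ curve, forward value tied to the molar mass by a
  fixed protein-in-water contrast of $2.05\times10^{10}\,$cm/g, which
  gives $0.0464\;\mathrm{mg^{-1}cm^2}$ for a 66.5 kg/mol monomer);
* aggregates are generated by the brute-force ensemble oracle
  (`oracleMixture()`): direct summation of
  $|\sum_k F_k(\mathbf q)e^{i\mathbf q\cdot\mathbf R_k}|^2$ over random
  freely jointed chains, random independent subunit orientations and
  random scattering directions -- no decoupling factorization and no
  random-flight closed form anywhere in the generator;
* heteroscedastic Gaussian noise
  $\sigma(q) = \texttt{noise\_level}\cdot I(0)\cdot(1 + q/q_{max})$;
* a species table that a $c(s)$ analysis of the same sample would
  deliver: masses $jM_1$, sedimentation coefficients from the inverse
  hydrodynamic relation, and an $f/f_0$ built from the scenario's axial
  ratio through the Perrin factor plus hydration.

The default scenario is a serum-albumin-like sample at the upper end of
the admissible range: $R_{g1} = 27.1\,$Å, $p = 1.3$, $M_1 = 66.5\,$kg/mol,
2.0 mg/ml, fractions 0.80/0.14/0.06 for monomer/dimer/trimer
($r_a = 0.20$), 120 log-spaced points on
$q \in [0.008, 0.25]\,$Å$^{-1}$, 0.5% relative noise at $q = 0$.  These
are the study conditions; they are not adjusted per experiment.

```{r demo}
library(aucsas)
ds <- makeDataset(syntheticScenario(seed = 1))
first    <- firstAUCSAS(ds$profile, ds$distribution)
improved <- improvedAUCSAS(ds$profile, ds$distribution)
c(first = rg1(first), improved = rg1(improved), truth = ds$truth$rg1)
```

**What passing tests do and do not show.**  Because subunit orientations
are drawn independently of positions, the decoupling factorization is
*exact* for this generator (up to Monte Carlo error) -- the oracle
comparison validates the implementation, not the physical approximation.
Real aggregates have touching, orientation-correlated subunits and
non-random geometries; for those the model error is a few per cent in
$I_1(q)$ at worst, and the generator's `correlated_orientations` and
`min_separation` stress modes exist to probe exactly that breakdown.
The generator also does not emulate interparticle interference,
instrument smearing, or buffer-subtraction artefacts; profiles are
assumed dilute and reduced.

## Numerical choices

* $\mathrm{sinc}$ and the sphere amplitude switch to 6th-order series
  below $|u| < 10^{-3}$ (catastrophic cancellation).
* Orientational averages: 128-point Gauss-Legendre in $\cos\alpha$ on
  $[0, 1]$.
* Degenerate inputs: duplicate $q$ values are error-weight merged on
  load; a missing error column is synthesized as
  $\sigma = \max(0.01\,I, 10^{-3}\min I_{>0})$ so weighted fits stay
  defined; profiles with fewer than 10 usable rows are rejected.
* Problem sizes in the validation suite (chosen for statistical power:
  Monte Carlo standard errors a factor $\ge 3$ below every tolerance
  they guard): $10^5$ chains for the random-flight identity,
  $2$-$3\times10^4$ ensemble draws per species for oracle comparisons,
  10 seeds for the recovery study.

## Known limitations

* The aggregate model is a *correction*, not a structure determination:
  $T_j$ and $\beta$ describe generic randomly arranged ellipsoids.
  Specific aggregate geometries (e.g. compact tetramers) are absorbed
  only approximately.
* The hydration-stripping step is a documented stand-in for a full
  hydrodynamic shape analysis; $\delta$ enters only through
  $(1+\delta/(\bar v\rho))^{1/3}$ and its default (0.3 g/g) moves $p$
  little for globular proteins.
* At $r_a$ well above 0.2 or $j > 4$ the prerequisites fail and results
  carry warnings; the method degrades gracefully but its guarantees are
  void.
* Maximum-dimension estimates are soft (see above).
* Absolute-scale quantities ($i_1(0)$, masses from it) inherit the
  calibration of the input profile; the package never rescales data.
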