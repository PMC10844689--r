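---
title: "Models and methods behind morphoplast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind morphoplast}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`morphoplast` analyses predator-induced shape plasticity from 2-D landmark
configurations: superimposition, linear models on shape with permutation
inference, phenotypic trajectories over an ordered risk gradient, and
modularity/integration tests over landmark partitions. This vignette
records the statistical models, the numerical conventions, and the design
decisions that were genuinely open, so that a maintainer can tell which
behaviour is principled and which is a convention.

```{r setup}
library(morphoplast)
```

## Superimposition

A configuration is a $k \times 2$ matrix (the default scheme has $k = 6$:
eye, neck, mid-dorsal, spine-base, mid-ventral, rostrum; module
definitions always reference these labels, never indices). Generalized
Procrustes Analysis iterates: translate each configuration to the origin,
scale it to unit centroid size $CS = \sqrt{\sum_i \lVert x_i - \bar x
\rVert^2}$, rotate it onto the current consensus by the SVD solution, then
replace the consensus with the rescaled mean. Iteration stops when the
summed squared Procrustes distance changes by less than `tolerance`
(default `1e-10`, on dimensionless unit-size shapes); `max_iter = 100`
exceeds what realistic landmark data needs by an order of magnitude, and
hitting it flags `converged = FALSE` with a warning rather than an error.

Three conventions make results reproducible and are worth stating:

* **Reflections are disallowed** during alignment (rotation determinant
  forced to $+1$). Mirroring is an explicit ingest step
  (`mirror_configurations()`), because absorbing reflections inside GPA
  would silently hide digitisation orientation errors.
* **Consensus orientation.** GPA is defined only up to a global rotation.
  The consensus is rotated onto its principal axes with the
  largest-magnitude loading made positive (second axis fixed by the
  determinant), so repeated runs, permuted inputs, and nuisance-transformed
  inputs give numerically identical coordinates.
* **Tangent projection.** Aligned configurations are orthogonally
  projected onto the hyperplane tangent to the unit sphere at the
  consensus. This linearises the unit-size constraint: exactly four
  coordinate dimensions (two translations, rotation, scale) are null in
  any downstream PCA, and the mean of the aligned configurations equals
  the consensus exactly. Without it, the fourth constraint is quadratic
  and the "null" eigenvalue is merely small, confounding dimension counts.

Semi-landmarks are treated as fixed points; no sliding by bending energy
or Procrustes distance is performed, because the digitisation protocol
that produces them (geometric construction from guide lines) defines them
as point estimates, not curve samples.

The size covariate used downstream is centroid size. The digitisation
protocol describes the *squared* quantity; because a monotone transform
is not innocuous once size enters a linear model, the variant is explicit
(`size_variant = "cs"`, `"cs-squared"`, `"log-cs"`) with standard CS as
default.

**Repeatability.** With every photograph digitised once per session
($m \ge 2$ sessions, jointly superimposed), a one-way Procrustes ANOVA on
individual identity yields mean squares using the Procrustes shape
degrees of freedom (coordinate df $\times (2k - 4)$). Variance components
$s^2_a = (MS_a - MS_w)/m$ and $s^2_w = MS_w$ give repeatability
$R = s^2_a / (s^2_a + s^2_w)$, clamped to $[0, 1]$. $R$ is invariant to
the df convention; the MS values themselves are not, which is why the
convention is stated.

## Procrustes ANOVA with residual randomization

The response is the $n \times 2k$ matrix of aligned coordinates. Sums of
squares are sequential (type I): the design matrix is built term by term
and orthonormalised against everything before it, so term SS is the drop
in residual summed squared Procrustes distance, the decomposition is
additive by construction, and rank-deficient terms are reported as
aliased rather than silently dropped. Predation risk enters as a
categorical factor over its six declared concentrations (df = 5) —
consistent with interaction dfs of 5 (risk × instar) and 10 (risk ×
clone) — not as a linear covariate.

Significance uses residual randomization in a permutation procedure
(RRPP): for each term, residuals of its *reduced* model are re-assigned
to specimens (one shared permutation per iteration across terms), the
term statistic recomputed, and $p = (b + 1)/(B + 1)$. The default
statistic is the term SS (the effect size $Z$ is the observed SS as a
standard-normal deviate of its null distribution); $F$ recomputed per
permutation is available via `effect_type = "F"` and is equivalent for
one-term models, where the permuted total SS is invariant. The default
$B = 10{,}000$ matches common practice for shape ANOVA; tests use smaller
$B$ since only the null-distribution mechanics, not Monte-Carlo
resolution, are under test.

Two floating-point conventions matter for exactness:

* Permutations that are *analytically* tied with the observed statistic
  (e.g. within-group relabelings) can differ at machine precision
  depending on summation order. All permutation counts therefore use a
  relative tolerance of `1e-8`, counting ties toward the null — the
  conservative convention for permutation tests.
* When a complete enumeration is supplied (`perm_matrix`, or
  `null = "exhaustive"` in the modularity/integration tests), the
  identity element is part of the null set and $p$ is the plain
  proportion at least as extreme — an exact test, identical to the
  $+1$-corrected estimate over the non-identity elements.

Least-squares cell means (`fit_lsmeans()`) are arithmetic cell means
under balance; with `average_over` factors, each grouping cell is the
unweighted mean of its subcell means, so unbalanced replication does not
tilt group means toward over-sampled subcells.

## Phenotypic trajectories

A trajectory is a group's sequence of least-squares mean shapes in
increasing risk order, as a matrix of $L$ points in the flattened shape
space. Attributes:

* **Magnitude** — path distance, the summed Euclidean segment lengths.
  Pairwise statistic: $|PD_1 - PD_2|$.
* **Direction** — the first principal axis of the $L$ points, sign-fixed
  by positive projection onto the last-minus-first chord; the pairwise
  statistic is the angle between unit directions, in degrees. The
  principal-axis definition is the default because it remains stable for
  curved trajectories (the carapace-bulge type of response); the plain
  chord is available via `method = "chord"` since the published analyses
  of this kind do not pin down which is meant. On a one-dimensional shape
  subspace both collapse to 0 or 180 degrees exactly.
* **Shape** — treat the $L$ points as "landmarks" in $2k$ dimensions,
  centre, scale to unit size, optimally rotate (full orthogonal
  superimposition, reflection permitted since trajectory chirality is not
  meaningful), and take the residual root-sum-of-squares.

Attributes are computed in the full Procrustes coordinate space; PCA is
used only to visualise trajectories. Significance is again RRPP: the
reduced model is the additive group + gradient model, its residuals are
permuted, cell means and all attributes recomputed each iteration
(default $B = 1000$; no published iteration count exists for this test).

One refinement matters for calibration of these *derived* statistics.
Observed residual cell means are orthogonal to the reduced design by
construction, so observed attributes carry estimation noise only in the
interaction subspace; raw permuted residuals regain full-dimensional
noise on top of the fixed fitted part, double-counting main-effect
estimation noise and visibly distorting the attribute nulls (the term-SS
statistics of the ANOVA are immune because their bases are orthogonal to
the reduced space). Permuted residuals are therefore re-residualized
against the reduced design before the fitted values are added back,
which makes the null attribute distribution exchangeable with the
observed one; calibration studies in the test suite confirm nominal 5%
rates under both a pure-noise null and a shared-response null.

## Modularity and integration

For a partition of the landmarks into two labelled blocks (each block at
least two landmarks; presets `head-body` and `dorsal-ventral`), with the
coordinate covariance partitioned into $S_{11}, S_{22}, S_{12}$:

$$CR = \sqrt{\frac{\sum S_{12}^2}{\sqrt{\sum S_{11}^{*2} \sum
S_{22}^{*2}}}}$$

with diagonals excluded from the within-block sums. The null re-assigns
whole landmarks (x and y kept together) to blocks of the observed sizes;
modularity is a *small* observed CR (lower-tail p). With six landmarks in
a 3|3 split only $\binom{6}{3} = 20$ assignments exist (10 distinct CR
values, since CR is symmetric under block swap): the sampled null then
warns and resamples, `null = "exhaustive"` enumerates, and — importantly —
the smallest achievable exact p is $2/20$. A 5% level is *unattainable*
at this granularity for any implementation; calibration studies of the CR
test in this package therefore use a 12-landmark 6|6 configuration
(924 assignments), while the six-landmark analyses report the exact p for
what it is.

Two-block PLS takes the SVD of $S_{12}$; scores are the centred blocks
projected on the first singular vectors (sign fixed by the
largest-magnitude component of the block-A vector; the block-B vector is
paired with it), and r-PLS is the absolute correlation of the first score
pair. Integration is a *large* observed r-PLS against row permutations of
one block (upper-tail p, default $B = 999$ as in standard practice for
these tests). Both statistics are computed on all specimens pooled across
clones and risk levels; pooling matches the way these tests are usually
reported for plasticity data (a single score scatter coloured by risk),
and group-mean structure is part of the covariation being summarised. A
residualised (within-group) variant would be a straightforward extension
but is deliberately not the default.

## Shape PCA and thin-plate splines

PCA is the eigendecomposition of the covariance of aligned flattened
coordinates via SVD; axis signs follow the largest-loading-positive
convention; exactly $\min(n-1, 2k-4)$ axes are non-null (see tangent
projection above), and variance fractions are reported over the non-null
axes. Axis meaning is visualised by reconstructing
`consensus + score * loading` at the observed score extremes (or a
multiple of the axis SD) and warping a regular lattice through the
thin-plate spline from the consensus to that target. The TPS kernel is
$U(r) = r^2 \log r^2$ with $U(0) := 0$ (removable singularity); the
$(k+3)$-equation linear system enforces exact interpolation, the affine
part absorbs linear maps (zero bending energy exactly for affine
targets), and bending energy is the quadratic form of the warp weights
with the kernel matrix. The default lattice is $24 \times 24$ over the
reference bounding box padded by 10%. Collinear references make the
system singular and are reported as such.

## The synthetic-data generator

`simulation_spec()` encodes the generative model the analyses assume.
Cell mean shapes (units: body length of the stylised outline, which is a
deliberately synthetic hexagon, not a tracing of a real animal):

$$\mu_{cir} = \text{base} + \text{instar offset} \cdot [i = 3] +
g_c f(r) d_c + \eta\, r\, u_{neck}$$

where $d_c$ is a clone-specific unit direction in shape space, $g_c$ its
gain, $f$ the risk response (linear by default; a saturating form is
available because real dose-response curves flatten), and $\eta$ a direct
displacement of the neck landmark along its outward normal — the
inducible-defence signature. Directions built with `tangent_directions()`
are orthogonal to the similarity transforms of the base shape, so they
survive superimposition to first order and make trajectory ground truth
well defined. Specimen noise is drawn from a block covariance: coordinate
SD `sd_within` (default 0.01 body lengths), correlation `rho_within`
(0.3) within a module and `rho_between` (0.1) between modules, plus
independent digitisation error (`digitisation_sd`, default 0.003);
positive semi-definiteness is validated at construction. Per-specimen
nuisance rotation (uniform $\pm\pi$), translation ($\pm 0.5$) and
log-uniform scale (0.7-1.4) exercise superimposition. Defaults emulate
the study design: 3 clones — one strong inducer (gain 0.10) and two weak
ones (0.04), the divergent clone's direction 40 degrees off the shared
response direction — 2 instars, 6 risk levels (0, 0.1, 0.25, 0.5, 0.75,
1 uL/mL), and 12 replicates per cell (the midpoint of the reported 4-20
range; an `"unbalanced"` preset spans it).

Ground truth shipped with every dataset: true cell means; true
trajectories, path distances and pairwise angles computed from the
*Procrustes-superimposed* true cell means (the estimand of the pipeline,
not the raw generator coordinates, which differ by the tangent-space
projection and unit-size scaling); and closed-form population CR and
r-PLS evaluated on the exact covariance (for equal variances and
exchangeable correlation the CR closed form is
$\sqrt{p_1 p_2 / \sqrt{p_1(p_1-1) p_2(p_2-1)}} = \sqrt{6/5}$ for 6|6
coordinates).

What the generator does *not* emulate: allometric size-shape covariance
within cells, non-Gaussian digitisation error, curved (saturating)
trajectories unless requested, and real anatomical proportions. Passing
recovery tests therefore demonstrates that the estimators recover the
model they assume under realistic noise and nuisance — not that real
*Daphnia* data satisfy that model.

## Validation problem sizes

The test suite validates, at sizes chosen to make each property sharp
while keeping the default run in the minutes range:

* exact superimposition of 50 nuisance-transformed copies (pairwise
  distances below $10^{-8}$);
* permutation p-values identical to complete enumeration (all $7! = 5040$
  residual assignments for the ANOVA, all 20 landmark re-assignments for
  CR, all $6! = 720$ row permutations for PLS);
* 5% type-I error within $\pm 2$ percentage points over 500 null
  simulations for each permutation test ($B = 999$; the CR calibration
  uses the 12-landmark configuration discussed above);
* trajectory angle recovery within 5 degrees and path-distance recovery
  within 5% (angles 0/30/60/90 degrees, 50 replicates per cell, 25
  simulations per angle). Path distance is a summed norm and thus
  positively biased by cell-mean noise of order
  $\sigma^2 k / (n \cdot \text{segment length})$; the recovery benchmark
  runs at digitisation-scale noise where the estimand dominates this
  floor, which is also the regime of the real data;
* sample CR within $\pm 0.02$ of the population closed form at
  $n = 5000$;
* exact TPS interpolation and affine exactness on 100 random
  configurations.

## Known limitations

* 2-D landmarks only; no 3-D superimposition, no sliding semi-landmarks.
* Sequential sums of squares only: term order is meaningful on unbalanced
  data (this is tested, not hidden). No type II/III, mixed models, or
  phylogenetic GLS.
* Trajectories over a single ordering factor.
* Two modules per partition; no multi-module CR or evolutionary-rate
  extensions.
* The CR test's p granularity with six landmarks is a property of the
  statistic's null space, not of this implementation; interpret 3|3
  partitions accordingly.
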