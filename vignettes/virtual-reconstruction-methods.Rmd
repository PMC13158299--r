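---
title: "Virtual reconstruction and allometry analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual reconstruction and allometry analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retromorph)
```

retromorph implements the quantitative core of a virtual-reconstruction
workflow for plastically deformed specimens — typically fossil crania —
together with the shape-statistical machinery used to analyse evolutionary
allometry in the comparative sample the reconstruction is judged against.
This vignette explains the models, their assumptions, the tunable
parameters, and the design decisions taken where more than one reasonable
implementation exists.

## Shape variables

A specimen is a configuration of k 3D landmarks in mm
(`landmark_config`), with per-landmark roles (anatomical landmark, curve
semilandmark, surface semilandmark), a missing-data mask and a bilateral
pairing table.  Generalized Procrustes analysis (`gpa`) removes position,
orientation and — in partial GPA — scale, iterating optimal proper
rotations against a running mean until the mean changes by less than
1e-10 (Frobenius norm; at most 100 iterations).  Reflections are never
introduced by superimposition: handedness is biological information, and
mirroring is an explicit symmetry operation, not an alignment choice.
Centroid size (CS) is measured on the raw coordinates before any scaling.
Boas (form-space) coordinates are the aligned coordinates re-multiplied
by CS — registration without scaling — and dividing them by CS recovers
the unit-size Procrustes coordinates exactly.

Statistics are computed in the linear tangent space at the mean shape
(orthogonal projection).  The package reports the correlation between
tangent (Euclidean) and Riemannian pairwise distances as a diagnostic;
for biologically realistic dispersion it is ≈ 0.999 or better, which is
what licenses linear multivariate models on tangent coordinates.  The
Riemannian distance itself is evaluated through the chordal distance
under the optimal rotation, `2*asin(c/2)`, which is algebraically the
usual arc-cosine of summed singular values but keeps full precision for
near-identical shapes — several exactness guarantees below are asserted
at the 1e-8 level, where the naive arc-cosine formula is pure round-off.

How many principal components of shape carry signal is decided by the
sequential eigenvalue-ratio rule: components are retained while adjacent
ratios exceed `exp(2*sqrt(2/n))` (`meaningful_pc_threshold`), which
evaluates to 1.62 at the canonical comparative sample size n = 34.  The
alternative exponent using n − 1 gives 1.65 at that n and is not used.

## Thin-plate splines, sliding, missing landmarks

The 3D thin-plate spline (`tps_fit`) uses the volumetric biharmonic
kernel, linear in distance; the sign is chosen as U(r) = −r so that the
kernel is conditionally positive definite and the bending energy
trace(WᵀKW) is non-negative, zero exactly for affine maps.  The kernel
system is solved densely with one step of iterative refinement, and
kernel distances are computed from explicit coordinate differences —
the squared-norm expansion loses about sqrt(machine-eps) of absolute
accuracy near r = 0, which would otherwise corrupt evaluation at the
control points themselves.  Bending energy is invariant to rigid motion
of the target and scales as 1/c when the source configuration is scaled
by c at fixed displacement magnitudes (both checked numerically in the
test suite).

Curve semilandmarks slide along their polyline tangents (central
differences) to minimize the bending energy of the TPS from a reference;
each proposed move is projected back onto the polyline and accepted only
if it does not increase the specimen's energy, so the per-sweep energy
sequence is non-increasing for a fixed reference.  When the reference is
the recomputed sample mean (the default, 3 sweeps), the energy functional
itself changes between sweeps and strict monotonicity across sweeps is
not guaranteed — the test suite therefore asserts monotonicity against a
fixed reference.  The number of sweeps and the choice of reference are
exposed as options because neither is canonical.

Missing landmarks are estimated by a TPS fitted from the reference
mean's shared landmarks onto the target's present landmarks; the missing
positions are the images of the reference mean's corresponding points.
Estimated landmarks are flagged and barred from subsequent sliding.

Bézier machinery (`bezier_points`, de Casteljau evaluation) supports the
gap-grid builder: three landmark series spanning a gap are resampled to
40 equidistant (arc-length) points, the i-th points across series are
"inverted" into transverse triples, and a Bézier curve through each
triple is sampled at 70 evenly spaced points, giving a 40 × 70 point
cloud that bridges the gap.  Arc-length inversion uses composite Simpson
quadrature on 20,000 subintervals, accurate well below the 1e-6 equal
spacing tolerance asserted in the tests.

## Retrodeformation by bilateral symmetry

The closed-form retrodeformation (`retrodeform_landmarks`) assumes the
undeformed specimen was bilaterally symmetric and the deformation is
approximately affine.  The configuration is first rotated into a
canonical frame in which the estimated midsagittal normal (the summed
left-minus-right pair differences) is the x axis; for an object-symmetric
configuration this makes it exactly coordinate-plane symmetric.  The
least-squares affine map A carrying the configuration onto its
reflected-relabeled mirror is then estimated, and the principal matrix
square root of A — the halfway transform — is applied.  Because
conjugation by the reflection J sends A to A⁻¹, the square root commutes
with the mirror and the halfway-transformed configuration is exactly
symmetric; residual (non-affine) asymmetry is removed by
reflected-relabeling averaging, and centroid size is restored.

What is recoverable deserves care.  Write an affine deformation as the
sum of a mirror-even part (J D J = D) and a mirror-odd part.  The odd
part — e.g. a shear displacing the midline-normal axis by a transverse
direction — breaks symmetry and is inverted *exactly* by the halfway
transform.  The even part (uniform or axis-aligned stretches) preserves
symmetry and is invisible to any symmetry-based method: a template
stretched 2× along its midline axis is still perfectly symmetric, and no
bilateral criterion can know the stretch happened.  The recovery
guarantees and the synthetic deformation generator
(`apply_plastic_deformation`) therefore work with mirror-odd shears; the
unilateral mode blends the shear through a logistic ramp across the
midline, emulating one-sided compression, which the affine protocol can
only partially correct — the asymmetry diagnostics make that residual
measurable.  If the estimated affine map has eigenvalues on the negative
real axis, no real principal square root exists; the function falls back
to averaging-only symmetrization and says so in the result.

## Reference-hyperplane restoration

`restore_hyperplane` projects a deformed target onto the affine hull of
reference specimens in a principal-component frame: GPA of references
plus target, PCA of the joint tangent coordinates (including the target,
so that three references plus the target make the stated first three
components carry all reference variation; a references-only eigenbasis
is available behind a flag), orthogonal projection of the target's score
vector onto the reference hull, exact inversion of the tangent
projection, and rescaling to the target's own centroid size — the
restored fossil should reflect the fossil's size, not the references'.
With three references the hull is a 2-plane; restoration is idempotent,
and a target constructed as hull point plus hull-orthogonal deformation
is returned to the hull point.

The exactness tests construct such targets with the generator
`simulate_reference_set`, which purges the deformation direction of the
hull directions and of the similarity directions (translations, scaling,
infinitesimal rotations).  Superimposition is nonlinear, so these
constructions are exact only to second order in the reference
dispersion; the closure tests therefore use a small dispersion (1e-4 of
CS, where the quadratic terms sit near 1e-9) while statistical tests use
realistic dispersion (0.03).  This is a property of shape space, not of
the implementation.

## The allometry engine

`rrpp_lm` fits multivariate linear models of shape on size and group by
least squares and assesses each term by residual randomization (RRPP):
the residuals of the term's reduced model are permuted, added back to the
reduced fit, and the term's F statistic recomputed; p is
`(count of permuted F ≥ observed + 1)/(n_perm + 1)` and the effect size
Z is the standardized position of the observed F in the permutation
distribution (computed on raw F by default; a log-F option exists since
implementations differ).  Type I SS compares sequentially nested models;
Type II compares each term against the model holding every term that
does not contain it; Type III drops each term from the full model under
sum-to-zero contrasts.  For balanced single-factor designs all three
coincide, which the tests assert.  The permutation kernel exploits the
identity that each permuted sum of squares is a quadratic form in a
fixed contrast matrix and the row/column-permuted Gram matrix of reduced
residuals, so a fit costs one set of hat matrices plus
O(n_perm × n²) compiled work regardless of the number of shape
variables.

Generalized least squares enters by whitening the data and design with
the inverse square root of a supplied covariance; an identity covariance
reproduces OLS exactly.  The phylogenetic covariance
(`phylo_covariance`) is the Brownian-motion matrix of shared root-to-MRCA
path lengths (via ape), expanded to specimens by duplicating species
rows and adding a 1e-8 relative diagonal jitter for invertibility.
Restricted permutation schemes (shuffling only within declared blocks)
support designs with non-exchangeable strata; `blocked_manova` applies
the same idea through vegan's permutational MANOVA for the
trial-structure test of the error protocol.

Slope homogeneity between two groups is tested by the vector correlation
(cosine of the angle) between per-group multivariate regression vectors,
with the angle's null distribution generated by RRPP from the
common-slope model.  Group dispersion homogeneity embeds the Euclidean
distance matrix by principal coordinates, measures each specimen's
distance to its group spatial median (Weiszfeld iteration to 1e-12), and
permutes group labels on the resulting one-way F.  Collinearity between
size and group is summarized by VIF = 1/(1 − R²) and its reciprocal.
Kendall's tau-b is computed from explicit concordance counts with tie
correction, with exact enumeration of the null for n ≤ 8 and the
tie-corrected normal approximation otherwise.

### The rarefaction + null-permutation protocol

With 27 specimens in one genus and 7 in the other, a non-significant
size-by-genus interaction could simply reflect the imbalance.
`rarefaction_slope_test` subsamples the majority genus to the minority
size (default 1,000 iterations), refits the unique-allometry model
(interaction, Type III) each time, and nests 20 genus-label shuffles
within each iteration — 20,000 null tests at the canonical settings —
recording interaction p and Z throughout.  A real but modest interaction
shows up as observed Z medians sitting above the null-shuffle Z medians,
a structure the shuffles destroy; calibration means the observed
interaction rejects at about the nominal rate when slopes are truly
parallel.

Two properties of this procedure matter for interpreting the package's
own validation.  First, rarefaction draws within one dataset share the
minority group and are strongly correlated, so type-I calibration is
measured across independent replicate datasets, not across iterations.
Second, residual-permutation tests are approximate in small samples: at
the rarefied n = 14 with ~100 tangent variables the interaction
p-distribution is measurably compressed toward its center, giving
rejection rates nearer 2–4% than 5% at α = 0.05.  This conservatism is
a property of the method class, not a defect of this implementation (the
same machinery is calibrated within binomial error at n = 34), and it is
consistent with rarefied interaction rejection rates below nominal
reported for comparable analyses.

## Measurement error

`simulate_digitization_trials` emulates repeated digitization (default
3 specimens × 4 trials, iid Gaussian jitter, optional per-specimen
resolution multipliers).  `landmark_error_summary` reports per-landmark
standard deviations of trial-to-mean Euclidean distances in mm and as %
of CS, in raw space or after Boas registration, flagging landmarks above
the conventional 1 mm and 2 mm thresholds; injected per-trial rotations
inflate raw SDs but not Boas SDs, a directional check that registration
choice matters only when orientations differ.  `procrustes_anova_icc`
superimposes all trials, runs a two-way specimen × trial RRPP ANOVA
(Type II) on tangent coordinates, and derives repeatability as a one-way
mean-squares ICC, `(MS_spec − MS_res)/(MS_spec + (k − 1) MS_res)`,
clamped to [0, 1]; measurement error is ME% = (1 − ICC)·100.  The ICC
variant (one-way, consistency) is a documented default — the standard
choice in geometric-morphometric error studies — and recovers generated
among/within variance ratios of 0.5, 0.9 and 0.99 within simulation
error.

## The synthetic-data generator

`make_template` builds a smooth, exactly symmetric configuration (14
pairs + 5 midline points = 33 landmarks by default, CS 100 mm).
`simulate_allometric_sample` draws two groups (27 + 7 specimens across
12 species) with per-group CS distributions N(95, 8²) and N(115, 8²) mm
— overlapping ranges, as in mixed macaque/baboon samples — a common
allometric slope of 3.5e-3 unit-shape displacement per mm CS, a group
mean offset of 0.075, optional slope divergence (group B's slope rotated
by a fixed angle toward an orthogonal direction), and 0.5 mm coordinate
noise, then places each specimen at its size in a random pose.  The
slope and offset magnitudes were fixed once so that size explains ≈ 14%
and genus ≈ 9% of tangent variance after GPA, the variance structure the
statistical engine is meant to operate in; the mild-divergence scenario
(25°) yields an interaction explaining ≈ 1.5–2% of variance with
non-significant p, i.e. coherent low-positive interaction structure for
the rarefaction null shuffles to destroy.  All randomness flows from a
single seed, and regeneration is bit-identical.

What the generator does not emulate: real cranial geometry (templates
are abstract smooth configurations with the right algebraic structure),
taphonomic noise beyond affine/unilateral shear, ontogenetic series,
sexual dimorphism, or phylogenetic signal in shape (species labels
structure the covariance, not the means).  Passing tests therefore
demonstrate the statistical and geometric machinery under known truth,
not the anatomical fidelity of any particular reconstruction.

## Problem sizes used in validation

The shipped test-suite and acceptance script use: 500 replicate null
datasets (n = 34, 999 permutations) for RRPP calibration; 200
independent datasets for rarefied-interaction calibration; 200
rarefaction iterations × 10 nested shuffles for the nested protocol;
100 random shears for retrodeformation closure; 6 replicate simulations
per ICC ratio.  These sizes put the Monte-Carlo error of each check well
inside the asserted intervals while keeping a full validation run in the
low minutes on one CPU.

## Known limitations

* Retrodeformation cannot recover mirror-even deformation components
  (inherent to symmetry-based methods), and the affine protocol only
  mitigates unilateral deformation.
* Sliding is sequential per point rather than a joint solve; with the
  accept-if-decrease guard it is robust but may need more sweeps than a
  joint minimization.
* The rarefied interaction test is mildly conservative at n = 14 (see
  above).
* No mesh repair, surface registration, or semilandmark acquisition from
  real meshes: mesh support is limited to I/O and TPS transfer of
  landmark-level corrections.
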