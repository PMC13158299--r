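# retromorph

Virtual reconstruction and allometry analysis for 3D landmark data.

Paleontological specimens are routinely distorted: post-mortem plastic
deformation shears a cranium away from its original, bilaterally
symmetric form, and the question of which genus a fossil resembles then
hinges on shape statistics computed over a comparative sample whose
members differ in size.  retromorph implements both halves of that
problem for k×3 landmark configurations:

**Reconstruction.**  Bilateral *retrodeformation*: the least-squares
affine map `A` carrying a configuration onto its reflected-relabeled
mirror is estimated and its principal matrix square root — the *halfway
transform* `A^(1/2)` — undoes the asymmetric (mirror-odd) component of
the deformation exactly; residual asymmetry is removed by
reflected-relabeling averaging, and the correction transfers to a
surface mesh by thin-plate-spline (TPS) warping.
*Reference-hyperplane restoration*: the deformed target is superimposed
with undeformed reference crania, and its score vector in the leading
principal components is replaced by its orthogonal projection onto the
affine hull of the reference scores — deformation orthogonal to the
reference variation is removed entirely.  Supporting machinery: 3D TPS
with bending energy (`U(r) = −r` kernel), bending-energy semilandmark
sliding, TPS estimation of missing landmarks, Bézier resampling and the
40 × 70 gap-bridging point grid.

**Statistics.**  Generalized Procrustes analysis with tangent-space
projection and Boas (form-space) coordinates; shape PCA with projected
(held-out) fossils and the eigenvalue-ratio rule
`exp(2·sqrt(2/n))` for meaningful components (1.62 at n = 34);
residual-randomization permutation MANCOVA (`rrpp_lm`) of shape on
centroid size and group with Type I/II/III sums of squares, permutation
p-values `p = (#{F* ≥ F} + 1)/(n_perm + 1)`, effect sizes Z, optional
phylogenetic GLS (Brownian covariance from a Newick tree) and restricted
permutation blocks; a vector-correlation homogeneity-of-slopes test; a
nested *rarefaction + null-permutation* protocol for unbalanced designs
(subsample the majority genus, refit the interaction, shuffle genus
labels within each rarefied set); spatial-median dispersion
homogeneity, Kendall's tau-b, VIF/tolerance; and a measurement-error
protocol (per-landmark SDs, trial Riemannian distances, two-way
Procrustes ANOVA repeatability with `ICC = (MS_s − MS_r)/(MS_s + (k−1)MS_r)`
and `ME% = (1 − ICC)·100`).

A synthetic-data module generates bilaterally symmetric templates,
two-genus allometric samples (27 + 7 specimens, 33 landmarks, 12
species), plastic deformations, digitization trials and restoration
reference sets with known ground truth, so every stage is testable
without access to specimen data.

## Worked example

```r
library(retromorph)

## a study-like sample: 27 + 7 specimens, 33 landmarks, common slope
sim <- simulate_allometric_sample(seed = 7)
al  <- gpa(sim$configs)
al
#> Procrustes-aligned sample: 34 specimens, 33 landmarks (unit_size)
#>   tangent/shape-space distance correlation: 1.0000

## common allometry: shape ~ size + genus, Type II SS, RRPP
fit <- rrpp_lm(~ size + group,
               data.frame(size = al$centroid_sizes,
                          group = sim$metadata$genus),
               al$tangent, ss_type = "II", n_perm = 999, seed = 1)
fit
#> Residual-randomization linear model (Type II SS, 999 permutations)
#>           Df       SS       MS   Rsq     F     Z     p
#> size       1 0.021620 0.021620 0.137 8.714 23.67 0.001
#> group      1 0.008552 0.008552 0.054 3.446 13.65 0.001
#> Residuals 31 0.076920 0.002481 0.488    NA    NA    NA
#> Total     33 0.157700       NA 1.000    NA    NA    NA

## retrodeformation: shear a symmetric template, then undo it
tm  <- make_template()
def <- apply_plastic_deformation(tm$config, "affine_shear", magnitude = 0.2)
rd  <- retrodeform_landmarks(def, tm$pairing)
rd
#> Retrodeformation: asymmetry 0.142 -> 7.5e-16
riemannian_distance(rd$retro_coords, tm$config$coords)
#> [1] 4.67e-16
```

Size explains 13.7% and genus 5.4% of tangent shape variance in this
draw, both significant at the permutation floor `p = 1/1000` — the
variance structure the generator is calibrated to.  The shear raised the
asymmetry score (a Riemannian distance between the configuration and its
mirror image) to 0.142 radians; retrodeformation drives it to machine
zero and recovers the true template exactly, because a transverse shear
is mirror-odd and therefore fully identifiable from bilateral symmetry
(the methods vignette explains what is and is not recoverable).

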