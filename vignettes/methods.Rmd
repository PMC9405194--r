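---
title: "Methods: synthetic morphometry and association scanning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic morphometry and association scanning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphogwas)
```

`morphogwas` couples two models: a geometric one (how four conformation
measurements are read off a fused multi-view point cloud) and a statistical
one (how those traits are screened and scanned against a SNP panel). This
vignette records the assumptions, the defaults and why they were chosen, the
numerical choices, and what the synthetic generators do and do not emulate.

## The measurement model

All clouds live in a world frame with X the anterior–posterior body axis
(head at low x), Y lateral (left = +Y), Z up, and the floor at `z = 0` — the
frame a calibrated walk-through rig produces. Per-view clouds are expressed
in camera frames; `fuse_views()` maps each through its camera-to-world rigid
transform and concatenates. Calibration itself is out of scope: transforms
are inputs, as delivered by external calibration of the rig.

The four measurements are defined as:

* **withers height / hip height** — perpendicular distance from the withers
  (highest point of the shoulder ridge) and sacrum (highest point of the
  rump) landmarks to the ground plane, `|n·p + d| × 100` cm;
* **chest width** — full 3-D Euclidean distance between the posterior
  corners of the two shoulder blades. Using the 3-D distance rather than its
  Y component is a deliberate choice; on the synthetic animals the two
  differ by well under 0.5% because the paired landmarks share an x
  position;
* **chest girth** — the cloud is sliced by a vertical slab
  `|x − x0| ≤ 1 cm` at the shoulder-corner x position, projected to (y, z),
  and the closed perimeter of the 2-D convex hull is returned. The hull
  under-measures concave sections by construction; that is the intended
  definition (a taut-tape girth rather than a contour girth).

Numerical choices: the hull is Andrew's monotone chain with collinear
boundary points dropped (the perimeter is unaffected); ties in landmark
detection resolve to the lowest point index, so results are reproducible;
slabs with fewer than 3 usable or non-collinear points are an error naming
the slab occupancy, never a silent `NA`. The slab half-width default of 1 cm
sits far above the point spacing of a fused depth-camera cloud and far below
the girth curvature scale; halving or doubling it moves synthetic girths by
well under 1%.

The ground plane is `z = 0` by default (`fixed_z0`), trusting the rig
calibration. `robust_fit` instead runs a random-sample consensus fit on the
lowest-z fifth of the cloud (200 iterations, 1 cm inlier tolerance, fixed
internal seed, least-squares refit on the consensus set, normal oriented
upward). It exists for clouds whose floor is present but not axis-aligned;
it is not a full scene-segmentation step.

Landmark detection is a deliberately simple heuristic stand-in for whatever
the original rig used (possibly manual annotation): withers = highest point
within the anterior 20–45% of the x extent, sacrum = highest within
70–95%, shoulder corners = extreme ±Y points in the slab through the
withers x. It is accurate on the synthetic shapes (heights to well under
1%), but its width estimate rides on the two extreme lateral points and
therefore absorbs roughly `+4 sigma` of sensor noise (~2 cm at 5 mm noise,
i.e. ~4% of a 52 cm chest). Supplying landmarks is supported everywhere and
is the right mode when an upstream annotator exists.

## The synthetic animal

The generator's job is to produce clouds whose true measurements are known
*analytically*, so measurement error can be scored without circularity.
The surface is an elliptical cylinder along X whose cross-section at x is a
pair of half-ellipses sharing the lateral semi-axis `ry`: the lower half has
fixed vertical semi-axis `rz`, the upper half `rz · s(x)` where `s(x)` adds
two Gaussian-profile dorsal ridges (sd 5% of body length) at the withers
(x = 0.30 L) and sacrum (x = 0.82 L). Ends taper elliptically over the
outer 8% of L; four leg cylinders set the belly clearance; the floor is
z = 0. Because the ridges are separated by ~10 ridge SDs, their overlap is
below double precision and every target has a closed form:

* withers height = `leg + rz + rz·s(x_w)`, hip height likewise at `x_s`;
* chest width = `2 ry`;
* chest girth = the mean of the Ramanujan-II perimeters of the upper and
  lower half-ellipses, `P(a,b) = pi (a+b) (1 + 3h/(10 + sqrt(4-3h)))`,
  `h = ((a-b)/(a+b))^2`, whose relative error is far below 1e-9 at these
  eccentricities.

A two-half-ellipse section was chosen over "a bump added to the ellipse"
because the girth is measured exactly at the withers section: any additive
bump there would destroy the closed-form perimeter that the error scoring
depends on. `shape_params_for_measurements()` inverts the model (fixed 5%
withers ridge, 1-D root find on the girth equation, then leg length and
sacrum ridge from the two heights), so a herd of phenotype records maps to a
herd of surfaces whose ground truths equal those records exactly.

Views emulate the three-camera rig: each of left/right/top rejection-samples
the surface to exactly `points_per_view` points in its visibility half-space
(side views keep `y ≥ -5 cm` / `y ≤ 5 cm`, the top view the upper torso;
the overlap margins guarantee full coverage), adds isotropic per-coordinate
Gaussian noise (`noise_sd`, default 5 mm), and is expressed in its camera
frame. The default density of 20,000 points per view is a realistic
decimated fused-cloud scale for this class of rig (a raw depth frame has
~217k pixels, of which the animal fills a fraction). Noise interacts with
the hull girth in both directions — extreme outward points inflate the hull,
chord shortfall deflates the polygon — and at this density the net effect is
a ~2.5% upward girth bias at 5 mm noise, which is what keeps the pooled
90th-percentile error near, but below, the 3% system envelope. What the
generator does **not** emulate: articulated posture, depth-sensor noise
anisotropy (axial vs lateral), occlusion by rig structures, and non-convex
brisket/abdomen profiles; passing tests therefore demonstrate correctness
of the geometry pipeline, not field accuracy on real cattle.

## The genotype and phenotype model

Genotypes are counts of the A1 (minor) allele. Clean SNPs are
`Binomial(2, p)` with `p ~ U(maf_low, maf_high)` (defaults 0.1–0.5, a
common-variant panel after array ascertainment); missingness is independent
per call (default 1%). Optional structure draws subpopulation frequencies
from a Balding–Nichols Beta around `p` with the configured F. Planted
violations are deterministic enough to be recovered exactly by tests: HWE
violators draw each call heterozygous with probability 0.9 (the exact test
rejects far beyond the 1e-6 screen at n ≈ 96); heterozygosity-outlier
samples likewise; low-call-rate samples/SNPs blank exactly 15% of calls;
rare SNPs carry exactly one heterozygous call. SNPs are spread round-robin
over the 29 autosomes with sorted positions.

Phenotypes follow the additive model `y_i = mu + sum_j beta_j g_ij + e_i`
with `e ~ N(0, sigma_e^2)`; missing genotypes contribute their SNP's mean
dosage (generator convention — the association test instead *drops* missing
calls per SNP, the standard testing convention; the asymmetry is
deliberate). Given a trait mean and CV, `sigma_e^2` is the implied total
variance minus the variance explained by the planted effects, floored at
zero, and the genetic part is mean-centered so the configured mean stays the
trait mean. The default herd calibration (means 614.9 kg, 143.1 cm,
146.4 cm, 52.2 cm, 217.1 cm, 60.4%; CVs 5.4–2.1%) describes a finished
Aberdeen-Angus pen; between-trait correlation beyond shared planted QTLs is
not modeled, a known simplification of real conformation data where stature
traits correlate strongly.

## QC and the scan

Filter order is fixed and reported step by step, so any reordering is
visible in the counts: (1) sample call rate ≥ 0.9, (2) SNP call rate ≥ 0.9,
(3) MAF ≥ 0.05, (4) exact Hardy–Weinberg p ≥ 1e-6, (5) heterozygosity
outliers beyond 3 population SDs. Call-rate comparisons are inclusive ("not
lower than"). The Hardy–Weinberg test is the plain exact conditional test
(Levene–Haldane distribution of the heterozygote count given allele counts,
p = total probability of configurations no more probable than the observed
one, no mid-p) — at a 1e-6 screen with n ≈ 96 the chi-square approximation
is untrustworthy in exactly the tail that matters. MAF classes follow the
left-closed conventions monomorphic / rare (0, 0.05) / intermediate
[0.05, 0.1) / common [0.1, 0.5]. PCA standardizes columns to unit
Hardy–Weinberg variance (`(g - 2p) / sqrt(2p(1-p))`, missing imputed at the
column mean) and reports eigenvalues on the variance scale (scores'
crossproduct = eigenvalues × (n−1)).

The scan is, per SNP, OLS of the trait on `[1, covariates, dosage]` with
two-sided t p-values; monomorphic-in-tested-set SNPs return `NA` with a
reason code rather than vanishing. The genome-wide threshold is Bonferroni
`alpha / m` with `m` the post-QC SNP count and a strict `<` comparison. No
genomic-control rescaling is applied (the informational lambda is reported
by `summary()`); no mixed-model/GRM correction, FDR alternative, or LD
pruning is provided. Whether other traits or PC scores enter as covariates
is left to the caller (`covariates=`, `pca_scores=`): the underlying model
statement is ambiguous on this point, so both modes exist and the default is
covariate-free. QQ expectations use `-log10((i - 0.5)/m)`; Manhattan
coordinates lay chromosomes end to end by their maximum observed position.

## Reproducibility and problem sizes

Every generator takes an explicit integer seed and is bit-deterministic
given it; the pipeline derives stage seeds from one root seed by fixed
offsets, so stages can be re-run standalone. The test suite and the
acceptance script run at desk scale by design: panels of 96 × 1,200–5,000
SNPs (the QC and scan code is dimension-agnostic; a 141k-SNP array panel is
simply more columns), herds of 96–200 animals, clouds of 3 × 20,000 points
for accuracy claims and lighter densities inside the pipeline demo. The
measurement-error claim is scored as the 90th percentile of pooled relative
errors over all four measurements of 200 noisy animals against the 3%
envelope; the herd-calibration claim as the 96-head mean chest girth against
217.1 cm within 3 standard errors.

## Known limitations

* The landmark detector is a heuristic; its chest-width estimate is
  noise-biased (documented above) and it assumes a roughly level, X-aligned
  animal.
* The convex-hull girth cannot exceed-measure concavities and slightly
  over-measures under sensor noise; both biases are inherent to the stated
  algorithm, not implementation artifacts.
* The QC chain is single-pass in a fixed order; the 3-SD heterozygosity rule
  is not re-applied after removals, so a pathological mixture could pass a
  second screen differently (the report makes this auditable).
* No kinship correction: planted-QTL power statements hold under the
  simulated unrelated-sample model, not under family structure.
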