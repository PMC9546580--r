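---
title: "Mapping root gravitropism QTL and filtering candidates by orthology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping root gravitropism QTL and filtering candidates by orthology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

When a seedling is rotated by 90°, its primary root bends back toward the
gravity vector.  Tracking the root tip angle every few minutes turns this
response into a function-valued phenotype: a sigmoid rise from 0° toward
90° (vertical), sometimes overshooting before settling.  In a recombinant
inbred line (RIL) population, the line-to-line variation of these curves
can be mapped to quantitative trait loci (QTL), either time point by time
point (tQTL) or through parameters of a fitted response curve (pQTL).
Because QTL intervals are broad — often hundreds of gene models — a
cross-species filter helps: if the same process was mapped in a second,
distantly related species, one-to-one orthologs that fall inside QTL
intervals of *both* species are strong candidates.  `graviqtl`
implements this entire chain, along with a synthetic-data module that
generates every input with recorded ground truth, so each stage can be
verified without external downloads.

# Response model

Tip-angle time courses are summarized by two sigmoids, written in the
lag/slope/asymptote parameterization used by growth-curve fitting
packages:

* logistic: `y(t) = A / (1 + exp(4 mu (lambda - t)/A + 2))`
* Gompertz: `y(t) = A exp(-exp(mu e (lambda - t)/A + 1))`

with `A` the final (steady-state) angle in degrees, `mu` the maximal
slope in degrees per minute, and `lambda` the lag time in minutes.  Both
forms satisfy the defining identities (the logistic passes `A/2` with
slope `mu` at `t = lambda + A/(2 mu)`; the Gompertz attains slope `mu`
at `y = A/e`), which the unit tests verify by calculus rather than by
reference values.

Each line's mean curve is fitted with both models by
Levenberg–Marquardt least squares (`minpack.lm`), initialized from the
data maximum, the maximal central-difference slope, and the implied lag;
up to five jittered restarts recover from failed starts.  The lower-AIC
model is selected; since both models have the same number of parameters
this equals the lower-RSS rule, and exact ties go to the logistic.
Growth-curve practice fits both models without a standard combination
rule, so the selection rule is this package's choice; on simulated data
the generating model is selected essentially always, and the parameters
of either model have the same interpretation.

Six mappable parameters come out of each fit: `lambda`, `mu`, `A`, the
spline peak `P` (cubic smoothing spline, GCV-chosen smoothing, maximum
on a 0.1-min grid), the overshoot `P - A` (left unclipped — slightly
negative values are informative noise around zero for monotone
responses; a clip option exists), and the integral `I` of the selected
sigmoid over the observation window (composite trapezoid on a 0.1-min
grid).  The integration window is each dataset's own observation
window: 0–180 min for the 3-min maize protocol, configurable to the
2-min × 8-h Arabidopsis assay.

# QTL machinery

Genotype probabilities for the two homozygous RIL states are computed by
a forward–backward hidden Markov model on each chromosome, with
transitions given by the Haldane map function of the inter-position
distance and a symmetric genotyping-error emission (default 0.002).
Pseudomarkers are inserted on a regular grid (default 1 cM).  The
population is treated as fully inbred — two states, no residual
heterozygosity — and the map distances are taken at face value, which is
how an intermated (expansion-adjusted) RIL map is consumed.

Scans use Haley–Knott regression of the phenotype on the expected
dosage `P(BB) - P(AA)`, with `LOD = (n/2) log10(RSS0/RSS1)`.  This was
chosen over multiple imputation as the default engine because it is
deterministic, so every result is bit-reproducible under a fixed seed;
at the effect sizes and marker densities simulated here the two give
practically identical profiles.  Genome-wide significance comes from
permutation: the phenotype is shuffled, the genome-wide maximum LOD
recorded, and the empirical `1 - alpha` quantile (type-7 interpolation)
taken as the threshold.  Thresholds are calibrated — at `alpha = 0.05`
the measured genome-wide false-positive rate over 1,000 fresh null
phenotypes is 0.05 within sampling error (the acceptance script
recomputes this).

Multiple-QTL models are built by penalized-LOD stepwise search: forward
addition of the position that maximizes the additive model LOD, with
coordinate-wise refinement of all positions after each addition, up to
`max_qtl`; then backward elimination; the visited model maximizing
`pLOD = LOD - k * penalty` wins, with the empty model (pLOD 0) allowed.
The penalty defaults to the permutation threshold.  Models are additive
only — gravitropism QTL in these populations are reported as additive
loci, and epistatic penalties are out of scope here.  Ties in the forward search are
broken toward the lowest (chromosome, position).  A numerical floor at
`RSS0 * 1e-10` guards the exact-fit limit so that, once a model explains
a noiseless trait to machine precision, further additions cannot gain
LOD from floating-point noise.  Support intervals use a 1.5-LOD drop
from the per-QTL conditional profile, expanded by one evaluated position
on each side; a zero drop degenerates to the peak grid point by
definition.

For tQTL mapping, each time point is an independent trait with its own
permutation threshold and stepwise model; `t = 0` is identically zero
after initial-angle subtraction and is excluded.  No correction is
applied across the ~60 time-point traits, matching per-trait genome-wide
control.  Significant models are linked over time into tracks: a track
is a maximal run of consecutive time points whose peaks stay on one
chromosome within `link_dist_cM` (default 10 cM) of the previous frame;
its duration is the run length times the frame interval.  A track
matches a pQTL when both sit on the same chromosome within
`match_dist_cM` (default 10 cM).  Both distances are configuration
knobs because no standard co-location rule exists; 10 cM is roughly
half a support-interval width at the simulated densities.

# Image phenotyping

The package replaces a machine-learning tip detector with a classical
pipeline: Otsu threshold, a 3-px morphological opening (to detach
speckle noise), largest connected component, Zhang–Suen skeletonization,
and a geodesic walk from the seed-side skeleton endpoint (assumed at the
top of the frame, configurable by rotating the input) to the farthest
endpoint, the tip.  Two details matter numerically:

* thinning erodes diagonal line ends by roughly the root width, so the
  path is extended through the mask, depth-limited and guided by the
  skeleton's final direction, to the true tip;
* raw path pixels jog in whole-pixel steps, so tail points are snapped
  to iterated local mask centroids (subpixel), deduplicated where the
  iteration collapses them at the tip cap, and the tangent comes from a
  quadratic in arc length.  A long-window quadratic first classifies
  the tip: straight tips (tangent turning < 4° over ~7 root-widths) use
  a long line fit, because a slow lateral drift collapses into a single
  rasterization step that a short window misreads; curved tips use a
  locally weighted quadratic differentiated at the tip.

On zero-noise synthetic stacks this keeps the worst frame within 3° of
the drawn terminal tangent across a 61-frame trajectory, verified
against generator truth.  Angles are signed, measured from the image
horizontal with 90° = straight down; assay conventions differ on signed
versus folded-to-[0, 90] angles, so signed angles are produced and
folding is left to the caller.

Genotype-group comparisons use one-way ANOVA with Tukey HSD letter
groupings at `alpha = 0.1` (or an equal-variance t test for two
groups), independently at each requested time point.  Letters are the
maximal cliques of the not-significantly-different graph, ordered by
group mean.  When all groups have zero within-group variance the
exact-tie convention applies: p = 1 for equal means, else 0.

# Orthology filter

QTL intervals live on the genetic map; genes on physical coordinates.
Interval endpoints are converted by linear interpolation between marker
anchors (clamped, with a flag, outside the anchored span), and genes
overlap an interval by at least 1 bp, strand-agnostic.  Candidate genes
from each species' intervals are then searched against the *full*
proteome of the other species — candidate sets first, reciprocal search
against full proteomes second, so reciprocity is judged genome-wide
rather than within the candidate sets.
Alignment is Smith–Waterman local alignment with BLOSUM62 and affine
gap costs 11/1 (blastp defaults), through `Biostrings`; an exhaustive
dynamic-programming oracle cross-checks the scores in the tests.  A
pair is kept when each member is the other's highest-scoring hit (ties
broken by percent identity, then lexicographic subject id), the partner
lies in an interval of its species, and both scores reach a minimum raw
score of 50 — there is no E-value machinery, mirroring plain
default-parameter blastp ranking; the floor only guards against junk
hits and can be set to 0.  Percent identity counts identities over all alignment
columns including gaps, the convention of the common blastp report.
One representative protein per gene is used — the longest annotated
isoform, a common default where no isoform policy is given.

# The synthetic-data module

The generator is the package's measurement standard, so its defaults
are the study conditions rather than tunables:

* genotypes: two-state RIL chains under Haldane recombination on the
  given map, symmetric start, optional call-error and missingness;
* phenotypes: per-line curve parameters
  `theta = baseline + sum(effect_j x_j) + N(0, line_sd^2)` with ±1/2
  genotype coding (an "effect" is therefore the between-homozygote
  difference in parameter units), trajectory = sigmoid plus an optional
  Gaussian overshoot bump centered at `lambda + A/mu` with SD
  `A/(2 mu)` (a documented free choice — the bump places overshoot just
  after the rise and widens with slower responses), plus per-time-point
  `N(0, obs_sd^2)`.  The baseline (`A` 60°, `mu` 0.7°/min, `lambda` 20
  min, logistic) is typical of maize seedling responses; `obs_sd`
  defaults to 3°, chosen to give per-line SEM bands of the magnitude
  seen in such assays, and between-line SDs (`lambda` 3 min, `mu`
  0.07°/min, `A` 6°) put roughly 10% coefficient of variation on each
  parameter.  These are the package's own realism choices, not
  measured values — no noise model for tip angles is established;
* proteomes: random protein pairs mutated at a per-site ortholog
  divergence (default 0.1), within-species paralog decoys at a strictly
  higher divergence, a gene block kept adjacent in both species so that
  the first interval of each species is guaranteed to contain ortholog
  pairs, and optional designed reciprocity failures (a decoy built from
  the other species' sequence at half the ortholog divergence);
* images: a constant-arc-length root whose tangent turns linearly from
  the seed to the stored tip angle, a seed blob, and additive Gaussian
  noise.

Everything is seeded and bit-reproducible, and every dataset ships its
ground truth.

What the generator does **not** emulate bounds what green tests mean for
real data: real tip-angle kinetics are not exactly sigmoid-plus-bump;
real images have illumination gradients, touching roots and agar
artifacts that the classical segmentation would mis-handle; real
proteomes have gene families, not independent random sequences, so real
BBH error rates are higher than the simulated ones; and the RIL model
has no segregation distortion or residual heterozygosity.  The tests
demonstrate correctness of the machinery under its stated model, not
field performance.

# Problem sizes and runtime choices

The test and acceptance runs use desk-scale versions of the study
conditions: populations of 200–250 lines on ten 100-cM chromosomes,
1,000-permutation thresholds for the calibration check and 120–200
permutations inside replicated recovery runs, 20 replicates for the
recovery-rate estimate, and 200-gene proteome pairs for the orthology
check.  These sizes keep the full suite around a minute while leaving
every statistical conclusion comfortably clear of its acceptance bound;
the same code paths run unchanged at publication scale (thousands of
permutations, full proteomes) — only the constants in the configuration
change.

# Known limitations

* Stepwise search is additive-only; no epistasis, covariates, or
  X-chromosome handling.
* The per-QTL heatmap attribution uses conditional LOD profiles, which
  can differ slightly from a joint multi-QTL attribution when QTL are
  closely linked.
* The image pipeline assumes one root per frame (largest component) and
  a seed at the top edge.
* `cm_to_bp` interpolation is linear between anchors; strong local
  recombination-rate variation between anchors is not modeled.
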