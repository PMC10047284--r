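---
title: "Models and methods behind chromatether"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind chromatether}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(chromatether)
```

chromatether quantifies how loss of nuclear-envelope tethering (disruption
of the LINC complex) changes chromatin repression in *Drosophila* larval
muscle. It combines four analysis arms that normally live in separate
toolchains — a coarse-grained polymer simulation, Targeted-DamID
differential-occupancy statistics, 3D nuclear image quantification with a
hierarchical mixed model, and seeded synthetic-data generators that make
every stage testable with known ground truth. This vignette explains the
models, their assumptions, the tunable parameters, and the design choices
made where the design was genuinely open.

## 1. The coarse-grained genome

One bead represents `bp_per_bead` = 5 kb of chromatin and has diameter
sigma = 30 nm; the 176.2 Mb genome therefore maps to 35,240 beads, split
into four chromosome chains. Each chain carries a single contiguous
pericentromeric-heterochromatin (PCH) block holding its share of the
genome-wide 30% PCH fraction; the block sits at the chain midpoint by
default (`pch_position = "center"`) because centromere placement within
the model chain is not otherwise constrained, and a chain-end variant is
provided.

H3K27me3 is laid down as random patches whose lengths follow a discretised
exponential distribution with mean 17 beads (a continuous draw, rounded,
floored at one bead — the discretisation preserves the mean
asymptotically). Patches are placed by rejection Monte Carlo: a candidate
is rejected if it would overlap an existing patch or cross a chromosome
boundary (patches are intra-chromosomal features). On rejection only the
*position* is redrawn, not the length; redrawing both would bias the
accepted lengths several beads short of the stated mean, because long
patches are rejected more often. Placement stops when flagged coverage
first reaches the 40% target, so the final coverage overshoots by less
than one patch length; over 50 full-genome seeds the mean accepted patch
length is 17.0 +/- 0.1 beads and coverage lies in [0.400, 0.402).

Two coverage modes exist. The default targets 40% of the genome uniformly.
The alternative (`coverage_mode = "per_compartment"`) targets 22% of
euchromatin and 77.5% of PCH separately (the midpoint of the 75–80% range
reported for pericentromeric H3K27me3); these compose to about 38.7%,
slightly below the global target, which is why the modes are kept
distinct rather than reconciled.

## 2. The tethering simulation

Chromosomes are bead-spring chains confined to a sphere whose radius gives
a 15% bead volume fraction, `R = (N / (8 phi))^(1/3)` in sigma units. A
fixed shell of lamina beads (one per sigma^2 of surface, Fibonacci
lattice) lines the confinement. Interactions:

* backbone harmonic springs, k = 100 kBT/sigma^2, rest length sigma
  (stiffness is a modelling choice; the chain only needs to stay intact);
* truncated, energy-shifted Lennard-Jones attraction between beads within
  2.5 sigma — eps_EE = 0.35 kBT between euchromatin beads, eps_HH =
  0.5 kBT among heterochromatin (PCH and H3K27me3 alike), and eps_cross =
  0.3 kBT for mixed contacts. The cross term is not independently
  constrained; it is set at the chain-collapse threshold so that
  self-attraction always dominates, which is what lets the two chromatin
  types phase-separate, and it is exposed in `sim_config()`;
* dynamic harmonic bonds between H3K27me3 beads and lamina beads: a bond
  forms when an unbonded H3K27me3 bead comes within 1.5 sigma of a lamina
  bead (to the nearest one; each chromatin bead holds at most one bond,
  lamina beads may host several), is a spring with constant K and rest
  length sigma while it lives, and breaks when stretched past 2.5 sigma.
  K = 10 is the strong-tethering regime, K = 1.5 the weak one;
* purely repulsive (WCA) sterics from lamina beads and from the smooth
  confining wall, plus a radial reflection that guarantees |r| <= R.

Dynamics are overdamped Langevin: `dr = (F/gamma) dt + sqrt(2 kBT dt /
gamma) eta`, with dt = 0.01 tau, gamma = 1, kBT = 1. Overdamped (rather
than underdamped with a thermostat) is the simplest scheme with the right
equilibrium statistics, and equilibrium structure is all the cluster and
radial-density analyses consume. Numerical guards: the net force per bead
is capped (default 50 kBT/sigma) so that transient core overlaps during
equilibration cannot blow up the integrator, and the wall contribution is
evaluated at a floor distance of 0.05 sigma. The bond registry is
refreshed every 10 steps (`registry_stride`); the formation/rupture rules
are distance thresholds, so the refresh period only has to be short
against the time a bead needs to travel ~1 sigma (about 170 steps at
these parameters). Initial configurations are confined random walks
relaxed for 500 zero-temperature capped-force steps to remove overlaps.
Everything is reproducible from a single integer seed; the integrator
uses its own xoshiro256++ stream seeded from R's RNG.

### Cluster and radial analyses

H3K27me3 clusters are connected components of the contact graph with
contact distance 1.5 sigma (first-neighbour shell; 2.5 sigma, the
interaction range, is available as an alternative). "In the nucleoplasm"
has two implementations: drop clusters containing any currently
lamina-bonded bead (`method = "unbonded"`), or keep clusters whose centre
of mass lies deeper than 2 sigma below the surface
(`method = "interior"`). At full genome size the two agree in spirit; at
the reduced sizes used for testing the unbonded rule degenerates —
in a small sphere nearly every large aggregate touches at least one
bonded bead, so the rule discards exactly the clusters that carry the
tethering effect — and the centre-of-mass rule is the robust choice.
Radial profiles count beads in ten equal-thickness shells and normalise
by the whole-sphere mean density, so the volume-weighted profile mean is
exactly 1.

The headline behaviour — weak tethering (K = 1.5) yields larger
nucleoplasmic H3K27me3 clusters and a lower outermost-shell H3K27me3
density than strong tethering (K = 10) — is exercised in the test suite
at N = 600 beads, 6 x 10^4 steps and 10 matched seeds per K (seed-paired
signed-rank comparison) with the interior
cluster rule, sizes chosen so the whole comparison runs in a few minutes
on one CPU. In pilots the direction was consistent in every seed at
N = 600–800; production-scale runs (35,240 beads) are supported but not
run by the tests.

## 3. DamID differential-occupancy statistics

Input is a per-gene table of replicate log2(Dam-fusion / Dam-only)
occupancies for control and mutant, a per-sample FDR for confident
occupancy, and the gene's GATC-site count. Genes pass the filter when
FDR < 0.05 (strict) and GATC sites > 1 (strict).

Hit calling treats each gene as a 2D point (mean control occupancy, mean
mutant occupancy). The first principal axis of the centred cloud is the
regression line; each gene's signed projection on the second axis,
divided by the projection standard deviation, is its `z_pca`. The sign is
oriented so mutant-enriched genes score positive. Significance requires
|z| > 1.96 (two-tailed, approximately a 95% band) together with the FDR
and GATC criteria. Residuals are standardised with the plain standard
deviation on mean-per-condition points; a robust scale estimator was
considered and rejected to keep the null calibration exact (on synthetic
null tables the flagged fraction is 5.0–5.1%).

Group overlaps are reported as percentages with the union (Jaccard)
denominator by default, with a smaller-set denominator as an option,
since the original overlap denominators are not stated. Fold-change
clustering uses k-means (10 restarts) with the number of clusters chosen
by the Gap statistic against a uniform-box reference (B = 50, the
Tibshirani one-standard-error rule, k up to 6); missing fold changes
impute to 0 ("no evidence of change"), and all-missing genes drop with a
warning.

The gene-proximity Monte-Carlo test asks whether a hit set clusters along
the chromosomes: the observed statistic counts hit genes whose nearest
other hit on the same chromosome lies within 10 kb, with gene–gene
distance defined as the interval gap `max(0, later.start - earlier.end)`
(midpoint distance is available; which definition the original analysis
used is not stated, and the gap is the conservative reading of "distance
between genes"). The null redraws equally many genes uniformly without
replacement from the annotation restricted to chr2L/2R/3L/3R, 1000 times,
and `p = (NGE + 1) / (Nruns + 1)`. For non-overlapping annotations the
nearest neighbour in gap distance is adjacent in start order, giving an
O(n log n) path; overlapping annotations fall back to interval-tree
distances, and the two routes are cross-checked in the tests.

## 4. Image quantification and the mixed model

Nucleus segmentation follows denoise → threshold → label: Gaussian
smoothing at sigma = 1 voxel (the denoising strength before thresholding
is a free choice), a global Otsu threshold on the DNA channel, 3D
26-connected components, then removal of components touching the stack
border or smaller than 20 µm^3 (a debris guard; muscle nuclei are far
larger). All intensity statistics are computed strictly over mask voxels,
which is what removes cytoplasmic background from nuclear means.

Puncta segmentation subtracts each nucleus' own background (the
within-mask median; a histogram-mode estimator is the alternative), clips
at zero, Otsu-thresholds the residual over mask voxels only, labels 3D
components and drops any below 0.01 µm^3. One guard is added beyond the
textbook recipe: the residual threshold must exceed three within-mask
MADs, otherwise the nucleus is treated as punctum-free. Without it, a
nucleus with no real puncta gets its unimodal noise floor split by Otsu
and a giant spurious "punctum" appears; with it, punctum-free nuclei are
correctly empty.

Radial chromatin profiles build shells from the anisotropic-aware
Euclidean distance of each mask voxel to the mask boundary (distances in
µm, not voxels), cut into ten equal-depth bins from periphery to centre,
and divide each shell's mean intensity by the mean of a cytoplasmic
reference — by default a 2-voxel-thick ring offset 3 voxels outside the
nucleus, excluding other nuclei, since the reference region is otherwise
unspecified.

Group comparisons use a linear mixed model with genotype as the fixed
effect and random intercepts for larva and muscle-within-larva (lmerTest,
Satterthwaite df). Strictly positive measures are fitted on the natural
log scale, so the genotype coefficient back-transforms to a percent
change of group means — the scale on which the biology is reported and on
which the synthetic generator's multiplicative effects live; measures
with non-positive values fall back to an identity-scale fit with the
effect expressed as percent of the control mean. A singular full fit
falls back to a larva-only random intercept and is flagged in the result.
Optional log10(volume) covariate and genotype x volume interaction
support intensity-versus-volume fits.

## 5. The synthetic generators, and what they do not show

`gen_damid_table()` draws per-gene baselines N(0,1) in log2 space,
replicate noise N(0, 0.2), and shifts true hits by 1.5 log2 units in the
mutant. The per-sample FDR column models *occupancy confidence*, not
differential evidence: non-hit genes draw FDR uniformly below 0.25
(per-gene tables are dominated by confidently detected genes), true hits
are always confidently detected. Hits can be placed uniformly or in tight
blocks within 10 kb to give the proximity test a true positive.
`gen_annotation()` places fixed-length, non-overlapping genes by the
uniform-spacings construction on chromosome arms with dm6-like lengths.

`gen_nuclei_cohort()` renders one ellipsoidal nucleus per stack with a
dim cytoplasmic surround, hierarchical mark intensity (grand mean x
genotype factor x log-normal larva, muscle and nucleus factors), optional
bright spherical puncta (placed non-overlapping — real repressive puncta
are distinct objects, and overlapping render-spheres would merge under
segmentation and bias volume ratios upward), an optional peripheral DNA
rim, Gaussian read noise and optional Poisson shot noise. Default
variance components are larva_sd = muscle_sd = 0.05 and nucleus_sd = 0.12
(log scale): batch-level variation is modest for normalised acquisition
while nucleus-to-nucleus variation dominates, matching the per-nucleus
scatter such experiments show. With 5 larvae x 3 muscles x 10 nuclei per
genotype these components put the between-larva standard error near 4% on
the log scale, which is what makes a +/-25%-relative recovery band
attainable in ~95% of seeds — cohort designs with much larger larva-level
variation cannot meet that band no matter how good the pipeline is,
because the estimand itself moves between seeds.

Recovery sweeps (`recover_intensity_effect()`, `recover_puncta_effect()`)
regenerate a cohort per seed, push it through segmentation,
quantification and the mixed model, and compare the estimate with the
injected effect. In pilots the estimate matches the *realised* latent
contrast to ~0.2 percentage points, i.e. the pipeline is essentially
unbiased and the remaining seed-to-seed spread is the generator's own
sampling noise. Intensity stacks default to 0.3 x 0.3 x 0.5 µm voxels;
puncta cohorts use 0.1 µm isotropic voxels so that 0.08–0.2 µm^3 puncta
span enough voxels for stable volumes.

What passing these tests does **not** show about real data: the generator
has no point-spread-function anisotropy beyond voxel anisotropy, no
chromatic offsets, no intensity gradients with depth, no segmentation
ambiguity from touching nuclei, and its puncta are hard spheres. Real
cohorts can also have larger batch effects than the defaults; the mixed
model handles those, but single-cohort effect estimates then carry
proportionally wider uncertainty.

## 6. Problem sizes used by the checks

Chosen as the package's own testing scale: patch statistics at the full
35,240-bead genome over 50 seeds; the tether comparison at 600 beads,
6 x 10^4 steps, 10 matched seeds per K; hit-caller calibration on 10,000 null
genes; proximity nulls at Nruns = 1000; intensity-effect recovery at the
full cohort design (300 nuclei) over 30 seeds per mark in the tests and
50 seeds in `scripts/acceptance.R`; puncta recovery over 30 nuclei per
seed. The deposited per-gene DamID tables are not shipped; the
deposited-data benchmark runs only if those TSVs are placed under
`inst/extdata/deposit/`.

## 7. Known limitations

* The simulation is a minimal equilibrium model: no hydrodynamics, no
  chromosome territories or Rabl orientation, no loop extrusion; the
  timestep is coarse (spring relaxation per step is order one), which
  inflates bond-length fluctuations by ~40% but leaves the
  bonded/unbonded balance and phase behaviour intact.
* The Euler–Maruyama + reflection boundary samples the confined ideal gas
  exactly uniformly (tested), but steep-potential regions carry the usual
  first-order discretisation bias.
* The PCA z-score inherits the usual caveat of regression-based hit
  calling: a large fraction of true hits tilts the principal axis and
  shrinks their apparent residuals. At realistic hit fractions (a few
  percent of detected genes) the effect is negligible; the synthetic
  cohorts keep that regime.
* `radial_distribution()` assumes a roughly convex nucleus; strongly
  lobed nuclei would mix depths across lobes.
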