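# chromatether

Tools for asking how chromatin repression changes when the nucleus loses
its mechanical coupling to the cytoskeleton. In *Drosophila* larval
muscle, disrupting the LINC complex (the SUN–KASH bridge across the
nuclear envelope) increases repressive chromatin: Polycomb binding goes
up, H3K27me3 and H3K9me3 intensities rise, H3K9ac falls, repressive
H3K27me3 puncta grow, and chromatin shifts from the nuclear periphery
toward the centre. chromatether re-implements the computational side of
that analysis as one tested, tidyverse-style R package for genomicists
and quantitative cell biologists who want to run, probe or extend these
analyses:

* **Coarse-grained tethering simulation** — the genome as bead-spring
  chains (1 bead = 5 kb = 30 nm), 70% euchromatin / 30% pericentromeric
  heterochromatin, H3K27me3 laid down as exponential patches (mean 17
  beads, 40% coverage), confined to a sphere at 15% volume fraction and
  lined with lamina beads. Heterochromatin self-attracts more strongly
  than euchromatin (eps_HH = 0.5 kBT vs eps_EE = 0.35 kBT, truncated LJ
  within 2.5 sigma), and H3K27me3 beads form dynamic harmonic bonds
  (spring constant K, formation < 1.5 sigma, rupture > 2.5 sigma) to the
  lamina. Overdamped Langevin dynamics; compiled core; cluster-size and
  radial-density analyses compare the strong (K = 10) and weak (K = 1.5)
  tethering regimes.
* **Targeted DamID statistics** — per-gene log2(Dam-fusion/Dam) tables
  filtered at FDR < 0.05 and GATC sites > 1; PCA-regression hit calling
  (z = standardised perpendicular residual, |z| > 1.96 two-tailed);
  group overlaps; k-means/Gap-statistic fold-change clustering; and a
  Monte-Carlo gene-proximity test with p = (NGE + 1)/(Nruns + 1).
* **3D nuclear image quantification** — Otsu segmentation of DNA-channel
  stacks, mask-restricted intensity and volume measures, bright-puncta
  segmentation with the 0.01 µm³ volume filter, periphery-to-centre
  radial shells, and genotype comparison with a linear mixed model
  (genotype fixed; larva and muscle-within-larva random).
* **Synthetic-data generators** — seeded, ground-truthed generators for
  every input (occupancy tables, BED annotations, two-channel nucleus
  stacks with hierarchical effects and puncta), so the whole pipeline is
  testable end to end without downloads.

## A worked example

Simulate a reduced genome under strong and weak lamina tethering and
compare nucleoplasmic H3K27me3 cluster sizes:

```r
library(chromatether)

spec  <- genome_spec()                        # 5 kb/bead, 4 chromosomes
beads <- partition_genome(spec, n_beads = 600) |>
  generate_h3k27me3_patches(spec, seed = 99)

strong <- lapply(1:3, function(s)
  run_simulation(beads, sim_config(lamina_bond_K = 10),
                 steps = 60000, stride = 5000, seed = s))
weak <- lapply(1:3, function(s)
  run_simulation(beads, sim_config(lamina_bond_K = 1.5),
                 steps = 60000, stride = 5000, seed = s))

compare_tether_strengths(strong, weak, method = "interior")
#> <tether_comparison> mean cluster size A = 25.37, B = 27.97; B larger
#>   (one-sided Mann-Whitney p = 0.211)
```

Weak tethering (K = 1.5, side B) produces larger nucleoplasmic H3K27me3
clusters than strong tethering — released from the lamina, the marked
beads coalesce in the interior. Three seeds per side show the direction
but cannot reach significance in a rank test; the test suite runs ten
matched seeds per side and tests the seed-paired differences, where the
separation is decisive (one-sided p < 0.05).

Call differential-occupancy hits on a synthetic DamID cohort with 50
true mutant-enriched genes:

```r
d <- gen_damid_table(synth_damid_spec(), seed = 1)
hits <- d$table |> filter_genes() |> pca_regression_hits()
dplyr::count(hits, significant, direction)
#> # A tibble: 3 × 3
#>   significant direction     n
#>   <lgl>       <chr>     <int>
#> 1 FALSE       decreased   619
#> 2 FALSE       increased   340
#> 3 TRUE        increased    50
```

All 50 flagged genes are the 50 planted hits (`d$truth`), and on null
tables the caller flags ~5% of genes, matching its 95% confidence band.
Recover an injected +43% H3K27me3 intensity effect through the full
image pipeline:

```r
spec <- synth_nuclei_spec(genotype_effect = 43)
cohort <- gen_nuclei_cohort(spec, seed = 1)
q <- quantify_cohort(cohort)
compare_groups(q, "mean_mark_intensity")
#> <group_comparison> mean_mark_intensity: mutant vs control = +43.0% (p = 8.56e-08)
```

`tidy()`, `glance()` and `autoplot()` methods are available on the fitted
comparison, hit tables, radial profiles and trajectories.

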