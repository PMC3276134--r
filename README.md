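# senescreen

Quantitative analysis of genome-wide, serially passaged **telomere-initiated
senescence screens** in budding yeast — and a seeded stochastic simulator of
such screens, so the whole pipeline runs and validates itself with no
external data.

## The problem

Telomerase-null yeast (e.g. *est1*Δ) senesce as telomeres shorten, and rare
recombination-dependent *survivors* let some cultures recover. A
genome-wide modifier screen crosses every viable gene deletion into the
telomerase-null background and follows thousands of replicate cultures
through serial passages (dilution → regrowth → photograph). Image analysis
turns each culture into a *size* per passage; everything downstream of that
table is this package:

1. **Variance stabilisation** — Box–Cox power transform, g(x) = x^0.6
   (`transform_sizes()`); healthy cultures land near 4000 units.
2. **Mean density profiles (MDPs)** — per genotype, the mean ± sd of its
   replicate culture sizes at each passage (`compute_mdp()`).
3. **Profile statistics** — Pearson correlation *r* between MDPs
   (shape similarity, affine-invariant), RMS difference (absolute
   dissimilarity), and MDP area Σₚ mean[p] (total fitness)
   (`pearson_correlation()`, `rms_difference()`, `mdp_area()`).
4. **Three-archetype classification** (`assign_classes()`), non-exclusive:
   - *normal* senescence: r > 0.85 to the his3Δ-like archetype;
   - *no recovery* (rad52Δ-like): r > 0.5 **and** mean passage-2 size below
     the screen-wide cutoff C^s = C^ave − 0.5·C^SD computed from all
     individual cultures at passage 2 (`compute_passage2_filter()`);
   - *fast recovery* (rif1Δ-like): the top-20 genotypes by r to the
     fast-recovery archetype (rank-based; a strict cutoff keeps almost no
     members).
5. **Recovered fractions** — the share of a genotype's replicate cultures
   at ≥ 1000 units by passage 19 (`recovered_fraction()`,
   `class_recovery_summary()`).
6. **QT clustering** — unsupervised quality-threshold clustering of MDPs:
   repeatedly extract the largest candidate cluster whose diameter stays
   under a threshold (`qt_cluster()`), no cluster count chosen in advance.
7. **Screen designs & I/O** — liquid 96-well (60 queries + 36 outer-frame
   controls × 16 plates = 576 control cultures) and solid 1536-position
   layouts (8/56/144 replicate schemes), plain-text culture tables with
   bit-exact round trips, validation reports, gene-set Venn overlaps,
   genetic-interaction quadrant summaries, and a one-call pipeline driver
   (`run_pipeline()`) that writes all tables plus a JSON run manifest.
8. **Simulator** (`simulate_screen()`, `preset_classes()`) — decline to a
   fitness nadir, stochastic survivor emergence (class recovery
   probabilities 0.50 / 0.81 / 0.29), permanent sterility, design-dependent
   dilution (1:70 liquid vs 16-fold solid → slower senescence on solid),
   multiplicative lognormal noise; bit-reproducible via per-culture RNG
   substreams keyed by (seed, plate, row, column).

## Worked example

Simulate a small solid-design screen (12 genotypes — three archetypes plus
three query genotypes behaving like each — 8 replicate cultures each),
transform, classify:

```r
library(senescreen)

sim     <- simulate_benchmark_screen(seed = 1, genotypes_per_class = 4,
                                     replicates = 8, control_replicates = 8)
dataset <- transform_sizes(sim$dataset)
#> screen_dataset: 96 cultures x 22 passages (solid design, transformed scale), 12 genotypes

mdps <- compute_mdps(dataset)
asg  <- assign_classes(mdps, dataset, archetype_config(fast_recovery_top_k = 4))
asg[, c("genotype", "r_normal", "r_no_recovery", "r_fast_recovery",
        "passes_p2_filter", "memberships", "recovered_fraction")]
#>  genotype r_normal r_no_recovery r_fast_recovery passes_p2_filter   memberships recovered_fraction
#>    fast02    0.435         0.251           0.977            FALSE fast_recovery              0.875
#>    fast03    0.502         0.394           0.982            FALSE fast_recovery              0.750
#>    fast04    0.412         0.215           0.977            FALSE fast_recovery              0.875
#>      his3    1.000         0.740           0.462            FALSE        normal              0.750
#>   norec02    0.669         0.984           0.265             TRUE   no_recovery              0.125
#>   norec03    0.716         0.987           0.343             TRUE   no_recovery              0.250
#>   norec04    0.574         0.966           0.176             TRUE   no_recovery              0.125
#>    norm02    0.968         0.836           0.439            FALSE        normal              0.625
#>    norm03    0.940         0.875           0.334            FALSE        normal              0.500
#>    norm04    0.914         0.917           0.357            FALSE        normal              0.500
#>     rad52    0.740         1.000           0.352             TRUE   no_recovery              0.250
#>      rif1    0.462         0.352           1.000            FALSE fast_recovery              0.750
```

Every genotype lands in the class of the archetype it was simulated as:
the rad52-like genotypes pass the early-senescence passage-2 filter
(`c_s = 2210` here, printed by `attr(asg, "p2_filter")`) and correlate
r > 0.96 with the rad52 MDP; the rif1-like genotypes top the fast-recovery
ranking; recovered fractions echo the class recovery probabilities
(high for fast recovery, low for no recovery). Class means:

```r
round(class_recovery_summary(asg), 3)
#>        normal   no_recovery fast_recovery
#>         0.594         0.188         0.812
```

Unsupervised clustering of a richer screen recovers planted structure:

```r
qt <- simulate_qt_benchmark(seed = 1)          # 23 planted profile variants
cl <- qt_cluster(compute_mdps(transform_sizes(qt$dataset)),
                 qt_config(450, 2, "rms"))
length(cl$clusters)
#> [1] 23
```

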