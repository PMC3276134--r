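---
title: "Quantitative analysis of telomere-initiated senescence screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative analysis of telomere-initiated senescence screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(senescreen)
```

## The experimental system

Budding-yeast cells lacking telomerase (for example *est1*Δ mutants) lose
telomeric DNA at every division and, after some tens of generations, enter
*senescence*: cultures grow poorly or not at all. Rare lineages —
*survivors* — escape by recombination-dependent telomere maintenance, and
cultures containing them regain near-normal fitness. A genome-wide screen
for modifiers of this process crosses every viable gene deletion into the
telomerase-null background and follows thousands of double-mutant cultures
through serial passages: at each passage a culture is diluted into fresh
medium (or pinned onto fresh agar), regrown, and photographed; image
analysis converts each culture to a *size* in integrated-intensity units.

`senescreen` implements the downstream quantitative analysis of such
screens — and a stochastic simulator of them, so that every statistic can
be validated against a known ground truth without any external data.

Two screen designs are supported, differing in throughput and dilution:

* **liquid**: 96-well plates, 60 query genotypes plus 36 control cultures
  on the outer frame of every plate, 16 plates, 16 passages, roughly
  1:70 dilution per passage;
* **solid**: 1536-position pinned arrays, 22 passages, at most ~16-fold
  effective dilution per passage. A culture diluted 1:*D* can perform about
  log2(*D*) doublings per passage, so the solid design senesces visibly
  more slowly — fewer telomere-shortening divisions happen per passage.

## From culture sizes to mean density profiles

Raw culture sizes are strongly heteroscedastic: healthy cultures of order
10^6 intensity units scatter far more, in absolute terms, than senescent
ones. Sizes are variance-stabilised with a Box–Cox power transform with
power parameter 0.6; `transform_sizes()` applies the plain power form
g(x) = x^0.6 by default, under which healthy cultures land near 4000
units. The textbook shifted form (x^0.6 − 1)/0.6 is available as
`variant = "scaled_power"`; the two differ by an affine map, so every
correlation-based statistic downstream is identical under either choice.
All profile statistics and thresholds in the package operate on the
transformed scale.

The unit of analysis is the **mean density profile (MDP)**: for one
genotype, the arithmetic mean (and sample standard deviation, n − 1
denominator) of its replicate culture sizes at each passage
(`compute_mdp()`). Three statistics compare MDPs:

* **Pearson correlation r** (`pearson_correlation()`) — trajectory *shape*
  similarity. r is invariant under positive-affine rescaling of either
  profile, so a sick strain and a healthy strain with similarly shaped
  senescence curves correlate well; this is deliberate, and it is why
  ranked heat maps of correlated profiles look stripy. A constant profile
  has no defined correlation; the package returns `NA` and never silently
  converts it to 0, because a fabricated zero would assert
  anti-membership.
* **RMS difference** (`rms_difference()`) — absolute, scale-dependent
  profile distance, sqrt(mean((a − b)^2)).
* **MDP area** (`mdp_area()`) — the plain sum of the profile over all
  passages, a total-fitness summary. No normalisation by passage count is
  applied.

## The three-archetype classification

Genotypes are classified by the similarity of their MDP to three archetypal
trajectories (`assign_classes()`), with non-exclusive memberships:

* **normal** (his3Δ-like control behaviour): r to the normal archetype
  above 0.85;
* **no recovery** (rad52Δ-like; recombination-dependent survivor formation
  crippled): r to the no-recovery archetype above 0.5 *and* mean size at
  passage 2 below the screen-wide cutoff C^s = C^ave − 0.5·C^SD, where
  C^ave and C^SD are the mean and standard deviation of *all individual
  culture sizes* at passage 2 (`compute_passage2_filter()`). The filter
  keeps out strains that merely share the late flat shape without having
  entered senescence early; it is intentionally scale-dependent, unlike
  the correlation term, and the package records the scale it was computed
  on. Which population each genotype contributes to the comparison is the
  genotype's mean transformed size at the filter passage — MDPs being the
  unit of classification.
* **fast recovery** (rif1Δ-like; accelerated entry into *and* exit from
  senescence): the top k = 20 genotypes by r to the fast-recovery
  archetype. This class is rank-based rather than threshold-based because
  a strict cutoff (r > 0.85) retains almost no members while the most
  correlated profiles still share a distinctive shape; ties at the k-th
  value are all included, and a strict-threshold mode is available via
  `r_fast_recovery_strict`.

Memberships may overlap — the screens' own class lists do (accelerated
strains are simultaneously the strongest anti-correlates of the normal
archetype) — and no precedence rule is imposed.

**Recovered fraction.** A genotype's recovered fraction
(`recovered_fraction()`) is the share of its replicate cultures that
reached 1000 transformed units or more by passage 19. Two readings of "by"
are implemented. The default, `at_passage`, tests the size at the deadline
passage itself. The alternative, `by_passage`, tests the running maximum up
to the deadline; it is provided for completeness but is *not* the default
because cultures start the screen above the threshold (≈4000 units), so a
running maximum taken from passage 1 classifies every culture as recovered
and the statistic degenerates. Under serial dilution a senescent culture
that never produced survivors is monotonically small at late passages,
while a culture with survivors stays large once recovered, so the
deadline-passage reading captures exactly the intended event. With default
simulator settings the two archetypal failure modes are well separated:
non-recovering cultures sit near the detection floor (≈380 units) at
passage 19, five-fold below the threshold in raw terms.

## The synthetic screen generator

`simulate_screen()` generates a screen with known ground truth. Each
culture follows a deterministic backbone (`expected_trajectory()`):
constant at `initial_fitness` until `onset_passage`, then geometric decline
by `decline_rate` per passage — scaled by the design's division budget
log2(dilution)/log2(70), so identical parameters senesce more slowly on
solid — down to a floor of `nadir_fraction × initial_fitness`. At the
nadir, each culture independently either recovers (probability
`recovery_prob`; regrowth starts after a geometric delay with mean
`recovery_onset_mean` passages and proceeds at `regrowth_rate` per passage
back toward the initial fitness) or, if it never recovers, risks permanent
sterility with per-passage probability `extinction_prob`, after which its
sizes are exactly 0 — emulating the tiny transferred volume that makes
deeply senescent cultures die out. Multiplicative lognormal measurement
noise (coefficient of variation `cv`, mean-preserving) is applied last,
with readings below a detection floor recorded as 0.

Reproducibility is structural: every culture draws from a private RNG
substream derived deterministically from (seed, plate, row, column), so an
identical configuration reproduces a screen bit-for-bit and adding plates
never perturbs existing cultures.

`preset_classes()` encodes the study conditions the package is validated
under. Values stated by the screen literature are taken directly: recovery
probabilities 0.50 / 0.81 / 0.29 for the normal / fast-recovery /
no-recovery classes, a fitness nadir near passage 6 for normal senescence
under the liquid design, healthy fitness ≈4000 transformed units (raw
initial fitness 10^6), 16 liquid / 22 solid passages, dilutions 70 and 16.
Values the literature does not quantify were chosen once, as plausible for
this system, and documented here rather than fitted: noise cv 0.25, nadir
floor 2% of initial fitness, recovery delay mean 3 passages (1 for the
fast-recovery class), per-passage extinction probability 0.10–0.15, reduced
initial fitness (5 × 10^5) and earlier onset for the no-recovery class.

What the generator does *not* emulate — and hence what passing tests do not
show about real screens: telomere-length dynamics and survivor type
structure, spatial plate effects and pinning artefacts, cross-contamination,
batch effects between plates, and the long tail of intermediate phenotypes
a genome-wide library contains. Parameter-recovery results on synthetic
screens bound the pipeline's correctness, not the biology's tidiness.

## Parameter-recovery benchmarks

Two canned experiments connect the simulator to the statistics
(`simulate_benchmark_screen()`, `simulate_qt_benchmark()`); the same
experiments run in the test suite and in `scripts/acceptance.R`.

**Archetype benchmark.** 120 genotypes (40 per archetype preset), solid
design, 8 replicate cultures each; the archetype genotypes themselves are
named his3/rad52/rif1, and the his3 control keeps the solid design's 144
replicates, which also stabilises the normal archetype's MDP. With default
thresholds, ≥90% of genotypes recover their ground-truth class membership,
and each truth class's culture-weighted recovered fraction lies within 3
binomial standard errors of its preset recovery probability. Two analysis
choices deserve note. First, the fast-recovery class size is set to
k = 40 in this experiment — the planted class size — since a top-20 class
can by construction contain at most half of 40 planted members; the
package default stays 20. Second, the binomial check is grouped by
*ground-truth* class: predicted memberships are non-exclusive and include
genuinely similar trajectories from other classes, so only the truth
grouping follows the binomial error model the check is based on. The
predicted-class means (`class_recovery_summary()`) are reported alongside.

**Clustering benchmark.** Quality-threshold (QT) clustering
(`qt_cluster()`) is the unsupervised alternative to archetype matching:
grow, around every remaining genotype, the largest candidate cluster whose
diameter (maximum pairwise distance) stays below a quality threshold;
extract the largest candidate; repeat. No cluster count is chosen in
advance. The implementation is deterministic: inputs are sorted by
genotype label, the point that least increases the diameter is added first
(ties alphabetical), and candidate ties go to the alphabetically first
seed. The default distance is 1 − r with diameter threshold 0.3
(members correlate above 0.7) and minimum cluster size 2 — all
configurable, since the original analysis published its cluster count but
not its settings; that count is treated as an outcome, not a target.

The benchmark plants the 23 trajectory variants of `qt_demo_classes()`
(three genotypes each, 24 replicates — the focused replicate count used for
genotypes of special interest on solid arrays). The variants were selected
by a greedy maximin design over a grid of onset passages, decline rates,
fitness tiers, nadir floors and flat profiles, so that their noise-free
expected profiles are mutually ≥ ~600 RMS units apart while within-variant
MDP scatter stays near 200. Clustering uses the RMS distance with a
diameter threshold of 450 — midway between those two scales — because
several variants differ by fitness tier alone, which the affine-invariant
correlation distance cannot see. QT clustering recovers all 23 planted
classes, each cluster pure.

```{r benchmark, eval = FALSE}
sim  <- simulate_benchmark_screen(seed = 1)
d    <- transform_sizes(sim$dataset)
mdps <- compute_mdps(d)
asg  <- assign_classes(mdps, d, archetype_config(fast_recovery_top_k = 40))
class_recovery_summary(asg)

qt  <- simulate_qt_benchmark(seed = 1)
cl  <- qt_cluster(compute_mdps(transform_sizes(qt$dataset)),
                  qt_config(450, 2, "rms"))
length(cl$clusters)
```

## Numerical and design choices

* **Transform variant.** `plain_power` is the default so that raw
  intensities of order 10^6 land on the familiar ≈4000-unit fitness scale
  and the 1000-unit recovery threshold is meaningful; classification is
  unaffected by the choice because r is affine-invariant.
* **Undefined correlations** sort after all defined values in ranked lists
  and never grant class membership.
* **Ties.** Ranked lists break correlation ties by genotype label;
  the top-k class includes every genotype tied at the k-th value (stable
  superset); QT tie rules are described above.
* **Sizes are validated, not coerced**: negative sizes, ragged passage
  series and empty tables are errors naming the offending culture;
  quality concerns (single replicates, sterile-from-start cultures) go
  into a structured report (`validate_dataset()`) instead of errors.
* **Serialisation.** Culture tables are plain delimited text with one
  comment line carrying scale/design/passage metadata; sizes are written
  at 17 significant digits so write-then-read is bit-exact.
* **Problem sizes.** The bundled experiments use 120 genotypes × 8
  replicates (archetype benchmark) and 69 genotypes × 24 replicates
  (clustering benchmark) on one to two simulated 1536-position plates —
  large enough for the binomial checks above to be sharp, small enough
  that the full suite runs in about a minute.

## Known limitations

* The passage-2 filter scale (raw vs transformed) in the original analyses
  is not documented; this package computes it on the transformed scale and
  records the scale in the filter object.
* The fast-recovery class is rank-based; its size parameter k is a
  modelling choice, not an estimate, and results for that class should be
  read accordingly.
* QT clustering is O(n³)–O(n⁴) in the number of genotypes; at genome-wide
  scale (thousands of MDPs) it is usable but slow, and the distance matrix
  dominates memory.
* The simulator's trajectories are piecewise-geometric with a hard floor;
  real senescence curves are smoother and their onset varies between
  replicate cultures, which the generator only captures through
  measurement noise and stochastic recovery timing.
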