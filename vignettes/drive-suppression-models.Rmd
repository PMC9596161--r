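---
title: "Modelling homing suppression drives in panmictic and continuous-space mosquito populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling homing suppression drives in panmictic and continuous-space mosquito populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drivesim)
```

## The problem

A homing suppression drive is a CRISPR construct inserted into a
haplosufficient female-fertility gene. In the germline of drive/wild-type
heterozygotes, Cas9 cuts the wild-type allele and homology-directed
repair copies the drive in, so the construct is inherited by well over
half of the offspring. Because females lacking a functional copy of the
target gene are sterile, a drive that reaches high frequency drags the
population's reproductive capacity down, potentially to collapse. Some
candidate drives add an X-shredder, a nuclease that destroys X-bearing
sperm and biases the offspring of drive-carrying fathers toward males.

Whether release of such a drive actually eliminates a target *Anopheles
gambiae* population depends on details that panmictic models cannot see.
In continuous space, wild-type individuals can recolonise areas the
drive has emptied and outrun it — "chasing" — so two drives with similar
genetic loads can behave very differently. `drivesim` implements the
allele-level mechanics of eight published drive parameterisations and
evaluates them in four population models: a discrete-generation panmictic
model, its continuous-space extension on the unit square, and a
weekly-time-step mosquito life-cycle model with overlapping generations,
again panmictic and spatial.

## Drive mechanics

All stochastic and deterministic components share one set of allele-level
rules, acting on genotypes over the alleles WT (wild-type), DR (drive)
and R2 (nonfunctional resistance). Functional (r1) resistance is outside
the model's scope.

* **Germline modification** happens only in DR/WT heterozygotes and is
  sequential per gametocyte: a wild-type allele first becomes R2 with the
  sex-specific germline resistance rate, and if it stays wild-type it is
  converted to DR with the sex-specific conversion rate. A gamete then
  carries either post-modification allele with probability 1/2
  (`gamete_distribution()`).
* **Embryo resistance**: if the mother carries a drive allele, each
  wild-type allele of the embryo is independently converted to R2 with
  the maternal embryo resistance rate, whether or not the embryo
  inherited the drive.
* **Paternal deposition** (zpg and zpgX parameterisations): sperm of
  drive-carrying fathers carries Cas9; the effect is mosaic and is
  modelled as sterilising drive-carrying daughters with the deposition
  rate, without touching their germline. Restricting the effect to
  drive-carrying daughters is a deliberate design decision: it is the
  reading under which the zpg drive shows the reported behaviour — an
  early peak in genetic load that declines to a low equilibrium, an
  allele frequency that plateaus well below fixation, and a load below
  every nos variant. Sterilising *all* daughters of drive fathers
  instead drives the equilibrium load above 0.99, contradicting all
  three observations.
* **Sex**: if the father carries the drive and the X-shredding rate is
  `s`, an offspring is male with probability `1/(2 - s)`; shredding
  never changes offspring numbers.
* **Fertility**: a female is fertile iff she carries at least one
  wild-type allele and was not sterilised by deposition. Somatic Cas9
  expression reduces the fecundity of DR/WT heterozygote mothers by the
  female somatic cost, and (for the nos parameterisation) of pairs with
  DR/WT fathers by the male somatic cost.

`drive_presets()` ships the eight parameterisations (two zpg
interpretations, each with and without the X-shredder, and four nos
interpretations differing in somatic costs) plus an inert `wildtype`
control.

## The four population models

**Discrete-generation panmictic** (`run_discrete_panmictic()`): 50,000
diploids by default. Every fertile female picks a uniform-random mate;
her offspring count is Binomial(50, w'/25) with
`w' = w * beta / ((beta - 1) N/K + 1)` (Beverton–Holt; `beta` is the
low-density growth rate, default 10), so a wild-type female at capacity
leaves two offspring on average. Ten burn-in generations precede a
heterozygote release amounting to 1% of the census.

**Discrete-generation spatial** (`run_discrete_spatial()`): the same
model on the unit square. Mates are sampled uniformly within the
migration radius (default 0.04) of each female; the Beverton–Holt term
uses the local density in a 0.01 circle around her (all individuals in
the circle, herself included — with self-exclusion the convex density
response inflates the wild-type equilibrium ~6% above K at the default
density, whereas self-inclusion holds it within 1%); offspring disperse
from the mother by an axis-wise Gaussian with standard deviation equal to
the migration value (mean displacement `0.04 * sqrt(pi/2) ~ 0.05`),
redrawing any displacement that leaves the arena. The release is placed
in a central 0.01-radius circle.

**Weekly Anopheles life-cycle** (`run_anopheles()`): weekly steps with
overlapping generations. Individuals are juveniles for two weeks and
adults from their third; adult survival follows the schedules
[5/6, 4/5, 3/4, 2/3, 1/2, 0] (females) and [2/3, 1/2, 0] (males), giving
3.5 expected adult-female-weeks and a mean generation time of
`r round(mean_generation_time(), 3)` weeks — hence 3,167 weeks stand in
for 1,000 generations. Females mate once, store sperm, and re-mate with
5% weekly probability; a mated fertile female lays Poisson(50 × pair
fitness) eggs in half of her weeks. Density acts only on juveniles: all
juvenile mortality is applied in one cull immediately after egg
generation, with survival
`beta / (25 ((beta - 1) r + 1)) * (2/3.5)^r`, where the competition
ratio `r` compares new eggs plus five-fold-weighted week-old larvae to
the competition expected at capacity. At `r = 1` this reproduces the
replacement recruitment exactly. The spatial variant replaces global
counts with a linear competition kernel (weight `1 - d/0.01`,
self excluded, as the competition comes from *other* larvae), migrates
every adult weekly (migration value = mean weekly displacement, default
0.0307 so the per-generation displacement matches the discrete default),
and restricts mate search to the migration radius — the weekly model
does not state a mate-search radius of its own, so the discrete model's
convention is reused.

Other conventions chosen where the weekly protocol is open: the
pre-release burn-in is 32 weeks (~10 generations, mirroring the discrete
model); released individuals are first-week adults split equally between
the sexes (the release sex composition is unstated everywhere, and the
equal split is also used in the discrete models); re-mating candidates
in the spatial variant are restricted to the radius and a failed
re-mating attempt keeps the stored mate; the drive counts as lost only
when no drive allele survives in living individuals *or* stored sperm.

## Genetic load and rescue mode

Genetic load is the fractional reduction of reproductive capacity at the
drive's equilibrium frequency relative to a same-size all-wild-type
population: per step, `load = 1 - P_actual / P_ideal` with `P_actual`
the fecundity-weighted mass of fertile females (X-shredder sex-ratio
bias enters through the female count) and `P_ideal` the all-wild-type
reference (half the census in the discrete model; the standing
fertile-female mass implied by the fixed weekly recruitment, i.e. the
female capacity, in the weekly model). A pure X-shredder fixed in all
males at shredding rate `s` has the closed form
`1 - 2(1 - s)/(2 - s)` (`xshredder_load(0.93) ~ 0.87`), which the
definition reproduces exactly.

To read the load without the population collapsing,
`measure_genetic_load()` runs in *rescue mode*: each step the next
cohort is regenerated at a fixed size from the fertile females, sampled
in proportion to pair fecundity, so genotype frequencies evolve exactly
as at capacity while the census never shrinks.

Two numerical choices matter here:

* **Equilibrium start.** The nos drive needs hundreds of generations to
  equilibrate from a small release, and high-frequency releases push the
  X-shredder drives through a transient whose fertile-female bottleneck
  small rescue populations cannot cross reliably. By default the rescue
  population is therefore initialised at the drive's expected
  equilibrium composition, obtained from the deterministic
  genotype-frequency recursion (`genotype_recursion()`), and the load is
  averaged over generations 61–100 (the stochastic system relaxes around
  the equilibrium within a few generations; the window matches the
  release-protocol convention). The equilibrium itself does not depend
  on how it is approached, which the release-protocol start
  (`start = "release"`) verifies.
* **Aggregated engine.** In rescue mode every transition probability
  depends only on an individual's genotype × deposition × age ×
  stored-mate cell, so the individual-based process is simulated exactly
  on cell counts with binomial/multinomial draws. This makes the cost of
  a load measurement independent of the population size. It matters
  because the fertile-female pool at equilibrium is small (about
  (1 − load)/2 of the census), and small rescue populations drift
  against the wild-type-loss boundary, biasing the measured load upward;
  cross-model parity is therefore measured at 100,000 individuals /
  200,000 adult females, where that bias is negligible, while the nos
  headline load uses the conventional 10,000 (unbiased for nos at that
  size). The test suite checks the aggregated engine against the
  individual-based implementation directly.

## The deterministic recursion

`genotype_recursion()` iterates the expected genotype × sex ×
deposition-flag composition of successive cohorts. Because density
dependence scales every female alike, the expected genotype frequencies
of every stochastic model at capacity follow this recursion, making it a
fast expectation engine and a reference for the individual-based runs.
Two caveats, both visible in the test suite: at finite population size
the stochastic mean acquires a small drift-curvature bias (about 0.01 in
allele frequency at K = 50,000 near steep plateaus), and from a
high-frequency release the replicate trajectories decohere in phase
during steep transients, so their mean lags the deterministic curve.
Comparisons are therefore made from the 1% release protocol, where all
eight presets track the recursion within three standard errors.

## Chasing, outcomes, and sweeps

During a spatial release, wild-type homozygotes cluster at the margins
of the suppressed region; Green's coefficient over an 8 × 8 grid
(`greens_coefficient()`: 0 for Poisson-random points, 1 for maximal
aggregation) quantifies this. Chasing starts when recolonisation
begins: `detect_chase_start()` takes the earlier of the first local
maximum of the (wild-type homozygote) clustering series and the first
local minimum of the wild-type allele count, each defined as the strict
extremum of a centred 11-step window after 3-step moving-average
smoothing. The window mirrors the observation that the two events fall
within about five generations of each other; the weekly models use ±16
weeks (~5 generations). The smoothing and strict-extremum rule are
conventions, chosen here because no canonical rule exists, so borderline
replicates may classify differently.

`classify_outcome()` distinguishes suppression with/without prior
chasing, long-term chasing (drive still present at the time cap; a rare
capped run with no detected chase is classified the same way, as the
taxonomy has no sixth category), and drive loss with/without chasing.
For chases it reports the mean genotype-fertile female count from chase
start and its ratio to the pre-release count; across replicates these
are aggregated weighted by chase duration. `run_sweep()` scans migration
× growth-rate grids, tallies outcomes per cell, and colours each cell by
the representative outcome (`representative_outcome()`), where each pair
of one suppression-without-chasing and one long-term-chasing replicate
first converts to two suppression-after-chasing counts; remaining ties
break in the fixed order suppression-no-chase, suppression-after-chase,
long-term-chase, drive-loss-after-chase, drive-loss-no-chase — a
convention, as no tie-breaking rule is published.

Seeds: every replicate's seed derives from the base seed and its grid
indices via `cell_seed()`, so sweeps are reproducible and a one-replicate
sweep equals the corresponding single run bitwise.

## What the simulations do and do not emulate

All populations are generated internally; there is no external data.
The models capture density-dependent growth, spatial mate limitation,
local competition, overlapping generations, sperm storage and the
allele-level drive mechanics. They deliberately omit seasonality,
long-distance migration, heterogeneous landscapes, interspecies
competition, functional (r1) resistance, and intrinsic fitness costs of
the drive allele itself. Distances are unitless (the unit square);
passing desk-scale tests shows internal consistency of the mechanics and
reproduction of the published equilibrium quantities, not field-scale
prediction.

Scale sensitivity deserves emphasis: chasing statistics depend on the
arena-to-dispersal ratio, so outcome *frequencies* at a desk-scale
K = 10,000 differ from the published full-scale values (drive loss is
far more common, and suppression percentages shift); the outcome
*ordering* across drives is the scale-robust property and is what the
test suite asserts (at K = 10,000, 20 replicates per drive, a
400-generation cap, and an ordering allowance of 0.15 ~ two binomial
standard errors). The wild-type stationarity checks run the spatial
models at their full sizes (K = 50,000; 25,000 adult females), where the
discreteness corrections to the density response are small.

## Worked example

```{r example, eval = FALSE}
library(drivesim)

# equilibrium genetic load of the nos drive
gl <- measure_genetic_load("nos", rescue_size = 10000, seed = 1)
glance(gl)
#>   drive  model     load
#>   nos    discrete  0.957

# a spatial release of the zpg drive: long-term chasing
run <- run_discrete_spatial("zpg", capacity = 10000, max_time = 300,
                            seed = 3)
glance(run)[, c("outcome", "chase_start", "fertile_female_ratio")]
#>   outcome          chase_start fertile_female_ratio
#>   long_term_chase            6                0.35
autoplot(run)
```

## Known limitations

* Outcome frequencies (not orderings) at desk scale are not comparable
  to full-scale values; full grids at published sizes need cluster time.
* The chase detector's smoothing window is a convention; chase start
  times can shift by a few steps under other reasonable rules.
* Rescue-mode loads at small populations are biased upward for
  high-load drives (small fertile pool against an absorbing boundary);
  use larger rescue sizes — the aggregated engine makes them free.
* The weekly spatial model's mate-search radius and the release-cohort
  sex composition are conventions where the protocol is silent; results
  at very low migration are sensitive to the former.
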