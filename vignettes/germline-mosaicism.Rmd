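---
title: "Quantifying germline mosaicism and spermatogonial selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying germline mosaicism and spermatogonial selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spermosaic)
```

## The problem

Gain-of-function point mutations in spermatogonial stem cells — classically
in RTK/RAS-pathway genes such as *FGFR3* — can confer a proliferative
advantage on the mutant stem cell.  Over decades of adult spermatogenesis
this produces clonal expansions in the testis and a rising mutant sperm
fraction with the donor's age (the paternal-age effect).  The measurable
signals are faint: variant allele frequencies (VAFs) of 10^-6^ to 10^-4^,
assayed by digital PCR over hundreds of thousands of molecules per sample.
`spermosaic` implements the full quantitative workflow around such data:

1. turning digital-PCR compartment counts into Poisson-corrected VAFs;
2. cohort statistics for the age association of sperm VAFs;
3. spatial clustering statistics for a dissected testis;
4. two generative stem-cell models — a neutral *hot-spot* model and a
   *selection* model — fitted to the observed testis average by matched
   simulation, with a Monte-Carlo maximum-statistic test for clustering.

## Digital-PCR quantification

A sample is partitioned so single molecules amplify in isolation.  With
`mut` mutant-positive and `wt` wild-type-positive compartments, the mean
number of mutant templates per informative compartment is the Poisson
occupancy correction

$$\lambda = -\ln\!\bigl(1 - \mathrm{mut}/(\mathrm{mut}+\mathrm{wt})\bigr),$$

which `poisson_vaf()` evaluates through `log1p` for numerical accuracy at
rare frequencies.  Replicate reactions (typically 4 per sample, ~300,000
molecules in total) are merged by *summing counts first* and correcting
once: at rare frequencies this is equivalent to averaging per-reaction
corrections, and it remains well defined when individual reactions contain
no mutant molecule.  Negative samples keep a VAF of exactly 0 — no
detection-limit imputation — because the downstream statistics are rank
based and handle ties; `detection_probability()` makes the sensitivity
explicit instead (a true VAF of 10^-5^ is missed with probability
$e^{-3} \approx 5\%$ at 300,000 molecules).

Spike-in dilution series spanning 1:10 to 1:10,000 are summarised by the
Pearson correlation of log~10~ expected versus log~10~ observed mixing
ratios (`calibration_fit()`); steps that sample zero mutant molecules carry
no log-scale information and are excluded but reported.  Cross-platform
comparisons of mutant incidence (digital PCR versus duplex sequencing) use
the two-sided Fisher's exact test on the 2×2 molecule table.

## Cohort statistics

The age association of each variant is Spearman's rank correlation of VAF
against donor age, two-sided throughout.  For cohorts of at most 7 donors
without ties `spearman_age()` evaluates the exact permutation null itself;
larger cohorts go through `stats::cor.test()` (exact where available,
asymptotic with mid-rank ties).  P-values are adjusted across exactly the
set of variants analysed in one run by Benjamini–Hochberg
(`age_associations()`); the family is explicit, never implicit.  Age-group
contrasts (younger ≤ 30, middle 31–44, older ≥ 45 years) run a
Kruskal–Wallis omnibus first and pairwise Mann–Whitney U tests only below a
configurable omnibus threshold (default 0.05).

Per-variant summaries report mean, median, type-7 interquartile range,
maximum and the clustering ratio Max VAF/IQR.  The ratio is kept raw in
machine output and additionally rounded to two significant digits for
display, matching the mixed precision of published summary tables; an IQR
of 0 with a positive maximum yields a "not defined" sentinel rather than an
infinite ratio.

## The dissected testis

The testis is cut into 6 slices of 32 pieces (a 4-strip × 8-row grid, 192
pieces).  Measurements are made on 48 pools of 4 spatially adjacent pieces;
pools above a drill-down threshold (default 5×10^-5^) are re-measured piece
by piece.  The exact pool boundaries are a configuration choice; the
default tiles each slice with 2-strip × 2-row blocks (8 pools per slice),
which is the only contiguous 4-piece tiling consistent with 48 pools.
Pooling uses summed molecule counts when counts are available (conserving
molecules exactly) and member means otherwise.  `cluster_summary()`
computes the Table-style statistics over any unit set; Max/IQR is near 1
under spatial uniformity and grows with subclonal expansion.  The quartile
convention is fixed to type 7 (linear interpolation between order
statistics) because Max/IQR is sensitive to it.

## The stem-cell models

Both models share the growth phase: from the founding cell,
`growth_generations` (default 30) symmetric doublings build the pool of
$2^{30}$ self-renewing spermatogonia present at puberty.  Every daughter
cell mutates with probability $\mu$ per division, so a mutation at
generation $g$ founds a clone of $2^{G-g-1}$ cells — earlier mutations,
bigger clones.  In the adult phase each stem cell divides every
`cycle_days` (default 16) days and either divides symmetrically (two stem
daughters) or differentiates towards sperm.  Wild-type cells do either
with probability 1/2, keeping the pool constant.  A donor of age $a$
contributes $T = \lfloor (a - 13)\,365.25/16 \rfloor$ adult cycles; the
puberty age of 13 years is a convention we expose in the configuration.

* **Hot-spot model** — mutant cells behave exactly like wild type; clusters
  arise only from shared lineage history.  Free parameter: $\mu$.
  New mutant lineages arrive in each adult cycle as Poisson($2^G\mu$)
  single cells, and a clone of $n$ cells becomes $2\,\mathrm{Binomial}(n,
  1/2)$ — a critical branching process.
* **Selection model** — mutant (and only mutant) stem cells divide
  symmetrically with probability `sym_bias` > 1/2, so clones grow
  supercritically with offspring mean $2\,p_{sym}$ per cycle.  Free
  parameter: the bias.  Here $\mu$ is fixed by calibration: we set it so
  the expected mutant fraction accumulated over the 30 pre-pubertal
  doublings equals the genome-average per-site de novo rate of
  1.1×10^-8^ per generation, i.e. $\mu = 1.1\times 10^{-8}/30 \approx
  3.7\times10^{-10}$.  This treats the pre-pubertal lineage as the
  reference source of de novo point mutations, consistent with the
  observation that an appreciable share of de novo mutations arise during
  early development.  The constant is exposed (`genome_site_rate`), not
  hard-coded.

Spatially, descendants stay in close proximity: a clone occupies a
contiguous arc of the unit circle at a uniformly drawn position, and the
circle is cut into `n_pieces` equal arcs to emulate the dissection.  Adult
dynamics do not re-shuffle positions (a documented simplification).
Measured allele fractions are the mutant-cell fraction times
`ploidy_factor` (default 0.5: diploid tissue, heterozygous mutation); the
factor rescales fitted parameters smoothly and is a configuration knob.
Double mutation within a clone is ignored — negligible at these rates.

### Fitting and the Monte-Carlo maximum test

`fit_parameter()` estimates the free parameter as the value that maximises
the fraction of simulated average testis frequencies within
`match_tolerance` (default 5%) of the observed average.  The search is a
13-point log grid spanning ±3 decades around a moment-matching initial
guess (the parameter whose closed-form expected average,
`expected_avg_freq()`, equals the observation), followed by golden-section
refinement between the bracketing grid neighbours.  Two numerical choices
matter:

* **Common random numbers.** Every parameter evaluation reuses the same
  derived seed, making the matched fraction a deterministic function of
  the parameter, so golden-section refinement on a noisy objective is well
  posed.  The master seed is taken from the configuration; the Monte-Carlo
  test derives one seed per batch as `seed + batch_index`.
* **Grid pruning.** Grid points whose expected average exceeds the
  observation by a large factor (3× hot-spot, 50× selection) are recorded
  as matched-fraction 0 without simulation: there the simulated average is
  a concentrated sum of thousands of clone contributions whose lower tail
  cannot reach the window, while simulating them would dominate the budget
  (the hot-spot cost scales linearly with $\mu$).  The selection factor is
  larger because its heavy-tailed average sits well above its typical
  value.  The searched range itself is unchanged.

`mc_test()` then simulates at the fitted parameter until
`n_matched` simulations (default 10,000; full-scale studies use >100,000,
reachable by argument) fall inside the matching window, and reports the
fraction whose *maximum piece frequency strictly exceeds* the observed
maximum — ties are not exceedances.  A count of zero is reported as
p = 0 together with the add-one upper bound $1/(n_{matched}+1)$.
Simulations whose mutant lineages would exceed the stem pool are
unphysical; the batch engine caps them and flags them `saturated` (they
can never match a rare observed average), while the stepwise simulator
raises a parameter-regime error.

**Partition for the maximum.** Summary tables describe the 48 pools, but
the reported maximum for drilled-down variants is an individual piece —
1/192 of the testis.  The Monte-Carlo comparison therefore simulates the
192-piece dissection grid (`n_pieces = 192`); with a 48-arc partition an
exceedance of a piece-level maximum would require a quarter of all mutant
mass in one pool-sized arc, which the matched-average constraint all but
forbids, and the test would lose essentially all its power.  The
average-frequency fit itself is partition-free.

### Engine

The simulator never materialises wild-type cells, and it also never
materialises doomed mutant lineages: arrivals are Poisson-thinned by the
exact extinction probabilities $q_j$ of the branching process
($q_0 = 0,\; q_j = (1-p) + p\,q_{j-1}^2$), and surviving clones follow the
transition law conditioned on survival, sampled by rejection.  This is
exact in distribution and makes the critical hot-spot regime (tens of
thousands of short-lived lineages per simulated testis) tractable.  The
batch engine is C++; readable stepwise R implementations of each stage
(`simulate_growth_phase()`, `simulate_adult_phase()`, `render_testis()`)
are the reference surface, and the test suite checks engine, stepwise
simulator and a brute-force cell-by-cell oracle against each other by
Kolmogorov–Smirnov tests on toy configurations, plus martingale
(critical) and $(2p_{sym})^T$ (supercritical) moment checks.
Reproducibility is exact: all randomness derives from R's RNG (the
engine's internal bit generator is seeded from it), so a fixed seed gives
bit-identical results.

## Synthetic data

The generators emulate the sampling designs so the whole pipeline is
testable without any external data, and always return their ground truth.

* `gen_cohort()`: ~90 donors aged 23–59, zero-inflated lognormal true
  VAFs around a median of 1.5×10^-5^ with an IQR-parameterised spread
  (the lognormal reproduces the heavy right tail behind published Max/IQR
  ratios of 5–66), an optional per-year multiplicative age trend
  referenced to age 40, 270,000–300,000 molecules per sample split over 4
  reactions, molecule-level binomial counts and a 10^-6^ per-molecule
  artifact rate matching wild-type-control backgrounds.  Compartments are
  not simulated individually — at rare frequencies molecule-level binomial
  sampling is equivalent; occupancy saturation is exercised separately
  through `poisson_vaf()`'s own tests.
* `gen_testis()`: the 6×4×8 grid with a uniform background, planted
  contiguous subclones given as per-piece cell fractions, and binomial
  molecule sampling at a configurable depth.
* `gen_dilution_series()`: binomial observation of 10-fold spike-in steps
  at realistic depths, including the zero-observation class at the most
  dilute step.

What the generators do *not* emulate: donor-level covariates (sperm count,
diagnosis), fluorescence amplitudes and threshold calling, spatially
correlated measurement error, and partial tissue dropout beyond simple
missingness.  Passing recovery tests therefore demonstrates correctness of
the statistical machinery under the stated sampling model, not robustness
to instrument-level artifacts.

## Problem sizes used by the test suite

The packaged checks run at desk scale, chosen to keep the full suite in
the tens of minutes while leaving every conclusion unchanged in kind:
2,000 simulations per evaluated parameter value for selection-model fits
(500 for the cheaper-to-peak hot-spot profile), 10,000 matched simulations
per Monte-Carlo p-value, 5,000 replicates for the oracle equivalence
checks, 10^5^ replicates for the supercritical moment check and 1,000
replicate cohorts for type-I calibration.  P-values below 1/10,000 are
reported through the add-one bound; resolving the most extreme published
clustering signals (p ~ 10^-5^) requires the full >100,000-matched-
simulation setting.

## Known limitations

* The spatial model is one-dimensional (arcs on a circle); real clones
  spread through a three-dimensional tubule network.  Max/IQR-style
  statistics are comparatively insensitive to this, but fine-grained
  spatial prediction is out of scope.
* The adult stem-cell pool is constant by construction; A_dark reserve
  stem cells and niche turnover are not modelled.
* The puberty age (13 y) and ploidy factor (0.5) are conventions; both are
  exposed in `sim_config()` and shift fitted parameters smoothly and
  monotonically.
* Matched-fraction fitting inherits Monte-Carlo noise; common random
  numbers stabilise the maximiser, but the reported parameter is exact
  only up to the refinement tolerance (0.05 decades by default).
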