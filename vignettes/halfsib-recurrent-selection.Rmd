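---
title: "Simulating half-sib family recurrent selection with halfsibsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating half-sib family recurrent selection with halfsibsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`halfsibsim` is a stochastic gene-to-phenotype simulator for recurrent
selection in open-pollinated species (forage grasses are the motivating
case). The phenotype of a plant follows the standard quantitative-genetic
decomposition

$$P = G + E + (GE) + R,$$

with a single environment type, so the environment main effect and the
genotype-by-environment deviations vanish and $P = G + R$ with
$R \sim N(0, \sigma^2_R)$. The genotypic value $G$ is the sum over
biallelic QTL of the classical single-locus parameterization: the two
homozygotes score $+a$ and $-a$ and the heterozygote scores $d$. Three
genetic-effects models are supported:

* **additive** — $d = 0$ at every QTL;
* **additive_dominance** — half the QTL (round half up) are purely
  additive, the remainder split as evenly as possible between partial
  ($0 < |d| < |a|$) and over ($|d| > |a|$) dominance;
* **dominance** — all QTL split between partial and over dominance.

Additive effects are drawn $a \sim N(0,1)$. The dominance *degree*
distribution is a modelling choice of this package, made explicit:
$d = u\,|a|\,\mathrm{sign}(a)$ with
$u \sim U(0,1)$ for partial and $u \sim U(1,2)$ for over dominance. Giving
$d$ the sign of the favorable homozygote keeps "favorable allele" well
defined at every locus; whether unfavorable-allele dominance should also
be sampled is genuinely open, and we chose not to, once, for
identifiability of the diversity statistics.

Meiosis uses the Haldane mapping function with no crossover interference:
adjacent loci at distance $\Delta$ cM recombine with probability
$r = \tfrac12(1 - e^{-2\Delta/100})$, and linkage groups assort
independently. Haldane is the simplest standard choice consistent with a
"recombination map" specification; map positions are uniform random on
seven 100-cM groups (the perennial ryegrass karyotype) because no
empirical map is bundled — the default 63 QTL + 194 markers mirror a
published ryegrass growth-score panel in *counts* only. The synthetic map
is therefore labelled synthetic throughout: real maps have non-uniform
marker density, QTL clustering and heterogeneous group lengths that
uniform placement does not emulate, so passing tests say nothing about a
specific empirical genome.

## Founders, families, trials

Founders carry exactly $\lfloor L/2 \rfloor$ heterozygous loci (fresh
random subset per individual) with the remaining loci split evenly at
random between the homozygote classes — a base population at allele
frequency 0.5 with equal fractions of homozygous and heterozygous loci,
which at $p = 0.5$ coincides with Hardy–Weinberg genotype proportions.

Half-sib families are built by polycross: every crossing-block member is
the female of one family, and each progeny's male parent is redrawn
uniformly from the *other* members, so selfs never occur. The male is
resampled per progeny rather than fixed per family; this matches the
"pollen cloud" semantics of a polycross nursery and keeps the among-family
genetic variance at the classical quarter of the additive variance
(`test-acceptance.R` verifies $\approx 25\%$ by one-way variance
decomposition).

Field trials are balanced: `years x locations x reps` plots of
`plants_per_plot` plants (default 3 × 3 × 3 × 30 = 810 plants per family).
Years, locations and replications carry no systematic effects; all
non-genetic variation is pooled into the plant-level residual. The
residual variance is not a free parameter — it is *calibrated* so that the
half-sib family-mean heritability

$$h^2_{fm} = \frac{\sigma^2_b}{\sigma^2_b + (\sigma^2_w + \sigma^2_R)/n}$$

hits the scenario target (0.1, 0.5 or 0.9 in the case study), where
$\sigma^2_b$ and $\sigma^2_w$ are the among- and within-family genotypic
variances estimated from the cycle-0 families and $n$ is the plants per
family. Calibration happens once, at cycle 0, and $\sigma^2_R$ is held
constant afterwards, so the realized heritability erodes as selection
exhausts genetic variance — the behaviour of an engine that fixes the
error variance when the genotype-environment system is created. Setting
`recalibrate_each_cycle = TRUE` in `run_strategy()` instead re-derives
$\sigma^2_R$ from each cycle's families, holding the heritability constant
through time; this is exposed as a sensitivity switch because the two
conventions bracket what published engines do, and they change the
trajectory tail noticeably (see "Known limitations").

## The two strategies

Each cycle: polycross the crossing block into one half-sib family per
parent, phenotype every family in the trial, advance the top
`round(k * 0.2)` families (round half up, minimum one; ties to the lower
family index) by family phenotypic mean, then take five plants from each
advanced family —

* **AHS** (among half-sib family selection): a *random* five;
* **AWHS** (among and within): the *best* five by individual phenotype.

Selection within a family operates on the trial plants' individual
phenotypes — what a breeder can actually observe — not on genotypic
values. With 20% among-family selection and five plants kept per family,
the crossing block size is restored exactly for the case-study sizes (10,
50, 100), and the updated block fully replaces the old one by default
(`crossing_block_replace_proportion = 1`; partial replacement is
supported). The program is closed: no germplasm enters after cycle 0.

## Statistics

* **Mean genotypic value** per cycle is computed over *all* progeny of the
  families the new crossing block was drawn from, never a sampled
  representative.
* **ΔG%** is the between-cycle change in that mean, scaled by
  (ideal value − cycle-0 mean) so a run that climbs all the way to the
  ideal accumulates exactly 100%. The normalization constant is a
  reporting choice; the ΔG90 *cycle* statistic is invariant to it (tested
  by recomputation under rescaled effects).
* **ΔG90** is 90% of the 50-cycle cumulative gain; its companion statistic
  is the first cycle whose cumulative gain reaches it. Runs with no
  positive total gain report value 0 at cycle 0 and are retained in
  aggregates, not discarded.
* **Hamming distance** is the average number of allele substitutions per
  individual needed to reach the ideal genotype, as a percentage of the
  `2 * n_qtl` allele slots, computed over QTL only (markers have no
  favorable allele) on the crossing block. The ideal is locus-wise
  value-maximal: heterozygote-ideal exactly when $d > |a|$. Note the
  strictness — with $\mathrm{sign}(d) = \mathrm{sign}(a)$ a
  large-magnitude *negative* $d$ leaves the positive homozygote on top, so
  $|d| > |a|$ would be the wrong test.
* **Fixation rates** count QTL at which every block member is homozygous
  for the same allele, split by whether that allele belongs to the
  higher-valued homozygote (the sign of $a$) — also under overdominance,
  for comparability with the classical favorable/non-favorable bookkeeping.

## The scenario grid and seeds

The case study crosses 2 strategies × 3 genetic models × 3 heritabilities
× 3 population sizes = 54 scenarios. Per-run seeds derive from the base
seed through a counter-based scheme keyed on the genotype-environment
configuration (model × heritability × size) and the run index —
deliberately *not* on the strategy. The two strategies of a configuration
therefore run under common random numbers: same synthetic map, same QTL
effect draw, same founders, with trajectories diverging only where the
selection rules differ. This pairing sharpens AHS-versus-AWHS contrasts at
small replicate counts, which is exactly how the comparison is framed. QTL
effects and founders are redrawn per run; the synthetic map is fixed per
configuration by default (`map_mode = "per_run"` redraws it) to keep
between-run variance attributable to sampling, not to map geometry.

## Problem sizes used by the checks

The shipped checks scale the trial down and state so explicitly, with the
residual variance recalibrated so the family-mean heritability target is
preserved (the documented scale-down mode):

* variance partition: 200 families × 200 progeny, noise-free;
* cycles-to-ΔG90 (additive, 100 parents, $h^2_{fm} = 0.5$): 10 replicate
  runs per strategy at 10 plants per plot (270 plants per family);
* final Hamming minima: 10 replicate runs per scenario at 3 plants per
  plot, over the panels where the minimum lives (both strategies,
  $h^2_{fm} = 0.9$, 50 and 100 parents — final Hamming decreases in both
  heritability and population size for every model, so these panels
  contain the grid minimum);
* the full-factorial rehearsal behind the ordering and trend checks: all
  54 scenarios at 2 paired runs and 2 plants per plot.

Family-mean heritability is invariant to the plot scale-down by
construction. Within-family selection is not: the best-5-of-270 (or
5-of-54) differential under a recalibrated, smaller residual is somewhat
stronger than best-5-of-810 at full scale, so AWHS is mildly flattered in
scaled-down runs; AHS, which samples within families at random, is
unaffected. This is the main distortion the scale-down introduces.

## Known limitations

* Diploid genetics only; many forage species are autotetraploid.
* No epistasis (the `K` of the gene-network specification is pinned to 0
  and rejected otherwise), no mutation, no migration, one environment
  type, no genomic or marker-assisted selection.
* Calibrate-once heritability semantics produce slower late-cycle
  trajectories than a per-cycle recalibrating engine, so the absolute
  cycle-to-ΔG90 counts depend on that convention (and on the synthetic
  map's geometry), while the AHS/AWHS ordering and the size of the gap
  between them are robust to it. Treat absolute cycle counts as
  convention-dependent; treat orderings and gaps as the transferable
  results.
* The dominance-degree distribution and the even partial/over split are
  this package's explicit choices; a different mixture shifts the
  dominance-model Hamming floor substantially (each overdominant locus
  fixed favorably still scores one substitution per individual).
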