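# halfsibsim

Stochastic simulation of recurrent selection in open-pollinated
(cross-pollinated) crops, built for the question every forage breeder
faces when designing a program around half-sib families: is it worth
phenotyping individual plants *within* families, or is selecting among
family means enough?

The package simulates the whole gene-to-phenotype loop. A
genotype-environment system couples a linkage map (QTL + neutral markers
on centimorgan positions) with per-QTL effects under three genetic
models — fully additive, a 50% additive / partial / over dominance
mixture, and a pure partial/over dominance mixture, with
`a ~ N(0, 1)` and the heterozygote scoring `d`. Phenotypes follow
`P = G + R`: meiosis uses the Haldane mapping function, half-sib families
are produced by polycross with selfing excluded, and the plant-level
residual variance is calibrated so the half-sib *family-mean*
heritability

```
h2_fm = s2_b / (s2_b + (s2_w + s2_R) / n)
```

matches a target (0.1 / 0.5 / 0.9). Two strategies run for 50 cycles:

* **AHS** — among half-sib family selection: advance the best 20% of
  families by phenotypic mean, keep a random 5 plants from each;
* **AWHS** — among *and within*: same family selection, but keep the best
  5 plants by individual phenotype.

Per cycle the simulator reports the population genotypic mean and genetic
gain (ΔG%), the Hamming distance to the locus-wise ideal genotype (as %
of allele slots), and favorable/non-favorable allele fixation rates; per
run it reports the 90% cumulative gain (ΔG90) and the cycle at which it
is first reached. A factorial scenario runner crosses strategy × genetic
model × heritability × population size (the canonical grid is 54
scenarios) with counter-based seeding that pairs the two strategies of
each configuration under common random numbers.

## Worked example

```r
library(halfsibsim)
set.seed(2024)

map <- build_synthetic_map(n_groups = 7, n_qtl = 63, n_markers = 194,
                           group_length_cM = 100)
eff <- sample_qtl_effects("additive", 63, qtl_ids = map$id[map$kind == "qtl"])
ges <- genetic_system(map, eff, model = "additive")
ges
#> Genotype-environment system
#>   loci: 257 (63 QTL, 194 markers) on 7 linkage groups
#>   model: additive; E = 1; K = 0; p0 = 0.5

design <- trial_design(plants_per_plot = 5)   # 3x3x3x5 = 135 plants/family
cfg <- strategy_config("AWHS", n_parents = 50)
res <- run_strategy(cfg, ges, design, target_h2_fm = 0.5)
res
#> AWHS run: 50 cycles, 50 parents
#>   mean G: -0.799 -> 56.627 (ideal 59.248)
#>   dG90 = 86.07% reached at cycle 25; final Hamming 8.19%

round(res$stats[c(1, 2, 11, 26, 51), ], 2)
#>    cycle mean_g hamming_pct fixed_favorable_pct fixed_nonfavorable_pct delta_g_pct
#> 1      0  -0.80       50.63                0.00                   0.00        0.00
#> 2      1   1.52       49.10                0.00                   0.00        3.87
#> 11    10  36.06       29.35                3.17                   0.00        5.17
#> 26    25  51.23       17.22               49.21                   0.00        0.76
#> 51    50  56.63        8.19               77.78                   4.76        0.31
```

Reading the trace: a random base population at allele frequency 0.5 sits
halfway to the ideal genotype (Hamming 50%); fifty cycles of
among-and-within selection carry the mean genotypic value from −0.8 to
56.6 against an ideal of 59.2, with 90% of that cumulative gain banked by
cycle 25. Favorable-allele fixation climbs to 78% of QTL while drift
fixes 4.8% the wrong way — the price of a closed program.

For a strategy comparison, run a grid (here scaled down):

```r
grid <- build_scenario_grid(models = "additive", heritabilities = 0.5,
                            sizes = 100, runs = 10, base_seed = 1)
ex <- run_experiment(grid, trial_design(plants_per_plot = 10))
ex$summary[, c("strategy", "mean_dg90_cycle", "mean_final_hamming")]
```

A command-line front end with `simulate`, `grid`, `summarize` and
`make-ges` subcommands is installed at `exec/halfsibsim` under the
package installation directory (YAML configuration; see
`read_simulation_config()`).

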