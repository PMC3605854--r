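# coalabc

Coalescent simulation and approximate Bayesian computation (ABC) for
inferring **island colonization histories** from paired mitochondrial
sequence and microsatellite data, plus **mismatch-distribution dating** of
population expansions.

The package grew out of the population system of the nematode
*Pristionchus pacificus* on La Réunion: four deeply diverged lineages
(A–D) each independently colonized the island, founding resident
populations (a–d) through bottlenecks. `coalabc` answers two questions for
systems of this shape:

1. **When did each island population expand?** The mismatch distribution
   (histogram of pairwise nucleotide differences) is fitted with the
   sudden-expansion model F(θ₀, θ₁, τ); the scaled expansion time τ = 2μt
   is converted to years via the per-locus mutation rate
   (t = τ/2μ), with parametric-bootstrap SSD and raggedness p-values.
2. **In what order and when were the islands colonized?** A structured
   coalescent simulator (population splits with founder bottlenecks,
   HKY+Γ+I sequence mutation, generalized stepwise microsatellite
   mutation) drives ABC over all 24 colonization orders with
   order-constrained uniform priors (t₈/t₇ > t₆, t₆/t₅ > t₄ > t₃ > t₂ >
   t₁): rejection on robustly scaled summary statistics,
   logistic-regression scenario choice, local-linear posterior adjustment,
   and the standard validation battery (PCA pre-evaluation, posterior
   predictive model checking, confidence in scenario choice,
   bias/precision on pseudo-observed datasets).

A synthetic-data module generates study-shaped datasets (97 island strains
in four populations of 16–30, 565-bp mtDNA, 16 STR loci, four world
lineages) under a known truth, so the entire pipeline is testable without
any data download.

## Worked example

```r
library(coalabc)

# a study-shaped synthetic dataset under colonization order c > a > b > d
bundle <- generate_study_like_dataset(seed = 1)
bundle
#> <coalabc_bundle> 380 mt sequences (565 bp), 760 STR gene copies x 16 loci,
#> 8 populations

# --- stage 1: mismatch-distribution dating of each island population ----
pops <- bundle$popmap$population %in% c("a", "b", "c", "d")
aln  <- bundle$mt[rownames(bundle$mt) %in% bundle$popmap$id[pops], ]
mmd  <- mmd_table(aln, bundle$popmap, n_boot = 200, seed = 1)
mmd[, c("population", "tau", "p_ssd", "t_years")]
#>   population       tau p_ssd t_years
#> 1          a 3.0729626 1.000   36000
#> 2          b 0.3058636 0.000    4000
#> 3          c 2.4270908 0.040   28000
#> 4          d 3.4247658 0.365   40000
```

Each row is one island population: `tau` is the fitted scaled expansion
time, `t_years = tau / (2 x 4.294e-5)` rounded to the nearest 1,000 years
(565-bp locus at 7.6e-8 substitutions/site/generation, one generation per
year), and `p_ssd` is the parametric-bootstrap goodness-of-fit p-value:
small values (population b in this realization, whose single mtDNA
genealogy happens to carry very little variation) mean the sudden-expansion
model fits the observed mismatch distribution poorly.

```r
# --- stage 2: ABC scenario choice over colonization orders --------------
scens  <- enumerate_colonization_scenarios(scenario_template())
length(scens)
#> [1] 24
priors <- default_priors()
design <- study_design()
cfg    <- run_config(out_dir = "results", seed = 1, design = design,
                     priors = priors, scenarios = scens,
                     n_per_scenario = 1000, tolerance = 0.01)
res    <- run_pipeline(bundle, cfg)
sort(res$model_choice$posterior, decreasing = TRUE)[1:3]
res$posterior$summary   # mean/median/quartiles of t1..t8, N's, db
```

`run_pipeline()` writes `model_choice.json` (posterior probability of each
colonization order), `parameter_posterior.tsv` (posterior mean, median,
quartiles and 95% interval per parameter) and `mmd.tsv` into the result
directory; every file embeds the seed and configuration hash, and a rerun
with the same configuration is byte-identical. At publication scale the
reference table would use hundreds of thousands of simulations per
scenario; the defaults are sized for a laptop.

The methods vignette (`vignettes/coalabc-methods.Rmd`) documents the
demographic model, mutation models, statistic panel, ABC choices, and the
limits of what synthetic-data validation shows.

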