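# fstpower

Monte Carlo power analysis for detecting single genetic loci under
artificial (domestication) selection with F<sub>ST</sub>-outlier scans.

Modern breeding programs — Atlantic salmon is the motivating case — run
several nearly isolated populations in parallel under the same breeding
goals. A locus that responds to that selection changes allele frequency in
the *same direction in every strain*, which leaves two complementary
footprints:

- **Low-F<sub>ST</sub> design** — among the farmed strains themselves,
  convergent selection *depresses* differentiation below the neutral
  expectation, so selected loci appear in the lower tail of the
  among-strain F<sub>ST</sub> distribution.
- **High-F<sub>ST</sub> design** — between a pool of farmed strains and a
  pool of wild (unselected) populations, selection *inflates*
  differentiation, so selected loci appear in the upper tail of the pooled
  farmed-vs-wild F<sub>ST</sub> distribution.

`fstpower` asks, before any genotyping is done: *given the known effective
population size N<sub>e</sub>, number of populations, generations of
selection, initial differentiation F<sub>ST</sub>(0), and a selection
coefficient s, what fraction of truly selected loci would such a scan
detect?*

## Model

A single bi-allelic locus is simulated forward in time in finite
populations of constant size N<sub>e</sub> (half males, half females,
discrete generations, random mating with replacement, no mutation or
migration). Selection is additive viability selection with no dominance:
parents are drawn with probability proportional to genotype fitness

&nbsp;&nbsp;&nbsp;&nbsp;w(AA) = 1 + s,&nbsp;&nbsp; w(Aa) = 1 + s/2,&nbsp;&nbsp; w(aa) = 1.

Each Monte Carlo iteration draws an overall founding frequency p₀ ~
U(0, 1), drifts all populations neutrally from that common founder until
the multi-population F<sub>ST</sub> first reaches the target
F<sub>ST</sub>(0) (emulating divergence among the founder river
populations), then applies `n_gen` generations with selection
(alternative hypothesis) or without (null). In the high-F<sub>ST</sub>
design, wild populations are first expanded to census 500 so drift is
concentrated in the small farmed strains, and the final comparison is
between the two pooled metapopulations.

Differentiation is measured with the Weir & Cockerham (1984) θ estimator
built from the variance components *a* (among populations), *b* (among
individuals within populations) and *c* (within individuals):
θ = a / (a + b + c). Power is the fraction of selection-arm θ values beyond
the empirical 5% (low design) or 95% (high design) order-statistic
percentile of the no-selection null distribution.

## Worked example

```r
library(fstpower)

scn <- sim_scenario(s = 0.5, approach = "high_fst", n_iter = 200)
scn
#> <sim_scenario> approach = high_fst
#>   ne = 50, n_pop = 10, n_gen = 10, fst0 = 0.05, s = 0.5
#>   wild_size = 500, n_iter = 200, burnin_cap = 500

estimate_power(scn, seed = 7)
#> <power_result> high_fst: power = 0.890 (178 of 200 alternative theta values
#>   above 95th null percentile 0.0408)
#>   discarded restarts: 1 (null), 2 (alt)
```

A locus with selective advantage s = 0.5, screened after 10 generations
across 10 farmed strains against 10 wild populations, would be flagged as
a high-F<sub>ST</sub> outlier (at the empirical 5% false-positive level)
in about 89% of cases: the 95th percentile of the simulated neutral
farmed-vs-wild θ distribution is ≈ 0.041, and 178 of the 200
selection-arm θ values exceed it. The `discarded restarts` counter reports
iterations rerun because the locus fixed globally for the same allele (an
unobservable marker). The same locus screened only *among* the farmed
strains (`approach = "low_fst"`) is detected far more rarely (power ≈ 0.13
with the same settings) — the core practical message of this kind of
power analysis.

The same run from a shell, writing `distributions.tsv` and `summary.json`:

```sh
Rscript exec/fstpower --approach low --s 0.5 --seed 7 --iterations 200 --out run1/
#> running low_fst design: s = 0.5, 200 iterations per arm, seed 7
#> power = 0.1300 (threshold 0.0340); wrote run1
```

Parameter sweeps (`--sweep s --values 0,0.1,0.25,0.5`, or `run_sweep()`
in R) re-estimate power varying one parameter at a time.

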