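---
title: "Methods: simulating the power of F_ST-outlier scans for domestication selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating the power of F_ST-outlier scans for domestication selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fstpower)
```

## The question

Parallel breeding programs keep several nearly isolated populations under
the same breeding goal. If selection acts (directly) on a bi-allelic
locus, its allele frequency moves in the same direction in every strain.
`fstpower` estimates, by forward simulation, the probability that such a
locus would be flagged by one of two F\_ST-outlier designs:

* **low_fst** — the locus shows *less* differentiation among the farmed
  strains than neutral drift predicts (lower tail of the among-strain
  F\_ST distribution);
* **high_fst** — the locus shows *more* differentiation between the
  pooled farmed strains and a pool of unselected wild populations (upper
  tail of the pooled two-group F\_ST distribution).

Because the null distribution is generated by simulation under the same
known demography (effective sizes, number of populations, generations,
initial differentiation), rather than estimated from genome-wide data,
the scan exploits all available prior knowledge of the breeding program.

## The simulation model

Each population holds `ne` diploid individuals at a single bi-allelic
locus, half males and half females. Generations are discrete and
non-overlapping; mating is random with replacement (a parent may have
many offspring; selfing is impossible because sexes are separate). There
is no mutation and no migration, so fixation is absorbing.

Selection is additive viability selection on allele A with no dominance
(h = 1/2):

$$w_{AA} = 1 + s, \qquad w_{Aa} = 1 + s/2, \qquad w_{aa} = 1 .$$

Each offspring draws a father from the males and a mother from the
females, each parent with probability proportional to its genotype
fitness, and inherits one uniformly chosen allele from each parent.
Because parents are sampled independently with replacement, each
offspring's paternal allele is an independent Bernoulli draw with the
fitness-weighted male gamete frequency

$$p^\ast = \frac{n_{AA} w_{AA} + \tfrac12 n_{Aa} w_{Aa}}
               {n_{AA} w_{AA} + n_{Aa} w_{Aa} + n_{aa} w_{aa}},$$

(and likewise maternal), so the per-sex offspring genotype counts are
jointly multinomial. `next_generation()` samples that multinomial
directly — an exact, not approximate, equivalence that makes a full
power analysis run in seconds.

With `s = 0` this reduces to the classical two-sex Wright–Fisher model:
offspring frequency is a martingale with one-generation variance
$p(1-p)/(2N)$ (when both sexes have frequency $p$), and expected
heterozygosity decays by the factor $1 - 1/(2N_e)$ per generation. The
test suite verifies both moments at $N \in \{50, 500\}$ with $10^4$
replicates, and checks a size-$10^4$ population under $s = 0.3$ against
the infinite-population viability recursion
$p' = (p^2 w_{AA} + p(1-p) w_{Aa})/\bar w$ generation by generation.

## One Monte Carlo iteration

1. Draw a founding frequency $p_0 \sim \mathrm{U}(0,1)$; exact 0 or 1
   (probability-zero draws that would make the locus monomorphic, hence
   not a marker) are redrawn.
2. **Burn-in.** Found all populations (`n_pop` for low_fst, `2 n_pop`
   for high_fst) by independent Hardy–Weinberg sampling from $p_0$, then
   drift them neutrally and synchronously until the multi-population
   Weir–Cockerham $\theta$ first reaches `fst0`. This emulates the
   divergence among the founder river populations. The target is checked
   from generation 0 onward, so `fst0 = 0` stops immediately.
3. **Selection phase.** low_fst: each farmed strain evolves `n_gen`
   generations with coefficient `s` (alternative) or neutrally (null).
   high_fst: the first half of the burnt-in populations is designated
   farmed (the populations are exchangeable at the split, so the rule is
   immaterial) and treated as above; each wild population is first
   expanded to `wild_size` by a single neutral generation — an
   instantaneous census expansion that damps subsequent wild drift — and
   then evolves neutrally for `n_gen` generations.
4. **Statistic.** low_fst: $\theta$ over the `n_pop` strain samples.
   high_fst: genotype counts are pooled within each group and $\theta$
   is computed for the two metapopulation samples (farmed
   $n = n_{pop} \cdot n_e$, wild $n = n_{pop} \cdot \text{wild\_size}$;
   500 and 5000 at the defaults).

Both hypothesis arms run `n_iter` independent iterations (no
common-random-number pairing). Power is the fraction of alternative-arm
$\theta$ values strictly beyond the empirical percentile of the null arm
(5th for low_fst, 95th for high_fst).

## The F_ST estimator

`weir_cockerham_theta()` implements the Weir & Cockerham (1984)
single-locus, two-allele $\theta$ with the standard unequal-sample-size
weights: from per-sample size $n_i$, allele frequency $p_i$ and observed
heterozygosity $h_i$ it forms the variance components $a$ (among
populations), $b$ (among individuals within populations) and $c$ (within
individuals) and returns $\theta = a/(a+b+c)$. Two deliberate choices:

* **Negative estimates are retained.** Clamping at zero would distort
  the lower tail of the null distribution — exactly the tail the
  low_fst design thresholds on.
* **A globally monomorphic locus has undefined $\theta$** ($a+b+c=0$);
  this is returned as a flag, never as 0 or NaN arithmetic.

The unit tests check the implementation against an independently written
transcription of the same estimator via the allele-indicator nested-ANOVA
mean squares, agreeing to $10^{-12}$ over 1000 random genotype tables,
plus exact boundary cases ($\theta = 1$ for two samples fixed for
opposite alleles; $\theta \le 0$ for identical samples).

## Handling degenerate iterations

An iteration can end with the locus fixed for the same allele in every
population, where $\theta$ is undefined. Such a locus could never be seen
in a real marker screen, so the iteration is **discarded and rerun with a
fresh founding frequency**; per-iteration restart counts are reported in
all outputs so the induced conditioning can be assessed. The same rule
applies when the burn-in either loses polymorphism globally or fails to
reach `fst0` within `burnin_cap` generations. More than 100 restarts in
a single iteration raises an error, marking the scenario as pathological
rather than looping forever.

This conditioning has a visible consequence under extreme selection: for
very large `s` in the low_fst design the observable-marker distribution
is bimodal — most iterations sit near $\theta \approx 0$ (all strains
near-fixed for A), while iterations founded at low $p_0$ show split
fixation at $\theta = 1$. The median and lower tail, not the mean, carry
the convergent-selection signal, and the tests are written accordingly.

## Parameters and defaults

| parameter | default | meaning |
|---|---|---|
| `ne` | 50 | per-strain effective size, simulated literally as the census size (typical pedigreed aquaculture values are 30–50) |
| `n_pop` | 10 | parallel farmed strains (plus 10 wild populations in high_fst) |
| `n_gen` | 10 | generations since onset of selection (few, for recently domesticated species) |
| `fst0` | 0.05 | initial differentiation, matching what is observed among wild source populations |
| `wild_size` | 500 | post-split census of wild populations, an order of magnitude above the strains |
| `s` | — | selection coefficient of the scanned locus |
| `n_iter` | 1000 | iterations per hypothesis arm |
| `burnin_cap` | 500 | burn-in guard; at `ne = 50` the drift approximation $F_{ST}(t) = 1-(1-\tfrac{1}{2N_e})^t$ predicts only ~5.1 generations to reach 0.05 |

Census size equal to $N_e$ with an exact 50:50 sex ratio is taken
literally; odd sizes are rejected rather than split unevenly.

## Determinism and seeding

All randomness flows from one master seed. Each iteration runs on a
deterministic substream keyed by (hypothesis, iteration index) through an
integer mixing function, so a single iteration is reproducible in
isolation, the two arms are independent, and increasing `n_iter` never
perturbs earlier iterations. Identical invocations produce byte-identical
output files. Every sweep point reuses the master seed, which acts as
common random numbers across points and makes power-versus-parameter
curves smoother than independent seeding would.

## Numerical choices

* **Percentile definition.** The threshold is a pure order statistic of
  the sorted null sample: element $\lceil 0.05 n \rceil$ (low_fst) or
  $\lfloor 0.95 n \rfloor$ (high_fst), with a *strict* inequality for
  "beyond". This is conservative and interpolation-free; any
  interpolating quantile definition differs by $O(1/n)$. Under the null
  it yields power just below the nominal 0.05 (49/1000 for distinct
  values).
* **Burn-in overshoot.** The stopping rule uses a noisy estimate of
  $\theta$, so the achieved initial differentiation slightly overshoots
  `fst0` and the mean stopping time (about 5–7 generations at the
  defaults) sits near, not exactly at, the deterministic 5.1; this is
  monitored with a broad tolerance rather than asserted tightly.

## What the simulations do and do not emulate

The generator reproduces the *designed* features of a breeding-program
scan: finite parallel strains, a common founder pool with realistic
initial divergence, uni-directional selection with shared breeding goals,
and wild reference populations with weak drift. It does **not** emulate:
linkage and LD (selection acts directly on the observed locus — a
best-case scenario; real scans lose power through incomplete
marker–locus LD), mutation, migration between strains or year classes,
overlapping generations, dominance, age structure, multi-locus outlier
statistics, or genotyping error. Passing tests therefore validate the
model's internal behaviour, not these aspects of real data.

## Problem sizes used in the test suite

The shipped tests scale the Monte Carlo work to what the checks need:
moment oracles use $10^4$ single-generation replicates; null calibration
uses 500 iterations per arm (99% binomial interval around 0.05);
qualitative design comparisons and monotonicity sweeps use 300
iterations per arm with a two-standard-error slack
($2\sqrt{0.25/300} \approx 0.058$) for non-decreasing checks; burn-in
timing uses 200 replicates. Full-scale runs (1000 iterations, the
package default) sharpen all of these but change no conclusion.

## Known limitations

* Power estimates are conditional on observable (polymorphic) loci via
  the discard rule; scenarios where most iterations fix globally are
  reported with large restart counts and should be interpreted with care.
* The estimator of $\theta$ is the bi-allelic single-locus form; no
  multi-locus averaging or bootstrap intervals are provided.
* Very weak selection combined with few generations is indistinguishable
  from drift at any attainable iteration count — the scans themselves,
  not the simulator, lack power there.
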