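---
title: "Sample-size effects on theta and the tests of neutrality"
author: "thetaSweep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sample-size effects on theta and the tests of neutrality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thetaSweep)
```

# The problem

Watterson's estimator of the population-scaled mutation rate,
$\hat\theta_W = S / a_n$ with $S$ the number of segregating sites and
$a_n = \sum_{i=1}^{n-1} 1/i$, is unbiased only when every mutation is
equally observable — neutrality and constant population size. Two common
violations concentrate variants at low frequency: exponential population
growth (fast coalescence near the tips of the genealogy creates an excess
of young, rare variants) and purifying selection (deleterious variants are
held at low frequency until they are lost). Rare variants are exactly the
ones a small sample misses, so under either violation $\hat\theta_W$
*rises with sample size*: small panels underestimate it, and they
underestimate it more severely for selectively constrained sites than for
neutral ones. Nucleotide diversity $\pi$ (the mean pairwise difference per
site) weights variants by heterozygosity, is insensitive to the rare tail,
and stays flat in sample size.

Because the tests of neutrality are built from these quantities, the bias
propagates: Tajima's $D \propto \pi - \theta_W$ and Fu–Li's $D^*$ (total
versus singleton mutations) drift with sample size at different rates for
synonymous and nonsynonymous sites, and the McDonald–Kreitman statistics —
the Neutrality Index $NI = (P_n/P_s)/(D_n/D_s)$ and the adaptive fraction
$\alpha = 1 - (D_s P_n)/(D_n P_s)$ — shift because the polymorphism counts
$P_n, P_s$ grow with the panel while the divergence counts do not. This
package quantifies all of these effects with exact folded-spectrum
statistics, a subsampling sweep pipeline, a forward Wright–Fisher
simulator, and a synthetic exome generator, so the full analysis is
reproducible without any external data.

# Statistics

All statistics operate on a `SiteFrequencySpectrum`: a folded (minor-allele)
histogram, because no outgroup or ancestral-state call is assumed — a
"singleton" is a site whose *minor* allele occurs once. Sample size in the
formulas is always the number of sequences $n$ (haplotypes); diploid panels
of $s$ individuals enter as $n = 2s$ and the sweep reports its axis in the
panel's native unit (individuals).

* `wattersonTheta`: $(S/a_n)/\mathrm{sites}$.
* `nucleotideDiversity`: $\sum_m c_m\, m(n-m) / \binom{n}{2} /
  \mathrm{sites}$, the folded form of the mean pairwise difference.
* `tajimaD`: $(k - S/a_1)\big/\sqrt{e_1 S + e_2 S(S-1)}$ with the full
  1989 variance constants ($b_1, b_2, c_1, c_2, e_1, e_2$ from
  `tajimaConstants`).
* `fuLiDStar`: the no-outgroup $D^*$ with the *corrected* (1995 erratum)
  $u_{D^*}, v_{D^*}$ constants; segregating-site and singleton counts stand
  in for total and singleton mutation counts. The constants were validated
  against an independently written implementation and against neutral
  coalescent simulations (mean $\approx 0$, sd $\approx 1$) before the
  package was built.
* Undefined statistics ($S = 0$, or empty MK cells) return `NA_real_` with
  a warning — never silently 0 — because per-gene statistics at small
  sample sizes frequently have no segregating sites, and an undefined value
  must remain distinguishable from a vanishing numerator. On disk they are
  written as `.`.
* MK counts are pooled over genes *before* the $NI$/$\alpha$ ratios are
  taken: per-gene ratios are usually undefined, and exome-wide values imply
  pooled counts. Polymorphism is counted within the analyzed subsample —
  a site segregating only outside the group does not count, which is
  precisely the sample-size mechanism under study. No frequency pruning is
  applied before the MK table (none is part of the analysis this package
  implements).

# The sweep pipeline

`runSweep` partitions the panel into *disjoint* groups of the requested
sizes (default 16, 32, 64, 128, 256, 512 individuals — exactly 1,008, the
default panel), pools each group's SNVs per site class into one spectrum,
computes every statistic, and summarises each series by

* the OLS slope of $\log_2(\mathrm{statistic})$ on $\log_2(n)$ — the
  power-law exponent of the sample-size response;
* the large-vs-small difference $\delta = v(512) - v(16)$ and ratio
  $v(512)/v(16)$ (oriented large/small, so inflation gives ratio > 1);
* Pearson correlation on log-transformed pairs (raw pairs for signed
  statistics, which cannot be log-transformed) and the Kendall rank
  correlation, with two-sided descriptive p-values (no multiple-testing
  correction is applied, and none is claimed).

Partitions are redrawn `nRedraws` times (default 10) with seed-derived
substreams; summaries are computed on the redraw-mean series and the
spread of per-redraw slopes is reported alongside (`slope_sd_redraws`),
since both aggregations are defensible and they answer slightly different
questions. Genes can be binned by dN/dS (half-open bins, top bin
inclusive) to resolve the constraint dependence; the dN/dS > 0.8 exclusion
filter is applied at load time by `readGeneTable`, guarding against
multiple-hit overcorrection in likelihood divergence estimates. Per-class
site totals must be supplied in the gene table — codon-level site counting
belongs to the upstream divergence pipeline, not here.

# The forward simulator

`runSimulation` is an individual-based Wright–Fisher simulator of a single
non-recombining locus (default 5 kb), with infinite-sites mutation on a
finite position grid (a new mutation redraws its position while it
collides with a segregating one), Poisson mutation influx
$2N'\mu' L$ per generation, and genic (semidominant, $h = 1/2$)
multiplicative selection: a haplotype carrying mutations $j$ has fitness
$\prod_j (1 - s_j/2)$. Deleterious effects draw a scaled coefficient
$\gamma = 2 N_e s$ from a gamma distribution with shape 0.206 and a
configurable mean (2–2000 in the study scenarios); the dominance and
fitness model are the standard defaults of forward simulators in this
field, which the source analyses did not override. Replicates are
independent loci; linkage *within* the locus is complete, matching the
caveat that genomic segments are inherited as blocks.

## Demography

Two scenarios share their history up to the final epoch:

1. burn-in at the ancestral size $N_e = 10{,}000$ (default
   200,000 generations, i.e. $10 \times 2N$, to reach mutation–drift
   equilibrium);
2. a split into two daughter populations that start at a bottleneck size
   of 1,032 diploids and grow exponentially at the same rate to
   $N_e = 9{,}210$ over 715 generations (~0.31 %/generation);
3. a final 920-generation epoch in which the *constant* branch stays at
   9,210 while the *exponential* branch grows to $N_e = 512{,}210$.

The three anchor sizes (10,000; 9,210; 512,210) are the scenario's stated
conditions; the *durations and bottleneck size are a reconstruction* from
the two-epoch human growth models this scenario family is built on
(out-of-Africa bottleneck ≈ 1,000 diploids, slow growth ≈ 0.3 %/gen,
recent explosive growth), and every one of them is an explicit,
overridable argument of `demographyConstant()` / `demographyExponential()`.
The wording "splits into two and both grow … until they reach 9,210"
fixes the qualitative shape — daughters start small and grow — but not the
onset or rate; the 920-generation final epoch reproduces the scenario's
hallmark behaviour (a ≈ 80–90 % neutral $\theta_W(512)/\theta_W(16)$
excess under growth, checked against the coalescent expectation below),
whereas a 205-generation final epoch, the other common choice in this
model family, yields almost none. After the split the branches exchange no
migrants, so only the sampled branch's size history is simulated; the
other branch cannot influence any sampled statistic.

## Rescaling

Forward simulation of $N_e = 512{,}210$ is not a desk-scale computation,
so `rescaleConfig` applies the standard $\theta$-preserving rescaling:
$N/\lambda$, $\mu\lambda$, $s\lambda$, durations$/\lambda$, which leaves
$4N\mu$, $\gamma = 2Ns$ and coalescent time in units of $2N$ invariant.
The study scenarios use $\lambda = 100$ for the exponential branch (final
population 10,244 haplotypes) and $\lambda = 17$ for the constant branch —
the strongest rescaling that keeps the final population at or above 1,024
haplotypes, so that the largest sample (512) never exceeds half the
population. Rescaled selection coefficients above 1 are capped at 1 (any
value past that point is effectively lethal and such mutations never
segregate); the capped fraction is reported in the run diagnostics.
Rescaling is exact for the scaled parameters but not for discreteness:
with $\lambda = 100$ the explosive growth spans ~9 discrete generations,
and samples become a sizeable fraction of the rescaled population, which
slightly flattens the largest-sample spectra. These are the known costs of
desk-scale forward simulation and the reason the simulation comparisons
carry Monte-Carlo-level tolerances.

## The coalescent oracle

`expectedThetaNeutral` provides an independent deterministic expectation
for neutral runs: $E[\hat\theta_W] = \mu L\, E[T_{total}]/a_n$, with
$E[T_{total}]$ obtained by integrating the ancestral-lineage pure-death
process (rates $\binom{k}{2}$ in coalescent time) with a stiff ODE solver
and mapping lineage counts back to generations through the analytic time
change of the piecewise constant/exponential schedule. For a constant-size
schedule it reduces to $4N_e\mu L$ at every sample size, and it is exactly
invariant under rescaling — both facts are asserted in the test suite, and
the integrator itself is cross-checked against a separately written Monte
Carlo coalescent sampler.

# The synthetic exome generator

`syntheticGeneTable` emulates the *shape* of a large human exome panel —
default 1,008 diploid individuals and 500 genes (scalable to the
~13,000-gene scale of real exome sets), 300 synonymous / 900 nonsynonymous
sites per gene, per-gene dN/dS from a Beta(1.2, 3.3) (mean ≈ 0.27) with
human–chimp-scale dS (mean ≈ 0.013) and Poisson divergence counts. SNV
panel frequencies follow the folded neutral law $\propto 1/m + 1/(n-m)$
tilted toward singletons: a uniform growth tilt of 0.37 (bringing the
panel singleton share to ≈ 45 %, as observed in large human exome panels)
plus, for nonsynonymous SNVs, a constraint tilt of
$0.25\,(1 - dN/dS)$, so that constrained genes carry proportionally more
singletons (and proportionally fewer nonsynonymous SNVs overall). The
tilt is a one-parameter modelling convenience that reproduces the
qualitative constraint ordering; it is *not* a mechanistic DFE-to-spectrum
map, and no quantitative claim rests on it. Allele copies are placed
uniformly on haplotypes so the panel spectrum realizes the drawn counts
exactly (Hardy–Weinberg, no structure, no linkage disequilibrium — real
panels have all three, which is one reason the empirical patterns are
checked directionally, not numerically). `plantedGeneTable` constructs a
deterministic table realizing an arbitrary spectrum exactly, the
construct-then-recover fixture for the pipeline.

# Numerical and design choices

* **Folded spectra only** — no ancestral-state calls anywhere; matches the
  no-outgroup $D^*$ and avoids polarization error as a confounder.
* **Sample-size unit** — statistics always use sequences ($n = 2s$ for
  diploid panels); the conversion is recorded in the sweep metadata.
* **Missing genotypes** — sites with any missing call are dropped listwise
  at VCF read; the synthetic and simulated paths are complete by
  construction.
* **Ties and degenerate series** — log-log regression drops non-positive
  values (with a warning) and returns `NA` below 3 points; correlation
  tests return `NA` for constant series; the delta/ratio summaries error
  when the requested sizes are absent rather than silently interpolating.
* **Determinism** — every stochastic entry point takes a seed; replicate
  $r$ and redraw $r$ use seed-derived substreams, so runs are
  bit-reproducible and manifests record the seed and file checksums.
* **Problem sizes** — the shipped tests run the simulator at a few hundred
  replicates and the acceptance script at 1,000 replicates (matching the
  scenario definition) under the rescalings above; these sizes give
  slope-level Monte-Carlo errors of roughly ±0.01 and were chosen as the
  point where the scenario comparisons stabilize.

# What the simulation scenarios do and do not reproduce

With the reconstruction above, the neutral checks are sharp: constant-size
$\theta_W$ is flat and matches $4N_e\mu$; the exponential branch's neutral
excess $\theta_W(512)/\theta_W(16)$ sits in the 80–90 % band implied by
the coalescent expectation; $\pi$ is flat everywhere; and the ordering of
sample-size slopes in the selection strength $\gamma$ is reproduced under
both demographies, as is the exponential-vs-constant ordering at fixed
$\gamma$.

The *absolute* constant-branch selection response this model can produce
is modest: an exact Poisson-Random-Field computation of the constant-size
expectation with a gamma(0.206) DFE caps the $\log_2$–$\log_2$ slope near
0.11 at mean $\gamma = 2000$ (the slope saturates in $\gamma$ because the
heavy near-zero mass of a shape-0.206 gamma keeps contributing
effectively neutral variants), and the forward simulator agrees with that
theory to within Monte-Carlo error — the test suite computes both and
compares them. At mean $\gamma = 2$ the constant-branch slope is ~0.015,
so the slope *ratio* between strong and weak constraint under constant
size is large (~8) and dominated by the tiny denominator. Reports of
substantially larger constant-size responses for this scenario family
(slopes around 0.2, ratios near 3) are not reachable by any gamma-mixture
DFE at near-constant size in this framework; the package reports what the
stated model implies rather than tuning the model toward such numbers.

# Limitations

* No recombination within a locus and independence across loci; no
  migration after the split; no beneficial mutations (the DFE is
  purifying-only); dominance fixed at $h = 1/2$.
* The synthetic exome generator is a test harness for the pipeline's
  *directional* behaviour: passing its checks demonstrates the pipeline
  machinery, not that real exome data would yield any particular number.
* Divergence counts are inputs (or generated); no alignment or codon-level
  site counting is performed here.
* Heavy rescaling compresses explosive growth into few discrete
  generations; comparisons against the continuous-time coalescent carry
  corresponding tolerance.
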