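# thetaSweep

Sample size changes what population genetics sees. Watterson's estimator
of the scaled mutation rate, `theta_W = S / a_n` (S segregating sites,
`a_n = sum_{i<n} 1/i`), is unbiased only when every variant is equally
observable. Exponential population growth and purifying selection both
pile variants into the rare tail that small samples miss, so `theta_W`
*rises* with the number of sequences sampled — and it rises faster for
selectively constrained (nonsynonymous) sites than for neutral
(synonymous) ones, while nucleotide diversity `pi` stays flat. Every test
built from these quantities inherits the bias: Tajima's D, Fu–Li's D*
(no outgroup), and the McDonald–Kreitman statistics, the Neutrality Index
`NI = (Pn/Ps)/(Dn/Ds)` and the adaptive fraction
`alpha = 1 - (Ds*Pn)/(Dn*Ps)`, all drift with panel size.

thetaSweep is for population geneticists who want to quantify that drift
on their own panels or in simulation. It provides:

* **Exact folded-spectrum statistics** (`wattersonTheta`,
  `nucleotideDiversity`, `tajimaD` with the full 1989 variance constants,
  `fuLiDStar` with the corrected no-outgroup constants), operating on a
  `SiteFrequencySpectrum` S4 container; undefined statistics are `NA`,
  never silent zeros.
* **McDonald–Kreitman machinery** (`MKCounts`, `aggregateMK`,
  `neutralityIndex`, `alphaAdaptive`), with counts pooled over genes
  before ratios.
* **A subsampling sweep pipeline** (`runSweep`): disjoint sample-size
  groups (default 16…512 of a 1,008-sample panel, redrawn multiply),
  per-class pooled spectra, dN/dS gene bins, log2–log2 regression slopes,
  large-vs-small deltas/ratios, and correlation tests.
* **A forward Wright–Fisher simulator** (`runSimulation`, Rcpp core) of a
  two-branch human-like growth model (constant vs. explosive growth) with
  a gamma distribution of deleterious fitness effects (`gamma = 2*Ne*s`,
  shape 0.206), full within-locus linkage, theta-preserving population
  rescaling (`rescaleConfig`), and a deterministic coalescent oracle
  (`expectedThetaNeutral`) for neutral validation.
* **A synthetic exome generator** (`syntheticGeneTable`,
  `plantedGeneTable`) emulating the shape of a large human exome panel,
  so the whole pipeline is testable without external data, plus readers
  and writers for the gene-table TSV pair, bi-allelic VCF and
  class-annotation BED.

See the vignette (`vignettes/sample-size-bias.Rmd`) for the models,
parameter choices and limitations.

## Worked example

```r
library(thetaSweep)

## spectrum statistics on a folded SFS: 10 sequences, 5 kb, 32 segregating
## sites of which 18 are singletons
sfs <- SiteFrequencySpectrum(c(18, 7, 4, 2, 1), nSeq = 10, nSites = 5000,
                             siteClass = "synonymous")
wattersonTheta(sfs)     # 0.002262309
nucleotideDiversity(sfs)# 0.001915556
tajimaD(sfs)            # -0.7379886
fuLiDStar(sfs)          # -0.691768
```

The negative D and D* say the spectrum is singleton-heavy relative to the
neutral constant-size expectation. Now the full sweep on a synthetic
1,008-individual exome panel:

```r
gt <- syntheticGeneTable(SynthConfig(nGenes = 200, seed = 7))
sw <- runSweep(gt, nRedraws = 2, seed = 42)

thetaRatioBySize(sw)
#   sample_size theta_ratio
# 1          16       0.176
# ...
# 6         512       0.210

sm <- sweepSummary(sw)
sm[sm$statistic == "theta_w", c("site_class", "slope", "slope_se", "ratio")]
#      site_class  slope slope_se ratio
#      synonymous 0.0765   0.0115  1.31
#   nonsynonymous 0.1201   0.0258  1.57

sm[sm$statistic %in% c("ni", "alpha"), c("statistic", "delta", "ratio")]
#   statistic  delta ratio
#          ni  0.111 1.194
#       alpha -0.111 0.743
```

Read: theta grows with sample size (log–log slope 0.08 at synonymous,
0.12 at nonsynonymous sites — constrained sites are more biased), the
512-vs-16 ratio is 1.31× vs 1.57×, `theta_N/theta_S` climbs from 0.18 to
0.21, the Neutrality Index rises with panel size (delta +0.11) and the
apparent adaptive fraction falls by the same amount — a small panel
overstates adaptation.

For the simulation side:

```r
cfg <- rescaleConfig(SimulationConfig(demography = demographyExponential(),
                                      nReplicates = 500, seed = 1), 100)
reps <- runSimulation(cfg)
meanThetaBySize(reps, "neutral")        # theta_W rises with n; pi flat
expectedThetaNeutral(16, cfg@demography, cfg@mu, 5000)  # coalescent oracle
```

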