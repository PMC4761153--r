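test_that("planted spectra round-trip exactly through the gene table", {
  nInd <- 25
  planted <- list(synonymous = SiteFrequencySpectrum(
    c(10, rep(0, 24)), nSeq = 50, nSites = 300, siteClass = "synonymous"))
  gt <- plantedGeneTable(planted)
  got <- pooledSFS(gt, "synonymous")
  expect_equal(unname(singletons(got)), 10)
  expect_equal(segSites(got), 10)

  set.seed(9)
  for (case in 1:5) {
    planted <- list(
      synonymous = randomFeasibleSFS(50, 200, siteClass = "synonymous"),
      nonsynonymous = randomFeasibleSFS(50, 600,
                                        siteClass = "nonsynonymous"))
    gt <- plantedGeneTable(planted, nIndividuals = 25)
    for (cl in names(planted))
      expect_equal(sfsCounts(pooledSFS(gt, cl)),
                   sfsCounts(planted[[cl]]))
  }

  # planted empty -> S = 0
  gt0 <- plantedGeneTable(list(synonymous = SiteFrequencySpectrum(
    rep(0, 25), nSeq = 50, nSites = 100, siteClass = "synonymous")))
  expect_equal(segSites(pooledSFS(gt0, "synonymous")), 0)

  # infeasible: more sites than capacity is blocked upstream
  expect_error(SiteFrequencySpectrum(c(30, 0), nSeq = 4, nSites = 10),
               "exceed")
})

test_that("zero SNV density gives an empty, statistic-free panel", {
  gt <- syntheticGeneTable(SynthConfig(nIndividuals = 40, nGenes = 20,
                                       synDensity = 0, nonsynDensity = 0,
                                       seed = 2))
  expect_equal(nrow(snvRecords(gt)), 0L)
  st <- statsBySize(gt, list(`8` = sampleIds(gt)[1:8]))
  expect_true(all(st$S == 0))
  expect_true(all(st$theta_w == 0))
})

test_that("neutral model produces a 1/i-law panel spectrum", {
  gt <- syntheticGeneTable(SynthConfig(nIndividuals = 40, nGenes = 600,
                                       sfsModel = "neutral",
                                       synDensity = 0.05, seed = 5))
  sfs <- pooledSFS(gt, "synonymous")
  n2 <- 80
  m <- seq_len(40)
  w <- 1 / m + 1 / (n2 - m)
  w[40] <- w[40] / 2
  # chi-square goodness of fit on pooled bins
  obs <- sfsCounts(sfs)
  br <- list(1, 2, 3:5, 6:12, 13:40)
  o <- vapply(br, function(b) sum(obs[b]), numeric(1))
  p <- vapply(br, function(b) sum(w[b]), numeric(1)) / sum(w)
  gof <- suppressWarnings(chisq.test(o, p = p))
  expect_gt(gof$p.value, 0.001)
})

test_that("constraint tilt concentrates nonsynonymous variants on singletons", {
  cfgSel <- SynthConfig(nIndividuals = 80, nGenes = 300, seed = 6,
                        sfsModel = "selection")
  gt <- syntheticGeneTable(cfgSel)
  synS <- sfsCounts(pooledSFS(gt, "synonymous"))
  nonS <- sfsCounts(pooledSFS(gt, "nonsynonymous"))
  expect_gt(nonS[1] / sum(nonS), synS[1] / sum(synS))
})

test_that("generation is deterministic in the seed and respects the filter", {
  cfg <- SynthConfig(nIndividuals = 30, nGenes = 25, seed = 77)
  g1 <- syntheticGeneTable(cfg)
  g2 <- syntheticGeneTable(cfg)
  expect_identical(dosageMatrix(g1), dosageMatrix(g2))
  expect_identical(geneSummary(g1), geneSummary(g2))
  expect_true(all(geneSummary(g1)$dn <= 0.8))
  expect_true(all(geneSummary(g1)$ds <= 0.8))
  g3 <- syntheticGeneTable(SynthConfig(nIndividuals = 30, nGenes = 25,
                                       seed = 78))
  expect_false(identical(dosageMatrix(g1), dosageMatrix(g3)))
})
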