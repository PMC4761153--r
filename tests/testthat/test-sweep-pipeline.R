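test_that("partitioning yields disjoint groups of the requested sizes", {
  ids <- sprintf("s%04d", 1:1008)
  sizes <- c(16, 32, 64, 128, 256, 512)  # sums to the full 1008 panel
  parts <- partitionSamples(ids, sizes, nRedraws = 3, seed = 1)
  for (p in parts) {
    expect_equal(unname(lengths(p)), sizes)
    expect_equal(length(unique(unlist(p))), 1008L)
  }
  # distinct redraws differ
  expect_false(identical(parts[[1]], parts[[2]]))
  # reproducible from the seed
  expect_identical(parts, partitionSamples(ids, sizes, nRedraws = 3,
                                           seed = 1))
  expect_equal(unname(unlist(partitionSamples(letters[1:16], 16,
                                              seed = 2)[[1]])) |> sort(),
               letters[1:16])
  expect_error(partitionSamples(ids, c(sizes, 1), seed = 1),
               "partition error")
})

test_that("dN/dS binning uses half-open bins with an inclusive top bin", {
  genes <- data.frame(gene_id = c("a", "b", "c"),
                      dn = c(0.01, 0.3, 0.5), ds = c(0.2, 0.4, 0.5),
                      dn_ds = c(0.05, 0.95, 1.0),
                      div_n = 1, div_s = 1, syn_sites = 10,
                      nonsyn_sites = 30)
  gt <- GeneTable(genes, data.frame(gene_id = character(),
                                    pos = integer(), class = character()),
                  matrix(integer(), 0, 2), c("i1", "i2"))
  bins <- binGenesByDnDs(gt)
  expect_length(bins, 10L)
  expect_equal(bins[["0-0.1"]], "a")
  expect_equal(sort(bins[["0.9-1"]]), c("b", "c"))  # 1.0 >= last edge
  # empty table -> 10 empty bins
  gt0 <- GeneTable(genes[0, ], data.frame(gene_id = character(),
                                          pos = integer(),
                                          class = character()),
                   matrix(integer(), 0, 0), character())
  expect_true(all(lengths(binGenesByDnDs(gt0)) == 0))
})

test_that("log-log slope recovers exact and planted power laws", {
  n <- c(16, 32, 64, 128, 256, 512)
  expect_equal(loglogSlope(n, 3e-4 * n^0.2)[["slope"]], 0.2,
               tolerance = 1e-10)
  expect_equal(loglogSlope(n, rep(2, 6))[["slope"]], 0)
  set.seed(31)
  for (case in 1:5) {
    b <- runif(1, 0.05, 0.5)
    y <- 1e-3 * n^b * 2^rnorm(6, 0, 0.05)
    sl <- loglogSlope(n, y)
    expect_lt(abs(sl[["slope"]] - b), 2 * sl[["stderr"]] + 0.05)
  }
  expect_warning(sl <- loglogSlope(1:3, c(1, -1, 2)), "non-positive")
  expect_true(is.na(sl[["slope"]]))
})

test_that("delta and ratio compare the largest and smallest sizes", {
  expect_equal(deltaAndRatio(c(16, 512), c(3, 3)),
               c(delta = 0, ratio = 1))
  expect_equal(deltaAndRatio(c(16, 64, 512), c(2, 3, 5)),
               c(delta = 3, ratio = 2.5))
  expect_error(deltaAndRatio(c(16, 64), c(1, 2)), "must both be present")
  expect_true(is.na(deltaAndRatio(c(16, 512), c(0, 2))[["ratio"]]))
})

test_that("correlation tests match direct computation", {
  n <- c(16, 32, 64, 128, 256, 512)
  up <- c(1, 2, 3, 4, 5, 6)
  expect_equal(correlationTests(n, up)[["kendall_tau"]], 1)
  expect_equal(correlationTests(n, rev(up))[["kendall_tau"]], -1)
  set.seed(17)
  for (case in 1:5) {
    y <- rnorm(6)
    expect_equal(correlationTests(n, y)[["kendall_tau"]],
                 bruteForceKendall(n, y), tolerance = 1e-12)
  }
  expect_warning(ct <- correlationTests(n, rep(1, 6)), "constant")
  expect_true(all(is.na(ct)))
})

test_that("single-sample group statistics follow n_seq = 2", {
  sfs <- list(nonsynonymous = SiteFrequencySpectrum(1, nSeq = 2,
                                                    nSites = 40,
                                                    siteClass = "nonsynonymous"))
  gt <- plantedGeneTable(sfs, nIndividuals = 1)
  st <- statsBySize(gt, list(`1` = sampleIds(gt)))
  nsRow <- st[st$site_class == "nonsynonymous", ]
  expect_equal(nsRow$theta_w, 1 / 40)   # a1 = 1 at n_seq = 2
  expect_equal(nsRow$S, 1)
})

test_that("pipeline statistics equal direct statistics on a planted SFS", {
  nInd <- 30
  set.seed(23)
  planted <- list(
    synonymous = randomFeasibleSFS(2 * nInd, 500, siteClass = "synonymous"),
    nonsynonymous = randomFeasibleSFS(2 * nInd, 1500,
                                      siteClass = "nonsynonymous"))
  gt <- plantedGeneTable(planted, nIndividuals = nInd)
  st <- statsBySize(gt, list(`30` = sampleIds(gt)))
  for (cl in names(planted)) {
    row <- st[st$site_class == cl, ]
    sfs <- planted[[cl]]
    expect_equal(row$S, segSites(sfs))
    expect_equal(row$singletons, unname(singletons(sfs)))
    expect_equal(row$theta_w, wattersonTheta(sfs), tolerance = 1e-12)
    expect_equal(row$pi, nucleotideDiversity(sfs), tolerance = 1e-12)
    if (segSites(sfs) > 0) {
      expect_equal(row$tajima_d, tajimaD(sfs), tolerance = 1e-12)
      expect_equal(row$fu_li_d_star, fuLiDStar(sfs), tolerance = 1e-12)
    }
  }
})

test_that("sweep output is consistent: ratio > 1 iff delta > 0", {
  gt <- syntheticGeneTable(SynthConfig(nIndividuals = 120, nGenes = 60,
                                       seed = 4))
  sw <- runSweep(gt, sizes = c(8, 16, 32, 64), nRedraws = 2, seed = 6)
  sm <- sweepSummary(sw)
  pos <- sm[sm$statistic %in% c("theta_w", "pi", "S") &
              is.finite(sm$delta) & is.finite(sm$ratio), ]
  expect_true(all((pos$ratio > 1) == (pos$delta > 0)))
  # stats table covers every redraw x size x class for the pooled bin
  st <- sweepStats(sw)
  allBin <- st[st$bin == "all", ]
  expect_equal(nrow(allBin), 2 * 4 * 2)  # redraws x sizes x classes
  expect_true(all(c("theta_w", "ni", "alpha", "nsnv_fraction")
                  %in% names(st)))
})

test_that("MK polymorphism counts are non-decreasing on nested groups", {
  gt <- syntheticGeneTable(SynthConfig(nIndividuals = 100, nGenes = 50,
                                       seed = 14))
  ids <- sampleIds(gt)
  nested <- list(`10` = ids[1:10], `40` = ids[1:40], `100` = ids)
  st <- statsBySize(gt, nested)
  syn <- st[st$site_class == "synonymous", ]
  expect_true(all(diff(syn$Pn) >= 0))
  expect_true(all(diff(syn$Ps) >= 0))
  expect_equal(length(unique(syn$Dn)), 1L)  # divergence does not move
  expect_equal(length(unique(syn$Ds)), 1L)
})
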