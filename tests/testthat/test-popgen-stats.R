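test_that("harmonic numbers match direct summation", {
  expect_equal(harmonicNumbers(2), c(a1 = 1, a2 = 1))
  expect_equal(harmonicNumbers(4)[["a1"]], 11 / 6, tolerance = 1e-12)
  expect_equal(harmonicNumbers(4)[["a2"]], 1 + 1 / 4 + 1 / 9,
               tolerance = 1e-12)
  # frozen from an independent summation script
  expect_equal(harmonicNumbers(16)[["a1"]], 3.3182289932289937,
               tolerance = 1e-12)
  expect_error(harmonicNumbers(1), "invalid sample size")
  # a1 strictly increases with n
  a1s <- vapply(2:60, function(n) harmonicNumbers(n)[["a1"]], numeric(1))
  expect_true(all(diff(a1s) > 0))
})

test_that("Watterson's theta follows S / a1 per site", {
  expect_equal(wattersonTheta(SiteFrequencySpectrum(0, 2, 1000)), 0)
  expect_equal(wattersonTheta(SiteFrequencySpectrum(20, 2, 1000)), 0.02)
  expect_equal(wattersonTheta(SiteFrequencySpectrum(c(11, 0), 4, 11)),
               (11 / (11 / 6)) / 11, tolerance = 1e-12)
  expect_error(wattersonTheta(SiteFrequencySpectrum(0, 4, 0)),
               "empty region")
})

test_that("nucleotide diversity equals the folded pairwise-difference form", {
  expect_equal(nucleotideDiversity(SiteFrequencySpectrum(c(0, 0), 4, 50)), 0)
  # two sequences differing at 1 of 100 sites
  expect_equal(nucleotideDiversity(SiteFrequencySpectrum(1, 2, 100)), 0.01)
  # explicit 4-haplotype matrix realizing counts {m=1: 2, m=2: 1}: the
  # per-locus mean pairwise difference is (2*(1*3) + 1*(2*2)) / 6 = 10/6
  hap <- rbind(c(1, 0, 0, 0),    # singleton
               c(0, 0, 0, 1),    # singleton
               c(1, 1, 0, 0))    # doubleton
  sfs <- SiteFrequencySpectrum(c(2, 1), nSeq = 4, nSites = 3)
  expect_equal(sfsCounts(sfs), as.numeric(bruteForceFoldedCounts(hap)))
  expect_equal(nucleotideDiversity(sfs), bruteForcePi(hap),
               tolerance = 1e-12)
  expect_equal(nucleotideDiversity(sfs) * 3, 10 / 6, tolerance = 1e-12)
})

test_that("pi from the SFS equals brute-force mean pairwise distance", {
  set.seed(42)
  for (case in 1:8) {
    n <- sample(c(4, 6, 10, 20), 1)
    L <- sample(20:60, 1)
    hap <- matrix(rbinom(L * n, 1, 0.3), nrow = L, ncol = n)
    sfs <- sfsFromGenotypes(hap, ploidy = 1, nSites = L)
    expect_equal(nucleotideDiversity(sfs), bruteForcePi(hap),
                 tolerance = 1e-12)
  }
})

test_that("theta and pi coincide exactly for two sequences", {
  set.seed(7)
  for (case in 1:5) {
    S <- sample(0:30, 1)
    sfs <- SiteFrequencySpectrum(S, nSeq = 2, nSites = 100)
    expect_identical(wattersonTheta(sfs), nucleotideDiversity(sfs))
  }
})

test_that("Tajima's D matches the hand-computed n = 10 case and sign rule", {
  # 5 singletons among 10 sequences over 1000 sites; expected value frozen
  # from an independent implementation of the 1989 constants
  sfs <- SiteFrequencySpectrum(c(5, 0, 0, 0, 0), 10, 1000)
  expect_equal(tajimaD(sfs), -1.7410958652071464, tolerance = 1e-12)

  # constants for n = 10, frozen from the same script
  cst <- tajimaConstants(10)
  expect_equal(cst[["e1"]], 0.019060533801591818, tolerance = 1e-12)
  expect_equal(cst[["e2"]], 0.00494892776989633, tolerance = 1e-12)

  # numerator vanishes when k == S/a1 (n = 4: one doubleton -> k = 4/3;
  # scale counts so S/a1 == k): S singletons won't do, construct k = S/a1
  # with counts {m=2: 3}: k = 3*4/6 = 2, S = 3, S/a1 = 3/(11/6) != 2;
  # use the sign property instead on random spectra
  set.seed(11)
  for (case in 1:10) {
    sfs <- randomFeasibleSFS(12, 500)
    if (segSites(sfs) == 0) next
    k <- nucleotideDiversity(sfs) * nSites(sfs)
    S <- segSites(sfs)
    expect_equal(sign(tajimaD(sfs)),
                 sign(k - S / harmonicNumbers(12)[["a1"]]))
  }

  expect_warning(d0 <- tajimaD(SiteFrequencySpectrum(0, 10, 100)),
                 "undefined")
  expect_true(is.na(d0))
  expect_error(tajimaD(SiteFrequencySpectrum(1, 2, 100)),
               "invalid sample size")
})

test_that("Fu-Li D* matches the independent constants oracle", {
  # n = 10, eta = 10, eta_s = 3; frozen from the independently written
  # constants script (corrected p.701 expressions)
  sfs <- SiteFrequencySpectrum(c(3, 4, 2, 1, 0), 10, 1000)
  expect_equal(segSites(sfs), 10)
  expect_equal(unname(singletons(sfs)), 3)
  expect_equal(fuLiDStar(sfs), 0.34365989628197235, tolerance = 1e-12)
  cst <- fuLiConstants(10)
  expect_equal(cst[["uD"]], 1.472929539814367, tolerance = 1e-12)
  expect_equal(cst[["vD"]], 0.4358006189157914, tolerance = 1e-12)

  # numerator vanishes when (n/(n-1)) eta == a_n eta_s: at n = 4,
  # a_4 = 11/6 and n/(n-1) = 4/3, so eta = 11 with eta_s = 8 gives 0
  expect_equal(fuLiDStar(SiteFrequencySpectrum(c(8, 3), 4, 100)), 0,
               tolerance = 1e-12)

  expect_warning(d0 <- fuLiDStar(SiteFrequencySpectrum(0, 10, 100)),
                 "undefined")
  expect_true(is.na(d0))

  # n = 3 folded is degenerate (every site is a singleton; both variance
  # constants vanish): signalled as NA, not returned as 0/0
  expect_warning(d3 <- fuLiDStar(SiteFrequencySpectrum(4, 3, 100)),
                 "degenerate")
  expect_true(is.na(d3))

  # denominator is well-defined above that: uD*eta + vD*eta^2 > 0
  for (n in c(4, 5, 10, 50, 200)) {
    cst <- fuLiConstants(n)
    eta <- 1:50
    expect_true(all(cst[["uD"]] * eta + cst[["vD"]] * eta^2 > 0))
  }
})

test_that("sfsFromGenotypes tallies minor alleles correctly", {
  expect_equal(segSites(sfsFromGenotypes(matrix(0L, 5, 4), ploidy = 2)), 0)

  # one diploid sample, one het site of 10 surveyed sites
  g <- matrix(c(1L, rep(0L, 9)), ncol = 1)
  sfs <- sfsFromGenotypes(g, ploidy = 2, nSites = 10)
  expect_equal(nSeq(sfs), 2L)
  expect_equal(sfsCounts(sfs), 1)
  expect_equal(nSites(sfs), 10)

  set.seed(3)
  hap <- matrix(rbinom(20 * 50, 1, 0.4), nrow = 20, ncol = 50)
  sfs <- sfsFromGenotypes(hap, ploidy = 1)
  expect_equal(sfsCounts(sfs), as.numeric(bruteForceFoldedCounts(hap)))

  # per-site class mask splits into one spectrum per class
  mask <- rep(c("synonymous", "nonsynonymous"), each = 10)
  byClass <- sfsFromGenotypes(hap, ploidy = 1, siteClass = mask)
  expect_named(byClass, c("synonymous", "nonsynonymous"))
  expect_equal(sfsCounts(byClass$synonymous),
               as.numeric(bruteForceFoldedCounts(hap[1:10, ])))
  expect_equal(nSites(byClass$nonsynonymous), 10)

  expect_error(sfsFromGenotypes(matrix(3L, 2, 2), ploidy = 2),
               "invalid input")
  expect_error(sfsFromGenotypes(matrix(NA_integer_, 2, 2), ploidy = 2),
               "missing")
})

test_that("spectrum validity invariants are enforced", {
  expect_error(SiteFrequencySpectrum(c(1, 2, 3), nSeq = 4, nSites = 100),
               "floor")
  expect_error(SiteFrequencySpectrum(60, nSeq = 2, nSites = 50),
               "exceed")
  expect_error(SiteFrequencySpectrum(1, nSeq = 2, nSites = 10,
                                     siteClass = "bogus"),
               "siteClass")
})
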