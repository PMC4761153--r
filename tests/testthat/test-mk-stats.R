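test_that("MK aggregation is element-wise summation", {
  expect_equal(mkCounts(aggregateMK(list())),
               c(Pn = 0, Ps = 0, Dn = 0, Ds = 0))
  agg <- aggregateMK(list(MKCounts(1, 2, 3, 4), MKCounts(1, 0, 0, 1)))
  expect_equal(mkCounts(agg), c(Pn = 2, Ps = 2, Dn = 3, Ds = 5))

  set.seed(21)
  recs <- lapply(1:100, function(i)
    MKCounts(rpois(1, 3), rpois(1, 3), rpois(1, 2), rpois(1, 2)))
  tot <- rep(0, 4)
  for (r in recs) tot <- tot + mkCounts(r)  # loop oracle
  expect_equal(unname(mkCounts(aggregateMK(recs))), unname(tot))
})

test_that("Neutrality Index and alpha follow their ratio definitions", {
  expect_equal(neutralityIndex(MKCounts(2, 2, 1, 1)), 1)
  expect_equal(neutralityIndex(MKCounts(10, 5, 4, 4)), 2)
  expect_equal(neutralityIndex(MKCounts(0, 5, 4, 4)), 0)
  expect_warning(ni <- neutralityIndex(MKCounts(1, 0, 1, 1)), "undefined")
  expect_true(is.na(ni))
  expect_warning(ni <- neutralityIndex(MKCounts(1, 1, 0, 1)), "undefined")
  expect_true(is.na(ni))

  expect_equal(alphaAdaptive(MKCounts(10, 10, 10, 10)), 0)
  expect_equal(alphaAdaptive(MKCounts(10, 5, 4, 4)), -1)
  expect_equal(alphaAdaptive(MKCounts(0, 5, 4, 4)), 1)
  expect_warning(a <- alphaAdaptive(MKCounts(1, 0, 1, 1)), "undefined")
  expect_true(is.na(a))
})

test_that("alpha equals 1 - NI and both are scale-invariant", {
  set.seed(5)
  for (case in 1:200) {
    mk <- MKCounts(rpois(1, 5) + 1, rpois(1, 5) + 1,
                   rpois(1, 5) + 1, rpois(1, 5) + 1)
    expect_equal(alphaAdaptive(mk), 1 - neutralityIndex(mk),
                 tolerance = 1e-12)
    cc <- runif(1, 0.5, 10)
    mk2 <- MKCounts(cc * mk@Pn, cc * mk@Ps, cc * mk@Dn, cc * mk@Ds)
    expect_equal(neutralityIndex(mk2), neutralityIndex(mk),
                 tolerance = 1e-12)
    expect_equal(alphaAdaptive(mk2), alphaAdaptive(mk), tolerance = 1e-12)
  }
})
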