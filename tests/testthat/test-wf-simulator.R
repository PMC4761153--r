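# Fast simulator checks; the heavier distributional properties live in
# test-acceptance.R.

smallConstant <- function(Ne = 300, dur = 6000)
  DemographySchedule(duration = dur, startSize = Ne)

test_that("no mutation means no variation", {
  cfg <- SimulationConfig(seqLength = 1000, mu = 0,
                          demography = smallConstant(100, 500),
                          sampleSizes = c(4L, 16L), nReplicates = 5,
                          seed = 3)
  reps <- runSimulation(cfg)
  tab <- summariseReplicates(reps)
  expect_true(all(tab$S == 0))
})

test_that("runs are reproducible from the seed", {
  cfg <- SimulationConfig(seqLength = 2000, mu = 5e-7,
                          demography = smallConstant(200, 2000),
                          sampleSizes = c(8L, 32L), nReplicates = 10,
                          seed = 42)
  t1 <- summariseReplicates(runSimulation(cfg))
  t2 <- summariseReplicates(runSimulation(cfg))
  expect_identical(t1, t2)
})

test_that("rescaling preserves scaled parameters and rejects bad lambda", {
  cfg <- SimulationConfig(nReplicates = 2, seed = 1,
                          demography = demographyExponential())
  expect_identical(rescaleConfig(cfg, 1), cfg)
  c100 <- rescaleConfig(cfg, 100)
  expect_equal(c100@mu, cfg@mu * 100)
  expect_equal(c100@demography@phases$endSize,
               cfg@demography@phases$endSize / 100)
  expect_equal(c100@demography@phases$duration,
               cfg@demography@phases$duration / 100)
  # theta-preserving: neutral expectation invariant under rescaling
  e0 <- expectedThetaNeutral(16, cfg@demography, cfg@mu, 5000)
  e50 <- with(list(cc = rescaleConfig(cfg, 50)),
              expectedThetaNeutral(16, cc@demography, cc@mu, 5000))
  e100 <- expectedThetaNeutral(16, c100@demography, c100@mu, 5000)
  expect_equal(e50 / e0, 1, tolerance = 1e-6)
  expect_equal(e100 / e0, 1, tolerance = 1e-6)
  # 512,210 / 10,000 leaves fewer than 256 individuals for 512 haplotypes
  expect_error(rescaleConfig(cfg, 10000), "config error")
  expect_error(rescaleConfig(cfg, 0.5), "config error")
})

test_that("sample sizes beyond the population are rejected", {
  expect_error(
    SimulationConfig(demography = smallConstant(100, 500),
                     sampleSizes = c(16L, 512L), nReplicates = 2, seed = 1),
    "exceeds the final population")
})

test_that("coalescent expectation reduces to 4 Ne mu L at constant size", {
  d <- smallConstant(Ne = 500, dur = 1000)
  for (n in c(2, 16, 100))
    expect_equal(expectedThetaNeutral(n, d, mu = 1e-6, L = 5000),
                 4 * 500 * 1e-6 * 5000, tolerance = 1e-3)
})

test_that("coalescent integrator agrees with an independent Monte Carlo", {
  dem <- rescaleConfig(SimulationConfig(nReplicates = 1, seed = 1,
                                        demography = demographyExponential()),
                       100)
  for (n in c(16, 64)) {
    ode <- expectedThetaNeutral(n, dem@demography, dem@mu, 5000)
    mc <- mcCoalescentTheta(n, dem@demography, dem@mu, 5000, nRep = 4000,
                            seed = 9)
    expect_lt(abs(ode - mc$theta), 3 * mc$se)
  }
})

test_that("neutral constant-size theta matches 4 Ne mu within Monte Carlo error", {
  # rescaled-equivalent of Ne = 10,000, mu = 1e-8: theta/site = 4e-4
  cfg <- SimulationConfig(demography = smallConstant(Ne = 250, dur = 5000),
                          mu = 2e-7, sampleSizes = c(8L, 64L, 400L),
                          nReplicates = 150, seed = 12)
  m <- meanThetaBySize(runSimulation(cfg), "neutral")
  for (i in seq_len(nrow(m)))
    expect_lt(abs(m$theta_w[i] - 4 * 250 * 2e-7), 3 * m$theta_se[i])
})

test_that("stronger purifying selection removes more variation", {
  base <- function(gamma, seed)
    rescaleConfig(SimulationConfig(
      demography = demographyConstant(), seed = seed, nReplicates = 60,
      sampleSizes = c(16L, 128L),
      dfe = DFEConfig(shape = 0.206, meanGamma = gamma,
                      neutralFraction = 0)), 30)
  mWeak <- meanThetaBySize(runSimulation(base(2, 5)), "constrained")
  mStrong <- meanThetaBySize(runSimulation(base(2000, 5)), "constrained")
  expect_true(all(mStrong$theta_w < mWeak$theta_w))
})

test_that("mixed neutral fraction yields both site classes", {
  cfg <- SimulationConfig(seqLength = 1000,
                          demography = smallConstant(150, 2000), mu = 4e-7,
                          sampleSizes = c(16L),
                          dfe = DFEConfig(meanGamma = 50,
                                          neutralFraction = 0.5),
                          nReplicates = 20, seed = 8)
  tab <- summariseReplicates(runSimulation(cfg))
  expect_setequal(unique(tab$site_class), c("neutral", "constrained"))
  expect_true(all(tab$n_sites == 500))
})

test_that("constant-size selected spectra match the Poisson Random Field
           expectation", {
  # equilibrium population of 300 diploids; sample sizes stay small relative
  # to 2N so the PRF's idealized sampling applies
  N <- 300; mu <- 3e-7; L <- 5000
  cfg <- SimulationConfig(seqLength = L, baseNe = N, mu = mu,
                          demography = DemographySchedule(duration = 8000,
                                                          startSize = N),
                          sampleSizes = c(8L, 16L, 32L, 64L),
                          dfe = DFEConfig(shape = 0.206, meanGamma = 2000,
                                          neutralFraction = 0),
                          nReplicates = 250, seed = 29)
  m <- meanThetaBySize(runSimulation(cfg), "constrained")
  for (i in seq_len(nrow(m))) {
    ex <- prfExpectedTheta(m$sample_size[i], 2000, 0.206,
                           thetaSite = 4 * N * mu, L = L)
    expect_lt(abs(m$theta_w[i] - ex), 3 * m$theta_se[i])
  }

  # the same theory bounds the attainable constant-size sample-size response
  # for the study's DFE: the 16..512 log-log slope is ~0.11, far below the
  # responses explosive growth produces
  th <- vapply(c(16, 32, 64, 128, 256, 512), prfExpectedTheta, numeric(1),
               gammaMean = 2000, shape = 0.206, thetaSite = 4e-4, L = 5000)
  sl <- loglogSlope(c(16, 32, 64, 128, 256, 512), th)[["slope"]]
  expect_gt(sl, 0.08)
  expect_lt(sl, 0.15)
})
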