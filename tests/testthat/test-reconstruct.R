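# The reconstruction engine: stage-by-stage checks and full-pipeline
# behavior on synthetic mixtures.

test_that("high-q scaling is exact and linear", {
  p <- guinierProfile(rg = 27, i0 = 0.1, noise_rel = 0.01, seed = 2,
                      concentration = 2)
  expect_equal(highqMonomerFirst(p, 1), p)
  h <- highqMonomerFirst(p, 0.8)
  expect_equal(intensities(h), 0.8 * intensities(p))
  expect_equal(sigmas(h), 0.8 * sigmas(p))
  expect_equal(sampleConcentration(h), 1.6)
  expect_error(highqMonomerFirst(p, 0), "r1")
})

test_that("monomer forward intensity follows the mass-weighted share", {
  solv <- testSolvent()
  d1 <- speciesDistribution(4.31, 1, 1.3)
  d1 <- assignAssociationNumbers(d1, solv)
  expect_equal(forwardIntensityMonomer(0.1, d1)$value, 0.1)
  d2 <- speciesDistribution(c(4.31, 6.84), c(0.8, 0.2), 1.3,
                            molar_mass = c(66500, 133000),
                            association_number = c(1L, 2L))
  fw <- forwardIntensityMonomer(0.12, d2, i0_sd = 0.003)
  expect_equal(fw$value, 0.12 * 0.8 / 1.2, tolerance = 1e-12)
  expect_equal(fw$sd, 0.003 * 0.8 / 1.2, tolerance = 1e-12)
  dmiss <- speciesDistribution(c(4.31, 6.84), c(0.8, 0.2), 1.3)
  expect_error(forwardIntensityMonomer(0.12, dmiss), "missing")
})

test_that("forward mixture inversion agrees with the forward-share formula", {
  # q -> 0 limit of the improved inversion, r_1 I(0) / S(0), must equal the
  # mass-share forward intensity exactly when M_j = j M_1
  fr <- c(0.8, 0.14, 0.06)
  d <- speciesDistribution(c(4.3, 6.8, 8.9), fr, 1.3,
                           molar_mass = 66500 * 1:3,
                           association_number = 1:3)
  S0 <- sum(fr * (1:3))
  I0 <- 0.117
  expect_equal(fr[1] * I0 / S0, forwardIntensityMonomer(I0, d)$value,
               tolerance = 1e-10)
})

test_that("Guinier extrapolation recovers exact and noisy parameters", {
  p <- guinierProfile(rg = 27, i0 = 0.1)
  gf <- extrapolateForward(p)
  expect_equal(gf$i0, 0.1, tolerance = 1e-8)
  expect_equal(gf$rg, 27, tolerance = 1e-8)
  pn <- guinierProfile(rg = 27, i0 = 0.1, q = seq(0.005, 0.1,
                                                  length.out = 50),
                       noise_rel = 0.01, seed = 4)
  gfn <- extrapolateForward(pn)
  expect_lt(abs(gfn$i0 - 0.1), 2 * gfn$i0_sd + 1e-6)
  # an aggregated mixture biases the apparent radius upward
  ds <- makeDataset(syntheticScenario(seed = 5))
  expect_gt(extrapolateForward(ds$profile)$rg, ds$truth$rg1)
})

test_that("Guinier connection is exact on self-consistent input", {
  p <- guinierProfile(rg = 27, i0 = 0.1,
                      q = exp(seq(log(0.005), log(0.2), length.out = 80)))
  con <- guinierConnect(p, i1_zero = 0.1)
  expect_equal(con$rg1, 27, tolerance = 1e-6)
  expect_equal(con$metric, 0, tolerance = 1e-8)
  expect_equal(intensities(con$profile), intensities(p), tolerance = 1e-9)
})

test_that("Guinier connection recovers a sphere monomer radius", {
  R <- 35  # sphere radius, Rg = sqrt(3/5) R = 27.11
  q <- exp(seq(log(0.005), log(0.25), length.out = 100))
  p <- scatteringProfile(q, 0.1 * sphereIntensity(q, R),
                         rep(0, length(q)))
  con <- guinierConnect(p, i1_zero = 0.1)
  expect_equal(con$rg1, sqrt(3 / 5) * R, tolerance = 0.01)
})

test_that("irreparably inconsistent inputs are refused", {
  p <- guinierProfile(rg = 27, i0 = 0.1,
                      q = exp(seq(log(0.005), log(0.2), length.out = 80)))
  # forward intensity 3x too large: no Guinier curve can join smoothly
  expect_error(guinierConnect(p, i1_zero = 0.3), "inconsistent")
})

test_that("mixture factor has the exact limits", {
  sh <- subunitShape(27.1, 1.3)
  q <- c(1e-5, exp(seq(log(0.008), log(0.25), length.out = 60)), 100 / 54.2)
  q <- sort(q)
  model <- aggregateModel(q, sh, 1:2)
  d1 <- speciesDistribution(4.31, 1, 1.3, molar_mass = 66500,
                            association_number = 1L)
  expect_equal(mixtureFactor(q, d1, model), rep(1, length(q)))
  d2 <- speciesDistribution(c(4.31, 6.84), c(0.8, 0.2), 1.3,
                            molar_mass = c(66500, 133000),
                            association_number = c(1L, 2L))
  S <- mixtureFactor(q, d2, model)
  expect_equal(S[1], 1.2, tolerance = 1e-6)          # S(0) = sum r_j j
  expect_lt(abs(S[length(q)] - 1), 0.01)             # S -> 1 at q D = 100
})

test_that("monomer-only input passes through both pipelines unchanged", {
  scen <- syntheticScenario(fractions = c("1" = 1), seed = 9,
                            noise_level = 0.003)
  ds <- makeDataset(scen)
  f <- firstAUCSAS(ds$profile, ds$distribution, testSolvent())
  im <- improvedAUCSAS(ds$profile, ds$distribution, testSolvent())
  expect_equal(rg1(f), 27.1, tolerance = 0.02)
  expect_equal(rg1(im), rg1(f), tolerance = 0.005)
  expect_lte(im@iterations, 2)
  # above the joint the reconstructed profile is the input (times r_1 = 1)
  keep <- qGrid(ds$profile) >= qConnect(f)
  expect_equal(intensities(monomerProfile(f))[keep],
               intensities(ds$profile)[keep], tolerance = 1e-9)
})

test_that("improved and first high-q branches agree where S -> 1", {
  ds <- makeDataset(syntheticScenario(seed = 6))
  dist <- assignAssociationNumbers(ds$distribution, testSolvent())
  sp <- speciesTable(dist)
  q <- qGrid(ds$profile)
  model <- aggregateModel(q, subunitShape(27.1, 1.3),
                          sp$association_number)
  S <- mixtureFactor(q, dist, model)
  # beyond q Rg1 = 3 the mixture factor deviates by at most a few per cent
  # (second sinc lobe); at very high q it is 1 to well below a per cent
  hi <- q * 27.1 > 3
  expect_lt(max(abs(S[hi] - 1)), 0.05)
  expect_lt(max(abs(S[q * 2 * 27.1 > 50] - 1)), 0.01)
})

test_that("the improved method repairs the first method monotonically", {
  # mean absolute radius error over seeds, per aggregate fraction: the
  # improved estimate is never farther from the truth than the first one
  for (ra in c(0.10, 0.15, 0.20)) {
    ef <- ei <- numeric(5)
    for (k in 1:5) {
      scen <- syntheticScenario(fractions = c("1" = 1 - ra, "2" = 0.7 * ra,
                                              "3" = 0.3 * ra),
                                seed = 20 + k)
      ds <- makeDataset(scen)
      f <- suppressWarnings(firstAUCSAS(ds$profile, ds$distribution,
                                        testSolvent()))
      im <- suppressWarnings(improvedAUCSAS(ds$profile, ds$distribution,
                                            testSolvent()))
      ef[k] <- abs(rg1(f) - 27.1); ei[k] <- abs(rg1(im) - 27.1)
    }
    expect_lte(mean(ei), mean(ef))
  }
})

test_that("output errors scale linearly with input errors", {
  ds <- makeDataset(syntheticScenario(seed = 12, noise_level = 0))
  prof <- ds$profile
  # impose a deterministic error band, then double it
  prof@sigma <- 0.01 * pmax(prof@intensity, max(prof@intensity) * 1e-4)
  r2 <- prof; r2@sigma <- 2 * prof@sigma
  a <- suppressWarnings(firstAUCSAS(prof, ds$distribution, testSolvent()))
  b <- suppressWarnings(firstAUCSAS(r2, ds$distribution, testSolvent()))
  hiq <- qGrid(monomerProfile(a)) >= max(qConnect(a), qConnect(b))
  expect_equal(sigmas(monomerProfile(b))[hiq],
               2 * sigmas(monomerProfile(a))[hiq], tolerance = 1e-9)
  expect_equal(b@i1_zero_sd, 2 * a@i1_zero_sd, tolerance = 0.05)
})

test_that("reconstruction demands a known concentration", {
  ds <- makeDataset(syntheticScenario(seed = 1))
  p <- ds$profile
  p@concentration <- NA_real_
  expect_error(firstAUCSAS(p, ds$distribution, testSolvent()),
               "concentration")
})
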