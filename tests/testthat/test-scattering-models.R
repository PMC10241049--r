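# Analytic scattering models against independent oracles.

test_that("ellipsoid amplitude has the right limits and sphere zero", {
  sh <- subunitShape(rg = 27, p = 2)
  expect_equal(ellipsoidAmplitude(0, 0.3, sh), 1)
  # p = 1: independent of orientation, equal to the sphere amplitude
  sp <- subunitShape(rg = 27, p = 1)
  q <- seq(0, 0.3, by = 0.01)
  a1 <- ellipsoidAmplitude(q, 0.1, sp)
  a2 <- ellipsoidAmplitude(q, 0.9, sp)
  expect_equal(a1, a2, tolerance = 1e-12)
  r <- sp@semi_axis
  u <- q * r
  expect_equal(a1, ifelse(u == 0, 1, 3 * (sin(u) - u * cos(u)) / u^3),
               tolerance = 1e-12)
  # first zero of the sphere amplitude at u = 4.493409 (root of tan u = u)
  z <- uniroot(function(qq) ellipsoidAmplitude(qq, 0, sp),
               c(4 / r, 4.8 / r), tol = 1e-12)$root
  expect_equal(z * r, 4.493409, tolerance = 1e-5)
})

test_that("orientational moments match adaptive quadrature", {
  sh <- subunitShape(rg = 30, p = 3)
  q1 <- 1 / sh@semi_axis   # q r = 1
  m <- orientationalMoments(c(0, q1), sh)
  expect_equal(m$meanF[1], 1, tolerance = 1e-10)
  expect_equal(m$meanF2[1], 1, tolerance = 1e-10)
  oracleF <- integrate(function(ca) ellipsoidAmplitude(rep(q1, length(ca)),
                                                       ca, sh),
                       0, 1, rel.tol = 1e-12)$value
  oracleF2 <- integrate(function(ca) ellipsoidAmplitude(rep(q1, length(ca)),
                                                        ca, sh)^2,
                        0, 1, rel.tol = 1e-12)$value
  expect_equal(m$meanF[2], oracleF, tolerance = 1e-8)
  expect_equal(m$meanF2[2], oracleF2, tolerance = 1e-8)
  # a sphere has no anisotropy: the two moments coincide squared
  spm <- orientationalMoments(seq(0, 0.3, 0.01), subunitShape(27, 1))
  expect_equal(spm$meanF^2, spm$meanF2, tolerance = 1e-12)
})

test_that("beta factor is 1 for spheres and matches a Monte Carlo average", {
  q <- seq(0, 0.4, by = 0.02)
  expect_equal(betaFactor(q, subunitShape(27, 1)), rep(1, length(q)),
               tolerance = 1e-12)
  sh <- subunitShape(rg = 25, p = 2)
  expect_equal(betaFactor(0, sh), 1, tolerance = 1e-8)
  expect_true(all(betaFactor(q, sh) > 0 & betaFactor(q, sh) <= 1))
  # Monte Carlo orientational average over 1e6 directions at q r = 2
  q2 <- 2 / sh@semi_axis
  ca <- aucsas:::withSeed(99, runif(1e6))
  Fv <- ellipsoidAmplitude(rep(q2, 1e6), ca, sh)
  beta_mc <- mean(Fv)^2 / mean(Fv^2)
  expect_equal(betaFactor(q2, sh), beta_mc, tolerance = 1e-3)
})

test_that("Debye structure factor reproduces the direct double sum", {
  # tetramer with explicit coordinates
  xyz <- rbind(c(0, 0, 0), c(50, 0, 0), c(30, 40, 0), c(10, 10, 60))
  dm <- as.matrix(dist(xyz))
  q <- seq(0, 0.5, by = 0.01)
  direct <- sapply(q, function(qi) {
    acc <- 0
    for (k in 1:4) for (l in 1:4) {
      d <- sqrt(sum((xyz[k, ] - xyz[l, ])^2))
      acc <- acc + if (qi * d == 0) 1 else sin(qi * d) / (qi * d)
    }
    acc / 4
  })
  expect_equal(debyeStructureFactor(q, dm), direct, tolerance = 1e-12)
  expect_equal(debyeStructureFactor(0, dm), 4)
  # dimer at q D = pi: sinc vanishes
  dim2 <- matrix(c(0, 60, 60, 0), 2, 2)
  expect_equal(debyeStructureFactor(pi / 60, dim2), 1, tolerance = 1e-12)
  expect_error(debyeStructureFactor(0.1, matrix(c(0, 1, 2, 0), 2, 2)),
               "symmetric")
})

test_that("random-flight factor has exact small cases and limits", {
  q <- seq(0, 0.5, by = 0.01)
  expect_equal(randomFlightStructureFactor(q, 1, 54), rep(1, length(q)))
  expect_equal(randomFlightStructureFactor(0, 3, 54), 3, tolerance = 1e-12)
  # j = 2 at the point where sinc(qD) = 0.5
  qd_half <- uniroot(function(x) sin(x) / x - 0.5, c(1, 3), tol = 1e-12)$root
  expect_equal(randomFlightStructureFactor(qd_half / 54, 2, 54), 1.5,
               tolerance = 1e-9)
  # high-q decay to 1
  expect_lt(abs(randomFlightStructureFactor(200 / 54, 4, 54) - 1), 0.01)
})

test_that("random-flight factor equals the chain-ensemble Debye average", {
  # defining identity at j = 4, qD = 1, checked by direct simulation
  D <- 54; j <- 4; qv <- 1 / D
  n <- 2e4
  tvals <- aucsas:::withSeed(7, {
    vapply(seq_len(n), function(i) {
      ch <- randomFlightChain(j, D)
      debyeStructureFactor(qv, as.matrix(dist(ch)))
    }, numeric(1))
  })
  se <- sd(tvals) / sqrt(n)
  expect_lt(abs(mean(tvals) - randomFlightStructureFactor(qv, j, D)),
            3 * se)
})

test_that("aggregate profiles obey the monomer, forward and grid rules", {
  sh <- subunitShape(27.1, 1.3)
  q <- exp(seq(log(0.008), log(0.25), length.out = 60))
  model <- aggregateModel(q, sh, j = 1:3)
  expect_equal(model@neighbor_distance, 2 * 27.1)
  i1 <- 0.046 * orientationalMoments(q, sh)$meanF2
  expect_equal(aggregateProfile(i1, 1, model), i1)
  i3 <- aggregateProfile(i1, 3, model)
  # forward limit: at q -> 0 the j-mer scatters j times the monomer
  q0 <- c(1e-9, q)
  m0 <- aggregateModel(q0, sh, 3)
  expect_equal(1 + m0@beta[1] * (m0@t_factors[["3"]][1] - 1), 3,
               tolerance = 1e-9)
  # high-q identity: i_j approaches i_1 inside the sinc envelope 2/(qD),
  # so the pure-aggregate deviation dies off as the interference decays
  hi <- q * 27.1 > 3
  expect_true(all(abs(i3[hi] / i1[hi] - 1) <= 2 / (q[hi] * 2 * 27.1)))
  expect_error(aggregateProfile(i1[-1], 2, model), "length")
})

test_that("semi-axis from rg inverts the ellipsoid gyration relation", {
  expect_equal(semiAxisFromRg(27, 1), 27 * sqrt(5 / 3), tolerance = 1e-12)
  expect_equal(semiAxisFromRg(27.3, 2), 24.92138, tolerance = 1e-6)
  for (p in c(0.5, 1, 1.7, 4)) {
    r <- semiAxisFromRg(20, p)
    expect_equal(sqrt(r^2 * (2 + p^2) / 5), 20, tolerance = 1e-12)
  }
})

test_that("coordinate gyration radius matches analytic and real references", {
  # two equal atoms 2 A apart
  expect_equal(rgFromAtomicCoordinates(
    data.frame(element = c("C", "C"), x = c(-1, 1), y = 0, z = 0)), 1)
  # uniform sphere point cloud tends to sqrt(3/5) R
  R <- 10
  pts <- aucsas:::withSeed(5, {
    m <- matrix(runif(3 * 60000, -R, R), ncol = 3)
    m[rowSums(m^2) <= R^2, ]
  })
  cloud <- data.frame(element = "C", x = pts[, 1], y = pts[, 2],
                      z = pts[, 3])
  expect_equal(rgFromAtomicCoordinates(cloud), sqrt(3 / 5) * R,
               tolerance = 0.01)
  expect_error(rgFromAtomicCoordinates(
    data.frame(element = c("C", "Xx"), x = c(0, 1), y = 0, z = 0)),
    "unknown element")
  # real structure: hen egg-white lysozyme 1DPX (ships with bio3d);
  # 13.847867 A frozen from an independent electron-count computation
  # (gemmi; protein heavy atoms, first alternate conformers)
  pdb <- system.file("examples", "1dpx.pdb", package = "bio3d")
  atoms <- readAtoms(pdb)
  expect_equal(nrow(atoms), 998)
  expect_equal(rgFromAtomicCoordinates(atoms), 13.847867, tolerance = 1e-5)
})

test_that("aggregate model validity rejects inconsistent factors", {
  sh <- subunitShape(27, 1.3)
  q <- seq(0.01, 0.2, length.out = 20)
  m <- aggregateModel(q, sh, 1:2)
  expect_true(validObject(m))
  bad <- m
  bad@beta <- rep(1.5, length(q))
  expect_error(validObject(bad), "beta")
})
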