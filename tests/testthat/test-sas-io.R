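# Profile and species-table I/O: round trips, fallbacks, validation.

test_that("profile write/read round-trips to 6 significant digits", {
  p <- guinierProfile(rg = 27, i0 = 0.12, noise_rel = 0.01, seed = 11,
                      concentration = 2.0)
  f <- withr::local_tempfile(fileext = ".dat")
  writeProfile(p, f)
  p2 <- readProfile(f, concentration = 2.0)
  expect_equal(qGrid(p2), qGrid(p), tolerance = 1e-6)
  expect_equal(intensities(p2), intensities(p), tolerance = 1e-6)
  expect_equal(sigmas(p2), sigmas(p), tolerance = 1e-6)
  expect_length(qGrid(p2), 100)

  # normalized profiles record their state in the header
  pn <- asNormalized(p)
  writeProfile(pn, f)
  expect_true(any(grepl("normalized = true", readLines(f))))
})

test_that("missing sigma column is synthesized by the documented rule", {
  q <- seq(0.01, 0.2, length.out = 30)
  I <- 0.1 * exp(-q^2 * 27^2 / 3)
  f <- withr::local_tempfile(fileext = ".dat")
  writeLines(sprintf("%.8g %.8g", q, I), f)
  p <- readProfile(f)
  expect_equal(sigmas(p), pmax(0.01 * I, 1e-3 * min(I[I > 0])),
               tolerance = 1e-6)
})

test_that("bad rows are dropped and duplicates merged", {
  q <- seq(0.01, 0.2, length.out = 30)
  I <- 0.1 * exp(-q^2 * 400 / 3)
  f <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("# comment", "; also a comment",
               "0 0.5 0.01",           # q = 0: dropped
               sprintf("%.8g %.8g %.8g", q, I, 0.01 * I),
               sprintf("%.8g %.8g %.8g", q[5], I[5] * 2, 0.01 * I[5])), f)
  expect_message(p <- readProfile(f), "dropped")
  expect_length(qGrid(p), 30)
  expect_false(any(qGrid(p) == 0))
  # merged point: error-weighted mean of I[5] and 2 I[5]
  w <- 1 / (0.01 * I[5])^2
  expect_equal(intensities(p)[5],
               (I[5] * w + 2 * I[5] * w) / (2 * w), tolerance = 1e-6)
})

test_that("comma-delimited input and nanometre q scaling are handled", {
  q_nm <- seq(0.1, 2, length.out = 40)  # nm^-1
  I <- exp(-q_nm^2)
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# csv dialect", sprintf("%g,%g,%g", q_nm, I, 0.01 * I)), f)
  p <- readProfile(f, q_scale = 0.1)
  expect_equal(max(qGrid(p)), 0.2, tolerance = 1e-9)
})

test_that("degenerate profiles are rejected", {
  f <- withr::local_tempfile(fileext = ".dat")
  writeLines(sprintf("%g %g", 1:5 / 100, exp(-(1:5))), f)
  expect_error(readProfile(f), "fewer than 10")
  empty <- new("ScatteringProfile", q = numeric(0), intensity = numeric(0),
               sigma = numeric(0), concentration = NA_real_,
               normalized = FALSE)
  expect_error(writeProfile(empty, f), "empty")
})

test_that("species tables round-trip and enforce fraction normalization", {
  d <- speciesDistribution(s20w = c(4.3, 6.5), weight_fraction = c(0.8, 0.2),
                           friction_ratio = 1.3)
  expect_equal(speciesTable(d)$weight_fraction[1], 0.8)
  f <- withr::local_tempfile(fileext = ".csv")
  writeSpeciesTable(d, f)
  d2 <- readSpeciesTable(f)
  expect_equal(frictionRatio(d2), 1.3)
  expect_equal(speciesTable(d2)$weight_fraction,
               speciesTable(d)$weight_fraction, tolerance = 1e-9)

  # slightly-off fractions renormalize with a warning; far-off is an error
  expect_warning(
    d3 <- speciesDistribution(c(4.3, 6.5), c(0.7997, 0.1998), 1.3),
    "renormaliz")
  expect_equal(sum(speciesTable(d3)$weight_fraction), 1, tolerance = 1e-12)
  expect_error(speciesDistribution(c(4.3, 6.5), c(0.6, 0.2), 1.3),
               "far from 1")

  # missing pragma
  writeLines(c("s20w,weight_fraction", "4.3,0.8", "6.5,0.2"), f)
  expect_error(readSpeciesTable(f), "friction_ratio")
})

test_that("monomer-first ordering is imposed on load", {
  d <- speciesDistribution(s20w = c(6.5, 4.3), weight_fraction = c(0.2, 0.8),
                           friction_ratio = 1.3)
  expect_equal(speciesTable(d)$s20w, c(4.3, 6.5))
  expect_equal(speciesTable(d)$weight_fraction, c(0.8, 0.2))
})

test_that("reports carry the full schema and round-trip Rg1 exactly", {
  ds <- makeDataset(syntheticScenario(seed = 3, noise_level = 0.004))
  res <- suppressWarnings(improvedAUCSAS(ds$profile, ds$distribution,
                                         testSolvent()))
  f <- withr::local_tempfile(fileext = ".json")
  writeReport(res, f, seed = 3)
  rep <- readReport(f)
  for (key in c("method", "rg1_A", "rg1_sd_A", "i1_zero", "i1_zero_sd",
                "q_connect", "iterations", "software", "seed"))
    expect_true(key %in% names(rep))
  expect_equal(rep$rg1_A, rg1(res), tolerance = 1e-12)
  expect_identical(rep$method, "improved")
  # without a P(r) object the dmax keys are simply absent, schema still valid
  expect_false("dmax_A" %in% names(rep))
})
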