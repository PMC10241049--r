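# Shared fixture builders: everything is generated in code.

# Ideal Guinier profile I = i0 * exp(-q^2 rg^2 / 3) with optional relative
# Gaussian noise.
guinierProfile <- function(rg = 27, i0 = 0.1,
                           q = seq(0.01, 0.2, length.out = 100),
                           noise_rel = 0, concentration = NA_real_,
                           seed = NULL) {
  I <- i0 * exp(-q^2 * rg^2 / 3)
  s <- pmax(noise_rel * I, 1e-12)
  if (noise_rel > 0) {
    I <- aucsas:::withSeed(seed, I + rnorm(length(q), 0, s))
  }
  scatteringProfile(q, I, s, concentration = concentration)
}

# Orientation-averaged sphere intensity of radius R (unit forward value).
sphereIntensity <- function(q, R) {
  u <- q * R
  amp <- ifelse(u < 1e-6, 1, 3 * (sin(u) - u * cos(u)) / u^3)
  amp^2
}

# Default BSA-like solvent used throughout the tests.
testSolvent <- function() solventConditions(vbar = 0.735, eta = 0.01002,
                                            rho = 0.99823)
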