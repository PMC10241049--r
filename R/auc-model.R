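# Hydrodynamic conversions: sedimentation coefficient -> molar mass, and
# frictional ratio -> subunit axial ratio.

#' Molar mass from the sedimentation coefficient and frictional ratio
#'
#' Combines the Svedberg relation with the Stokes radius of a sphere of
#' equal anhydrous volume scaled by the frictional ratio:
#' \deqn{M = \left[\frac{s\,(f/f_0)\,6\pi\eta\,(3\bar v/4\pi)^{1/3}
#'   N_A^{2/3}}{1-\bar v\rho}\right]^{3/2}}
#' with s in CGS seconds (input in Svedberg, 1 S = 1e-13 s), eta in poise,
#' vbar in cm^3/g and rho in g/cm^3.  Monotone increasing in both `s20w`
#' and `friction_ratio`; homogeneous of degree 3/2 in each.
#'
#' @param s20w sedimentation coefficient, Svedberg (may be a vector).
#' @param friction_ratio frictional ratio f/f0, >= 1.
#' @param solvent a [SolventConditions-class].
#' @return molar mass, g/mol.
#' @examples
#' molarMassFromSedimentation(4.31, 1.30, solventConditions())
#' @export
molarMassFromSedimentation <- function(s20w, friction_ratio,
                                       solvent = solventConditions()) {
  stopifnot(is(solvent, "SolventConditions"))
  if (any(s20w <= 0)) stop("s20w must be positive")
  if (any(friction_ratio < 1)) stop("friction_ratio must be >= 1")
  buoy <- 1 - solvent@vbar * solvent@rho
  if (buoy <= 0) stop("vbar * rho >= 1: particle would not sediment")
  base <- s20w * 1e-13 * friction_ratio * 6 * pi * solvent@eta *
    (3 * solvent@vbar / (4 * pi))^(1 / 3) * .NA_CONST^(2 / 3) / buoy
  base^(3 / 2)
}

#' Forward map: sedimentation coefficient of a species of known molar mass
#'
#' Inverse of [molarMassFromSedimentation()]; used by the synthetic-data
#' generator to emit species tables consistent with their masses.
#'
#' @param molar_mass g/mol.
#' @inheritParams molarMassFromSedimentation
#' @return sedimentation coefficient, Svedberg.
#' @export
sedimentationFromMolarMass <- function(molar_mass, friction_ratio,
                                       solvent = solventConditions()) {
  stopifnot(is(solvent, "SolventConditions"))
  buoy <- 1 - solvent@vbar * solvent@rho
  1e13 * molar_mass^(2 / 3) * buoy /
    (friction_ratio * 6 * pi * solvent@eta *
       (3 * solvent@vbar / (4 * pi))^(1 / 3) * .NA_CONST^(2 / 3))
}

#' Fill molar masses and association numbers of an AUC species table
#'
#' Computes each species' molar mass from its sedimentation coefficient and
#' the shared frictional ratio, then assigns the association number
#' j = round(M_j / M_1), clipped to >= 1.  Warns (without aborting) when the
#' sample violates the method's prerequisites: any j > 4, or total aggregate
#' fraction r_a = 1 - r_1 above 0.2, both of which indicate the sample
#' should be re-purified before a quantitative reconstruction.
#'
#' @param distribution a [SpeciesDistribution-class].
#' @param solvent a [SolventConditions-class].
#' @return the distribution with `molar_mass` and `association_number`
#'   filled in.  Idempotent.
#' @examples
#' d <- speciesDistribution(c(4.31, 6.8), c(0.8, 0.2), 1.3)
#' speciesTable(assignAssociationNumbers(d, solventConditions()))
#' @export
assignAssociationNumbers <- function(distribution,
                                     solvent = solventConditions()) {
  stopifnot(is(distribution, "SpeciesDistribution"))
  sp <- distribution@species
  sp$molar_mass <- molarMassFromSedimentation(
    sp$s20w, distribution@friction_ratio, solvent)
  sp$association_number <- pmax(1L, as.integer(round(
    sp$molar_mass / sp$molar_mass[1])))
  if (any(sp$association_number > 4))
    warning("association number above 4 detected; the method assumes ",
            "residual aggregates are 4-mer at most -- re-purify the sample")
  ra <- 1 - sp$weight_fraction[1]
  if (ra > 0.2)
    warning(sprintf(
      "aggregate weight fraction r_a = %.3f exceeds the 0.2 prerequisite; ",
      ra), "the sample should be re-purified")
  distribution@species <- sp
  validObject(distribution)
  distribution
}

#' Perrin translational friction factor of a prolate ellipsoid of revolution
#'
#' \deqn{F_P(p) = p^{-1/3}\sqrt{p^2-1}/\ln(p+\sqrt{p^2-1}),\quad p > 1,}
#' continuous at the sphere limit F_P(1) = 1.  This is the shape-only part
#' of the frictional ratio (hydration excluded).
#'
#' @param p axial ratio >= 1 (vectorized).
#' @return dimensionless friction factor >= 1.
#' @export
perrinFactor <- function(p) {
  if (any(p < 1)) stop("perrinFactor is defined for p >= 1")
  out <- numeric(length(p))
  sph <- (p - 1) < 1e-10
  out[sph] <- 1
  pp <- p[!sph]
  xi <- sqrt(pp^2 - 1)
  out[!sph] <- pp^(-1 / 3) * xi / log(pp + xi)
  out
}

#' Axial ratio of the subunit from the measured frictional ratio
#'
#' The frictional ratio delivered by c(s) analysis mixes hydration and
#' shape.  The hydration contribution is stripped as
#' (f/f0)_shape = (f/f0) / (1 + delta/(vbar * rho))^(1/3) with delta the
#' hydration parameter (g water per g protein), and the remaining shape
#' factor is inverted through the Perrin factor of a prolate ellipsoid of
#' revolution by bracketed root finding on p in [1 + 1e-6, 100].  A shape
#' factor at or below 1 returns p = 1 (sphere).
#'
#' @param friction_ratio measured f/f0, >= 1.
#' @param hydration hydration parameter delta, g/g (default 0.3, a
#'   conventional value for globular proteins).
#' @param solvent a [SolventConditions-class] providing vbar and rho.
#' @return axial ratio p >= 1.
#' @examples
#' p <- axialRatioFromFriction(1.30)
#' perrinFactor(p) * (1 + 0.3 / (0.735 * 0.99823))^(1/3)  # recovers 1.30
#' @export
axialRatioFromFriction <- function(friction_ratio, hydration = 0.3,
                                   solvent = solventConditions()) {
  stopifnot(is(solvent, "SolventConditions"))
  if (friction_ratio < 1) stop("friction_ratio must be >= 1")
  if (hydration < 0) stop("hydration must be >= 0")
  shape <- friction_ratio /
    (1 + hydration / (solvent@vbar * solvent@rho))^(1 / 3)
  if (shape <= 1) return(1)
  upper <- 100
  if (shape > perrinFactor(upper))
    stop(sprintf(
      "shape frictional ratio %.3f exceeds the p = %d Perrin factor; ",
      shape, upper), "re-examine f/f0, hydration or vbar")
  uniroot(function(p) perrinFactor(p) - shape,
          lower = 1 + 1e-6, upper = upper, tol = 1e-12)$root
}
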