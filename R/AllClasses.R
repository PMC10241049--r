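#' ScatteringProfile: a one-dimensional small-angle scattering curve
#'
#' Holds a scattering-vector grid `q` (reciprocal angstroms), intensities
#' (absolute scale, cm^-1, or concentration-normalized, mg^-1 cm^2) and
#' their standard errors, together with the total mass concentration of the
#' solute when known.
#'
#' @slot q numeric, strictly increasing, all positive; reciprocal angstroms.
#' @slot intensity numeric, same length as `q`.
#' @slot sigma numeric standard errors, same length as `q`, non-negative.
#' @slot concentration total mass concentration, mg ml^-1, or `NA`.
#' @slot normalized logical; `TRUE` when `intensity` is per unit
#'   concentration (i = I/c), which requires a positive `concentration`.
#'
#' @seealso [scatteringProfile()], [readProfile()], [writeProfile()]
#' @exportClass ScatteringProfile
setClass("ScatteringProfile",
  representation(
    q = "numeric",
    intensity = "numeric",
    sigma = "numeric",
    concentration = "numeric",
    normalized = "logical"
  ),
  prototype(concentration = NA_real_, normalized = FALSE)
)

setValidity("ScatteringProfile", function(object) {
  msg <- character()
  n <- length(object@q)
  if (length(object@intensity) != n || length(object@sigma) != n)
    msg <- c(msg, "q, intensity and sigma must have equal length")
  if (n > 0) {
    if (any(!is.finite(object@q)) || any(object@q <= 0))
      msg <- c(msg, "q must be finite and positive")
    if (is.unsorted(object@q, strictly = TRUE))
      msg <- c(msg, "q must be strictly increasing")
    if (any(object@sigma < 0, na.rm = TRUE))
      msg <- c(msg, "sigma must be non-negative")
  }
  if (length(object@normalized) != 1 || length(object@concentration) != 1)
    msg <- c(msg, "concentration and normalized must be scalars")
  else if (isTRUE(object@normalized) &&
           (is.na(object@concentration) || object@concentration <= 0))
    msg <- c(msg, "a normalized profile requires a positive concentration")
  if (length(msg)) msg else TRUE
})

#' Construct a ScatteringProfile
#'
#' @param q scattering-vector magnitudes, reciprocal angstroms.
#' @param intensity intensities (cm^-1 absolute, or mg^-1 cm^2 normalized).
#' @param sigma standard errors of `intensity`; same units.
#' @param concentration total mass concentration, mg ml^-1 (optional).
#' @param normalized logical; is `intensity` already divided by
#'   concentration?
#' @return a [ScatteringProfile-class] object.
#' @examples
#' p <- scatteringProfile(q = seq(0.01, 0.2, length.out = 50),
#'                        intensity = exp(-seq(0.01, 0.2, length.out = 50)^2),
#'                        sigma = rep(1e-3, 50))
#' p
#' @export
scatteringProfile <- function(q, intensity, sigma,
                              concentration = NA_real_, normalized = FALSE) {
  new("ScatteringProfile", q = as.numeric(q), intensity = as.numeric(intensity),
      sigma = as.numeric(sigma), concentration = as.numeric(concentration),
      normalized = isTRUE(normalized))
}

#' SpeciesDistribution: the AUC c(s) species table
#'
#' The result of a sedimentation-velocity c(s) analysis reduced to the
#' quantities the reconstruction needs: one row per solution species with
#' its sedimentation coefficient (s_20,w, Svedberg), weight fraction, and --
#' once assigned -- molar mass and association number, plus the shared
#' frictional ratio f/f0.  The monomer (smallest s) is always the first row.
#'
#' @slot species data.frame with columns `s20w`, `weight_fraction`,
#'   `molar_mass` (g/mol, `NA` until computed) and `association_number`
#'   (integer, `NA` until assigned), ordered by increasing `s20w`.
#' @slot friction_ratio shared frictional ratio f/f0, dimensionless, >= 1.
#'
#' @seealso [speciesDistribution()], [readSpeciesTable()],
#'   [assignAssociationNumbers()]
#' @exportClass SpeciesDistribution
setClass("SpeciesDistribution",
  representation(species = "data.frame", friction_ratio = "numeric")
)

setValidity("SpeciesDistribution", function(object) {
  msg <- character()
  sp <- object@species
  need <- c("s20w", "weight_fraction", "molar_mass", "association_number")
  if (!all(need %in% names(sp)))
    return(paste("species table must have columns:", paste(need, collapse = ", ")))
  if (nrow(sp) < 1) msg <- c(msg, "at least one species is required")
  if (any(sp$s20w <= 0)) msg <- c(msg, "s20w must be positive")
  if (any(sp$weight_fraction <= 0 | sp$weight_fraction > 1))
    msg <- c(msg, "weight fractions must be in (0, 1]")
  if (abs(sum(sp$weight_fraction) - 1) > 1e-6)
    msg <- c(msg, "weight fractions must sum to 1 within 1e-6")
  if (is.unsorted(sp$s20w))
    msg <- c(msg, "species must be ordered by increasing s20w (monomer first)")
  jj <- sp$association_number
  if (any(!is.na(jj) & jj < 1))
    msg <- c(msg, "association numbers must be >= 1")
  if (length(object@friction_ratio) != 1 || object@friction_ratio < 1)
    msg <- c(msg, "friction_ratio must be a scalar >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a SpeciesDistribution
#'
#' Species are reordered by increasing sedimentation coefficient so the
#' monomer comes first.  Weight fractions off unity by less than 1e-3 are
#' renormalized with a warning; larger discrepancies are an error.
#'
#' @param s20w sedimentation coefficients, Svedberg (10^-13 s).
#' @param weight_fraction weight fractions r_j, summing to 1.
#' @param friction_ratio shared frictional ratio f/f0 (>= 1).
#' @param molar_mass molar masses, g/mol (optional; see
#'   [assignAssociationNumbers()]).
#' @param association_number integer association numbers j (optional).
#' @return a [SpeciesDistribution-class] object.
#' @examples
#' speciesDistribution(s20w = c(4.3, 6.5), weight_fraction = c(0.8, 0.2),
#'                     friction_ratio = 1.3)
#' @export
speciesDistribution <- function(s20w, weight_fraction, friction_ratio,
                                molar_mass = NULL, association_number = NULL) {
  n <- length(s20w)
  if (length(weight_fraction) != n)
    stop("s20w and weight_fraction must have equal length")
  tot <- sum(weight_fraction)
  if (abs(tot - 1) >= 1e-3)
    stop(sprintf("weight fractions sum to %.4f, too far from 1", tot))
  if (abs(tot - 1) > 1e-6) {
    warning(sprintf("weight fractions sum to %.6f; renormalizing", tot))
    weight_fraction <- weight_fraction / tot
  }
  sp <- data.frame(
    s20w = as.numeric(s20w),
    weight_fraction = as.numeric(weight_fraction),
    molar_mass = if (is.null(molar_mass)) NA_real_ else as.numeric(molar_mass),
    association_number = if (is.null(association_number)) NA_integer_
                         else as.integer(association_number)
  )
  sp <- sp[order(sp$s20w), , drop = FALSE]
  rownames(sp) <- NULL
  new("SpeciesDistribution", species = sp,
      friction_ratio = as.numeric(friction_ratio))
}

#' SolventConditions: constants for hydrodynamic conversions
#'
#' @slot vbar partial specific volume of the solute, cm^3 g^-1.
#' @slot eta solvent (water, 293 K) viscosity, poise.
#' @slot rho solvent (water, 293 K) density, g cm^-3.
#' @slot temperature kelvin; informational, since sedimentation
#'   coefficients are assumed already normalized to s_20,w.
#' @seealso [solventConditions()], [molarMassFromSedimentation()]
#' @exportClass SolventConditions
setClass("SolventConditions",
  representation(vbar = "numeric", eta = "numeric", rho = "numeric",
                 temperature = "numeric")
)

setValidity("SolventConditions", function(object) {
  msg <- character()
  if (object@eta <= 0 || object@rho <= 0)
    msg <- c(msg, "eta and rho must be positive")
  if (object@vbar <= 0) msg <- c(msg, "vbar must be positive")
  if (object@vbar * object@rho >= 1)
    msg <- c(msg, "vbar * rho must be < 1 (particle must sediment)")
  if (length(msg)) msg else TRUE
})

#' Construct SolventConditions
#'
#' Defaults are water at 293 K (viscosity 0.01002 P, density
#' 0.99823 g cm^-3) and a typical protein partial specific volume.
#'
#' @param vbar partial specific volume, cm^3 g^-1.
#' @param eta viscosity, poise.
#' @param rho density, g cm^-3.
#' @param temperature kelvin (informational).
#' @return a [SolventConditions-class] object.
#' @export
solventConditions <- function(vbar = 0.735, eta = 0.01002, rho = 0.99823,
                              temperature = 293.15) {
  new("SolventConditions", vbar = vbar, eta = eta, rho = rho,
      temperature = temperature)
}

#' SubunitShape: ellipsoid-of-revolution model of the monomer
#'
#' The aggregate model treats each subunit as an ellipsoid of revolution
#' with semi-axes `r` and `p*r`.  The gyration radius of that ellipsoid is
#' rg^2 = r^2 (2 + p^2) / 5, which ties the three slots together.
#'
#' @slot axial_ratio axial ratio p (> 0; prolate convention p >= 1).
#' @slot semi_axis equatorial semi-axis r, angstroms.
#' @slot rg gyration radius of the ellipsoid, angstroms.
#' @seealso [subunitShape()], [semiAxisFromRg()]
#' @exportClass SubunitShape
setClass("SubunitShape",
  representation(axial_ratio = "numeric", semi_axis = "numeric", rg = "numeric")
)

setValidity("SubunitShape", function(object) {
  msg <- character()
  if (object@axial_ratio <= 0) msg <- c(msg, "axial_ratio must be positive")
  if (object@semi_axis <= 0) msg <- c(msg, "semi_axis must be positive")
  rg2 <- object@semi_axis^2 * (2 + object@axial_ratio^2) / 5
  if (abs(object@rg^2 - rg2) > 1e-9 * max(rg2, 1))
    msg <- c(msg, "rg inconsistent with semi_axis and axial_ratio")
  if (length(msg)) msg else TRUE
})

#' Construct a SubunitShape from gyration radius and axial ratio
#'
#' @param rg target gyration radius, angstroms.
#' @param p axial ratio (semi-axes r and p*r).
#' @return a [SubunitShape-class] whose ellipsoid has gyration radius `rg`.
#' @examples
#' subunitShape(rg = 27.1, p = 1.3)
#' @export
subunitShape <- function(rg, p = 1) {
  r <- semiAxisFromRg(rg, p)
  new("SubunitShape", axial_ratio = p, semi_axis = r, rg = rg)
}

#' AggregateModel: precomputed mixture-model factors on a q grid
#'
#' Stores the subunit anisotropy factor beta(q) and the random-flight
#' inter-subunit structure factors T_j(q) used by the improved
#' reconstruction, for each association number present in the sample.
#'
#' @slot q grid, reciprocal angstroms.
#' @slot beta beta(q) = <F>^2 / <|F|^2>, in (0, 1].
#' @slot t_factors named list, one T_j(q) vector per association number j.
#' @slot subunit the [SubunitShape-class] used.
#' @slot neighbor_distance mean distance D between neighboring subunit
#'   centres of mass, angstroms (convention: D = 2 rg of the subunit).
#' @seealso [aggregateModel()], [mixtureFactor()], [aggregateProfile()]
#' @exportClass AggregateModel
setClass("AggregateModel",
  representation(q = "numeric", beta = "numeric", t_factors = "list",
                 subunit = "SubunitShape", neighbor_distance = "numeric")
)

setValidity("AggregateModel", function(object) {
  msg <- character()
  if (length(object@beta) != length(object@q))
    msg <- c(msg, "beta must match the q grid")
  if (length(object@beta) &&
      (any(object@beta <= 0) || any(object@beta > 1 + 1e-12)))
    msg <- c(msg, "beta must lie in (0, 1]")
  for (nm in names(object@t_factors)) {
    tj <- object@t_factors[[nm]]
    j <- as.numeric(nm)
    if (length(tj) != length(object@q))
      msg <- c(msg, sprintf("T_%s must match the q grid", nm))
    # T_j(0) = j and T_j > 0 everywhere; the sinc oscillation makes T_j dip
    # mildly below 1 at intermediate q, which is physical
    else if (any(tj <= 0) || any(tj > j + 1e-9))
      msg <- c(msg, sprintf("T_%s must lie in (0, %s]", nm, nm))
  }
  if (object@neighbor_distance <= 0)
    msg <- c(msg, "neighbor_distance must be positive")
  if (length(msg)) msg else TRUE
})

#' MonomerResult: output of an AUC-SAS reconstruction
#'
#' @slot profile reconstructed monomer profile I_1(q) (absolute scale) with
#'   propagated errors; the stored concentration is the monomer
#'   concentration c_1 = r_1 c.
#' @slot rg1,rg1_sd monomer gyration radius and its standard deviation,
#'   angstroms.
#' @slot i1_zero,i1_zero_sd concentration-normalized forward intensity
#'   i_1(0) = I_1(0)/c_1, mg^-1 cm^2, with propagated error.
#' @slot q_connect joint point q_c between the Guinier curve and the
#'   high-q branch, reciprocal angstroms.
#' @slot method `"first"` or `"improved"`.
#' @slot iterations number of gyration-radius iterations performed.
#' @slot mixture_factor final mixture factor S(q) (improved method;
#'   length-0 for the first method).
#' @slot guinier list of diagnostics from the connection and Guinier fits.
#' @slot warnings character vector of accumulated warnings.
#' @seealso [firstAUCSAS()], [improvedAUCSAS()], [writeReport()]
#' @exportClass MonomerResult
setClass("MonomerResult",
  representation(
    profile = "ScatteringProfile",
    rg1 = "numeric", rg1_sd = "numeric",
    i1_zero = "numeric", i1_zero_sd = "numeric",
    q_connect = "numeric", method = "character",
    iterations = "numeric", mixture_factor = "numeric",
    guinier = "list", warnings = "character"
  )
)

setValidity("MonomerResult", function(object) {
  msg <- character()
  if (!object@method %in% c("first", "improved"))
    msg <- c(msg, "method must be 'first' or 'improved'")
  q <- object@profile@q
  if (length(q) && (object@q_connect < min(q) || object@q_connect > max(q)))
    msg <- c(msg, "q_connect must lie inside the data q range")
  if (length(msg)) msg else TRUE
})

#' PairDistanceDistribution: P(r) from the indirect Fourier transform
#'
#' @slot r distance grid, angstroms, from 0 to `dmax`.
#' @slot p_of_r distribution values (>= 0, vanishing at both ends).
#' @slot dmax maximum intraparticle distance, angstroms.
#' @slot rg_real gyration radius from the second moment of P(r), angstroms.
#' @slot quality list of regularization diagnostics (chi2, reduced chi2,
#'   lambda, smoothness norm, i0).
#' @seealso [indirectTransform()], [estimateDmax()]
#' @exportClass PairDistanceDistribution
setClass("PairDistanceDistribution",
  representation(r = "numeric", p_of_r = "numeric", dmax = "numeric",
                 rg_real = "numeric", quality = "list")
)

setValidity("PairDistanceDistribution", function(object) {
  msg <- character()
  if (length(object@r) != length(object@p_of_r))
    msg <- c(msg, "r and p_of_r must have equal length")
  if (any(object@p_of_r < 0)) msg <- c(msg, "p_of_r must be non-negative")
  n <- length(object@p_of_r)
  if (n >= 2 && (object@p_of_r[1] != 0 || object@p_of_r[n] != 0))
    msg <- c(msg, "p_of_r must vanish at r = 0 and r = dmax")
  if (length(msg)) msg else TRUE
})

#' SyntheticScenario: parameters of a simulated aggregate-contaminated sample
#'
#' The defaults emulate a serum-albumin-like sample at the upper end of the
#' admissible aggregate content: a 27.1-angstrom monomer of 66.5 kg/mol at
#' 2.0 mg/ml with weight fractions 0.80/0.14/0.06 for monomer/dimer/trimer
#' (aggregate fraction r_a = 0.20) on a 120-point log-spaced q grid that
#' brackets a typical laboratory SAXS range.
#'
#' @slot shape [SubunitShape-class] of the monomer.
#' @slot fractions named numeric, weight fraction per association number j.
#' @slot concentration total mass concentration, mg ml^-1.
#' @slot monomer_mass monomer molar mass, g/mol.
#' @slot q scattering-vector grid, reciprocal angstroms.
#' @slot noise_level relative error sigma/I at q = 0.
#' @slot seed integer RNG seed.
#' @seealso [syntheticScenario()], [makeDataset()]
#' @exportClass SyntheticScenario
setClass("SyntheticScenario",
  representation(shape = "SubunitShape", fractions = "numeric",
                 concentration = "numeric", monomer_mass = "numeric",
                 q = "numeric", noise_level = "numeric", seed = "numeric")
)

setValidity("SyntheticScenario", function(object) {
  msg <- character()
  if (is.null(names(object@fractions)) ||
      anyNA(suppressWarnings(as.integer(names(object@fractions)))))
    msg <- c(msg, "fractions must be named by integer association numbers")
  if (abs(sum(object@fractions) - 1) > 1e-9)
    msg <- c(msg, "fractions must sum to 1")
  if (any(object@fractions <= 0))
    msg <- c(msg, "fractions must be positive")
  if (object@noise_level < 0) msg <- c(msg, "noise_level must be >= 0")
  if (any(diff(object@q) <= 0) || any(object@q <= 0))
    msg <- c(msg, "q must be positive and strictly increasing")
  if (length(msg)) msg else TRUE
})
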