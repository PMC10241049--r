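# Accessor generics and show methods.

#' @describeIn ScatteringProfile-class the q grid (reciprocal angstroms).
#' @param object,x objects of the documented classes.
#' @export
setGeneric("qGrid", function(x) standardGeneric("qGrid"))

#' @export
setMethod("qGrid", "ScatteringProfile", function(x) x@q)

#' @export
setMethod("qGrid", "AggregateModel", function(x) x@q)

#' Intensities of a scattering profile
#' @param x a [ScatteringProfile-class].
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @export
setMethod("intensities", "ScatteringProfile", function(x) x@intensity)

#' Standard errors of a scattering profile
#' @param x a [ScatteringProfile-class].
#' @export
setGeneric("sigmas", function(x) standardGeneric("sigmas"))

#' @export
setMethod("sigmas", "ScatteringProfile", function(x) x@sigma)

#' Is a profile concentration-normalized?
#' @param x a [ScatteringProfile-class].
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))

#' @export
setMethod("isNormalized", "ScatteringProfile", function(x) x@normalized)

#' Mass concentration stored with a profile (mg/ml)
#' @param x a [ScatteringProfile-class].
#' @export
setGeneric("sampleConcentration",
           function(x) standardGeneric("sampleConcentration"))

#' @export
setMethod("sampleConcentration", "ScatteringProfile",
          function(x) x@concentration)

#' Species table of an AUC distribution
#' @param x a [SpeciesDistribution-class].
#' @return data.frame with columns s20w, weight_fraction, molar_mass,
#'   association_number; monomer first.
#' @export
setGeneric("speciesTable", function(x) standardGeneric("speciesTable"))

#' @export
setMethod("speciesTable", "SpeciesDistribution", function(x) x@species)

#' Shared frictional ratio f/f0
#' @param x a [SpeciesDistribution-class].
#' @export
setGeneric("frictionRatio", function(x) standardGeneric("frictionRatio"))

#' @export
setMethod("frictionRatio", "SpeciesDistribution", function(x) x@friction_ratio)

#' Monomer gyration radius of a reconstruction (angstroms)
#' @param x a [MonomerResult-class].
#' @export
setGeneric("rg1", function(x) standardGeneric("rg1"))

#' @export
setMethod("rg1", "MonomerResult", function(x) x@rg1)

#' Concentration-normalized forward intensity i_1(0) (mg^-1 cm^2)
#' @param x a [MonomerResult-class].
#' @export
setGeneric("i1Zero", function(x) standardGeneric("i1Zero"))

#' @export
setMethod("i1Zero", "MonomerResult", function(x) x@i1_zero)

#' Connection point q_c (reciprocal angstroms)
#' @param x a [MonomerResult-class].
#' @export
setGeneric("qConnect", function(x) standardGeneric("qConnect"))

#' @export
setMethod("qConnect", "MonomerResult", function(x) x@q_connect)

#' Reconstructed monomer profile (absolute scale)
#' @param x a [MonomerResult-class].
#' @export
setGeneric("monomerProfile", function(x) standardGeneric("monomerProfile"))

#' @export
setMethod("monomerProfile", "MonomerResult", function(x) x@profile)

#' Maximum intraparticle distance (angstroms)
#' @param x a [PairDistanceDistribution-class].
#' @export
setGeneric("dMax", function(x) standardGeneric("dMax"))

#' @export
setMethod("dMax", "PairDistanceDistribution", function(x) x@dmax)

setMethod("show", "ScatteringProfile", function(object) {
  n <- length(object@q)
  cat(sprintf("ScatteringProfile: %d points, q in [%g, %g] 1/A\n",
              n, if (n) min(object@q) else NA, if (n) max(object@q) else NA))
  cat(sprintf("  intensity: %s; concentration: %s mg/ml\n",
              if (object@normalized) "normalized (mg^-1 cm^2)"
              else "absolute (1/cm)",
              if (is.na(object@concentration)) "unknown"
              else format(object@concentration)))
})

setMethod("show", "SpeciesDistribution", function(object) {
  cat(sprintf("SpeciesDistribution: %d species, f/f0 = %.3f\n",
              nrow(object@species), object@friction_ratio))
  print(object@species)
})

setMethod("show", "SubunitShape", function(object) {
  cat(sprintf(
    "SubunitShape: ellipsoid of revolution, p = %.3f, r = %.2f A, Rg = %.2f A\n",
    object@axial_ratio, object@semi_axis, object@rg))
})

setMethod("show", "AggregateModel", function(object) {
  cat(sprintf(
    "AggregateModel: %d q points, j = {%s}, D = %.2f A, subunit p = %.3f\n",
    length(object@q), paste(names(object@t_factors), collapse = ", "),
    object@neighbor_distance, object@subunit@axial_ratio))
})

setMethod("show", "MonomerResult", function(object) {
  cat(sprintf("MonomerResult (%s AUC-SAS)\n", object@method))
  cat(sprintf("  Rg1  = %.2f +/- %.2f A\n", object@rg1, object@rg1_sd))
  cat(sprintf("  i1(0) = %.4g +/- %.2g mg^-1 cm^2\n",
              object@i1_zero, object@i1_zero_sd))
  cat(sprintf("  q_c  = %.4f 1/A (q_c * Rg1 = %.2f), %d iteration(s)\n",
              object@q_connect, object@q_connect * object@rg1,
              as.integer(object@iterations)))
  if (length(object@warnings))
    cat("  warnings:", paste(object@warnings, collapse = "; "), "\n")
})

setMethod("show", "PairDistanceDistribution", function(object) {
  cat(sprintf(
    "PairDistanceDistribution: %d points, Dmax = %.1f A, Rg(real) = %.2f A\n",
    length(object@r), object@dmax, object@rg_real))
})

setMethod("show", "SyntheticScenario", function(object) {
  cat(sprintf(
    "SyntheticScenario: Rg1 = %.1f A (p = %.2f), M1 = %g g/mol, c = %g mg/ml\n",
    object@shape@rg, object@shape@axial_ratio, object@monomer_mass,
    object@concentration))
  cat(sprintf("  fractions: %s; noise %.3g; seed %d\n",
              paste(sprintf("j=%s: %.3f", names(object@fractions),
                            object@fractions), collapse = ", "),
              object@noise_level, as.integer(object@seed)))
})
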