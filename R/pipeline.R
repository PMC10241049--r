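# End-to-end pipeline wrappers behind the command-line entry point.

#' Run the full reconstruction pipeline
#'
#' Reads a scattering profile and an AUC species table, reconstructs the
#' monomer profile with the requested method, performs the P(r) analysis,
#' and writes four artifacts into `output_dir`: the monomer profile
#' (`monomer.dat`, absolute scale at the monomer concentration), the pair
#' distance distribution (`pr.dat`), a JSON report (`report.json`) and a
#' log of warnings (`run.log`).
#'
#' @param sas_path path to the 3-column scattering profile.
#' @param species_path path to the AUC species table.
#' @param concentration total mass concentration, mg/ml.
#' @param output_dir directory for artifacts (created if needed).
#' @param method `"improved"` (default) or `"first"`.
#' @param vbar,hydration solvent/solute parameters (cm^3/g and g/g).
#' @param guinier_cap Guinier validity limit on q * Rg.
#' @param max_iter,tol iteration controls of the improved method.
#' @param dmax_scan optional dmax scan vector for [estimateDmax()].
#' @param q_scale multiplier applied to q on load (0.1 for nm^-1 data).
#' @param seed optional integer recorded in the report.
#' @return the [MonomerResult-class], invisibly; artifacts on disk.
#' @export
runAUCSAS <- function(sas_path, species_path, concentration, output_dir,
                      method = c("improved", "first"), vbar = 0.735,
                      hydration = 0.3, guinier_cap = 1.3, max_iter = 20,
                      tol = 1e-3, dmax_scan = NULL, q_scale = 1,
                      seed = NULL) {
  method <- match.arg(method)
  profile <- readProfile(sas_path, concentration = concentration,
                         q_scale = q_scale)
  distribution <- readSpeciesTable(species_path)
  solvent <- solventConditions(vbar = vbar)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  result <- withCallingHandlers(
    if (method == "improved")
      improvedAUCSAS(profile, distribution, solvent, hydration = hydration,
                     max_iter = max_iter, tol = tol,
                     guinier_cap = guinier_cap)
    else
      firstAUCSAS(profile, distribution, solvent, guinier_cap = guinier_cap),
    warning = function(w) invokeRestart("muffleWarning"))
  writeProfile(result@profile, file.path(output_dir, "monomer.dat"))
  pr <- tryCatch({
    dm <- if (is.null(dmax_scan)) estimateDmax(result@profile)
          else estimateDmax(result@profile, dmax_scan)
    indirectTransform(result@profile, as.numeric(dm))
  }, error = function(e) {
    message("P(r) analysis skipped: ", conditionMessage(e)); NULL
  })
  if (!is.null(pr)) {
    writeLines(c("# r(A) P(r)",
                 sprintf("%.6g %.6g", pr@r, pr@p_of_r)),
               file.path(output_dir, "pr.dat"))
  }
  writeReport(result, file.path(output_dir, "report.json"), pr = pr,
              seed = seed)
  writeLines(c(sprintf("method = %s", method),
               sprintf("Rg1 = %.3f +/- %.3f A", result@rg1, result@rg1_sd),
               sprintf("i1(0) = %.5g +/- %.2g mg^-1 cm^2",
                       result@i1_zero, result@i1_zero_sd),
               sprintf("q_c = %.5f 1/A (q_c Rg1 = %.2f)", result@q_connect,
                       result@q_connect * result@rg1),
               if (length(result@warnings))
                 paste("warning:", result@warnings) else "no warnings"),
             file.path(output_dir, "run.log"))
  invisible(result)
}

#' Generate and write a synthetic dataset
#'
#' Wraps [syntheticScenario()] and [makeDataset()]; writes the noisy
#' profile (`profile.dat`), the species table (`species.csv`) and a truth
#' record (`truth.json`) into `output_dir`.  Emits the prerequisite
#' warnings when the requested scenario violates the method's assumptions
#' (aggregate fraction above 0.2, association number above 4).
#'
#' @param ra total aggregate weight fraction; split 0.7/0.3 between dimer
#'   and trimer when `fractions` is not given.
#' @param rg,p,mass,concentration,noise,seed scenario parameters (see
#'   [syntheticScenario()]).
#' @param fractions optional full named fraction vector overriding `ra`.
#' @param output_dir directory for the three files.
#' @param ... further arguments passed to [makeDataset()].
#' @return the dataset list from [makeDataset()], invisibly.
#' @export
simulateDataset <- function(output_dir, ra = 0.2, rg = 27.1, p = 1.3,
                            mass = 66500, concentration = 2.0,
                            noise = 0.005, seed = 1, fractions = NULL,
                            ...) {
  if (is.null(fractions)) {
    fractions <- c("1" = 1 - ra, "2" = 0.7 * ra, "3" = 0.3 * ra)
    fractions <- fractions[fractions > 0]
  }
  if (1 - fractions[["1"]] > 0.2)
    warning("aggregate fraction above the 0.2 prerequisite; ",
            "reconstructions from such data are not guaranteed")
  if (any(as.integer(names(fractions)) > 4))
    warning("association number above the 4-mer prerequisite")
  scen <- syntheticScenario(rg = rg, p = p, fractions = fractions,
                            concentration = concentration,
                            monomer_mass = mass, noise_level = noise,
                            seed = seed)
  ds <- makeDataset(scen, ...)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  writeProfile(ds$profile, file.path(output_dir, "profile.dat"))
  writeSpeciesTable(ds$distribution, file.path(output_dir, "species.csv"))
  truth <- ds$truth
  jsonlite::write_json(
    list(rg1_A = truth$rg1, i1_zero = truth$i1_zero,
         i0_total = truth$i0_total, axial_ratio = truth$axial_ratio,
         friction_ratio = truth$friction_ratio, seed = truth$seed),
    file.path(output_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(ds)
}
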