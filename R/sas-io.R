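# Plain-text I/O: 3-column .dat scattering profiles, AUC species tables,
# and structured JSON result reports.

#' Convert a profile to absolute scale
#'
#' @param profile a [ScatteringProfile-class].
#' @return the profile with intensities in cm^-1 (multiplied by the stored
#'   concentration if it was normalized).
#' @export
asAbsolute <- function(profile) {
  stopifnot(is(profile, "ScatteringProfile"))
  if (!profile@normalized) return(profile)
  c0 <- profile@concentration
  profile@intensity <- profile@intensity * c0
  profile@sigma <- profile@sigma * c0
  profile@normalized <- FALSE
  profile
}

#' Convert a profile to concentration-normalized scale
#'
#' @param profile a [ScatteringProfile-class] with a known positive
#'   concentration.
#' @return the profile with intensities in mg^-1 cm^2 (divided by the
#'   stored concentration).
#' @export
asNormalized <- function(profile) {
  stopifnot(is(profile, "ScatteringProfile"))
  if (profile@normalized) return(profile)
  c0 <- profile@concentration
  if (is.na(c0) || c0 <= 0)
    stop("cannot normalize: concentration unknown")
  profile@intensity <- profile@intensity / c0
  profile@sigma <- profile@sigma / c0
  profile@normalized <- TRUE
  profile
}

#' Read a scattering profile from a 3-column text file
#'
#' Accepts the de facto SAS .dat dialects: whitespace- or comma-delimited
#' columns q, I and (optionally) sigma, with `#` or `;` comment lines.
#' Rows with non-finite or non-positive q are dropped (with a message),
#' duplicate q values are merged by error-weighted averaging, and a missing
#' sigma column is synthesized as
#' sigma(q) = max(0.01 I(q), 1e-3 * min positive I) so downstream weighted
#' fits always have finite errors.  Units are declared, not converted: q
#' must be in reciprocal angstroms (use `q_scale = 0.1` for data recorded
#' in reciprocal nanometres).
#'
#' @param path file path.
#' @param concentration total mass concentration, mg/ml (optional).
#' @param normalized is the intensity column already concentration
#'   normalized?
#' @param q_scale multiplier applied to the q column on load (default 1).
#' @return a [ScatteringProfile-class].
#' @export
readProfile <- function(path, concentration = NA_real_, normalized = FALSE,
                        q_scale = 1) {
  if (!file.exists(path)) stop("cannot read ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*[#;]", lines) & nzchar(trimws(lines))]
  if (!length(lines)) stop("no data rows in ", path)
  sep <- if (grepl(",", lines[1])) "," else ""
  dat <- utils::read.table(text = lines, sep = sep, header = FALSE,
                           fill = TRUE, stringsAsFactors = FALSE)
  dat <- as.data.frame(lapply(dat, function(col)
    suppressWarnings(as.numeric(col))))
  if (ncol(dat) < 2) stop("need at least 2 columns (q, I) in ", path)
  q <- dat[[1]] * q_scale
  I <- dat[[2]]
  s <- if (ncol(dat) >= 3) dat[[3]] else rep(NA_real_, length(q))
  bad <- !is.finite(q) | q <= 0 | !is.finite(I)
  if (any(bad)) {
    message(sum(bad), " row(s) with non-finite or non-positive q/I dropped")
    q <- q[!bad]; I <- I[!bad]; s <- s[!bad]
  }
  if (length(q) < 10) stop("fewer than 10 usable rows in ", path)
  if (anyNA(s) || all(s == 0)) {
    minI <- min(I[I > 0])
    s <- pmax(0.01 * I, 1e-3 * minI)
  }
  ord <- order(q)
  q <- q[ord]; I <- I[ord]; s <- s[ord]
  if (anyDuplicated(q)) {
    message("duplicate q values merged by error-weighted averaging")
    grp <- match(q, unique(q))
    w <- ifelse(s > 0, 1 / s^2, 1)
    wsum <- as.vector(rowsum(w, grp))
    I <- as.vector(rowsum(I * w, grp)) / wsum
    s <- sqrt(1 / wsum)
    q <- unique(q)
  }
  scatteringProfile(q, I, s, concentration, normalized)
}

#' Write a scattering profile as 3-column text
#'
#' The header records units, normalization state and concentration so that
#' [readProfile()] round-trips the profile (values are written with 8
#' significant digits).
#'
#' @param profile a [ScatteringProfile-class].
#' @param path output path.
#' @export
writeProfile <- function(profile, path) {
  stopifnot(is(profile, "ScatteringProfile"))
  if (length(profile@q) == 0) stop("refusing to write an empty profile")
  units <- if (profile@normalized) "i(1/(mg/ml)/cm)" else "I(1/cm)"
  hdr <- c(
    sprintf("# q(1/A) %s sigma(same units)", units),
    sprintf("# normalized = %s", if (profile@normalized) "true" else "false"),
    sprintf("# concentration_mg_ml = %s",
            if (is.na(profile@concentration)) "NA"
            else format(profile@concentration, digits = 8))
  )
  body <- sprintf("%.8g %.8g %.8g", profile@q, profile@intensity,
                  profile@sigma)
  ok <- tryCatch({
    writeLines(c(hdr, body), path); TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write ", path)
  invisible(path)
}

#' Read an AUC species table
#'
#' CSV (or whitespace) file with columns `s20w` and `weight_fraction`
#' (optional `molar_mass`, `association_number`), plus a pragma comment
#' line `# friction_ratio = <value>`.  Fractions off unity by less than
#' 1e-3 are renormalized with a warning; larger discrepancies are an
#' error.  Species are reordered monomer (smallest s) first.
#'
#' @param path file path.
#' @return a [SpeciesDistribution-class].
#' @export
readSpeciesTable <- function(path) {
  if (!file.exists(path)) stop("cannot read ", path)
  lines <- readLines(path, warn = FALSE)
  prag <- grep("^\\s*#\\s*friction_ratio\\s*=", lines, value = TRUE)
  if (!length(prag))
    stop("missing '# friction_ratio = <value>' pragma in ", path)
  ff0 <- as.numeric(sub(".*=\\s*", "", prag[1]))
  if (!is.finite(ff0)) stop("unreadable friction_ratio value in ", path)
  body <- lines[!grepl("^\\s*[#;]", lines) & nzchar(trimws(lines))]
  sep <- if (grepl(",", body[1])) "," else ""
  df <- utils::read.table(text = body, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE)
  if (!all(c("s20w", "weight_fraction") %in% names(df)))
    stop("species table needs columns s20w and weight_fraction")
  speciesDistribution(
    s20w = df$s20w, weight_fraction = df$weight_fraction,
    friction_ratio = ff0,
    molar_mass = if ("molar_mass" %in% names(df)) df$molar_mass else NULL,
    association_number = if ("association_number" %in% names(df))
      df$association_number else NULL)
}

#' Write an AUC species table
#'
#' @param distribution a [SpeciesDistribution-class].
#' @param path output path.
#' @export
writeSpeciesTable <- function(distribution, path) {
  stopifnot(is(distribution, "SpeciesDistribution"))
  hdr <- sprintf("# friction_ratio = %.10g", distribution@friction_ratio)
  sp <- distribution@species
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(format(sp, digits = 10), con, sep = ",",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a reconstruction report as structured JSON
#'
#' Fixed schema: method, rg1 (+sd), i1_zero (+sd), q_connect, iterations,
#' the echoed species table and frictional ratio, optional P(r) summary
#' (dmax, rg_real), software version and optional seed.  Read back with
#' [readReport()].
#'
#' @param result a [MonomerResult-class].
#' @param path output path.
#' @param pr optional [PairDistanceDistribution-class] to summarize.
#' @param seed optional integer recorded for reproducibility.
#' @export
writeReport <- function(result, path, pr = NULL, seed = NULL) {
  stopifnot(is(result, "MonomerResult"))
  sp <- result@profile
  rep <- list(
    method = result@method,
    rg1_A = result@rg1, rg1_sd_A = result@rg1_sd,
    i1_zero = result@i1_zero, i1_zero_sd = result@i1_zero_sd,
    q_connect = result@q_connect,
    qc_rg1 = result@q_connect * result@rg1,
    iterations = result@iterations,
    monomer_concentration_mg_ml = sp@concentration,
    n_points = length(sp@q),
    warnings = result@warnings,
    software = paste0("aucsas ", as.character(packageVersion("aucsas")))
  )
  if (!is.null(pr)) {
    stopifnot(is(pr, "PairDistanceDistribution"))
    rep$dmax_A <- pr@dmax
    rep$rg_real_A <- pr@rg_real
  }
  if (!is.null(seed)) rep$seed <- as.integer(seed)
  ok <- tryCatch({
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("cannot write ", path)
  invisible(path)
}

#' Read a JSON reconstruction report
#'
#' @param path file path written by [writeReport()].
#' @return a named list.
#' @export
readReport <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
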