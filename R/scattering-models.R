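# Analytic scattering models: ellipsoid form factor, orientational moments,
# anisotropy factor beta(q), Debye and random-flight inter-subunit structure
# factors, and the decoupled j-mer profile.

#' Equatorial semi-axis of an ellipsoid with prescribed gyration radius
#'
#' For an ellipsoid of revolution with semi-axes r and p*r the gyration
#' radius obeys rg^2 = r^2 (2 + p^2)/5; this returns
#' r = rg * sqrt(5 / (2 + p^2)).
#'
#' @param rg target gyration radius, angstroms.
#' @param p axial ratio.
#' @return semi-axis r, angstroms.
#' @examples
#' semiAxisFromRg(27.3, 2)  # ~24.92 A
#' @export
semiAxisFromRg <- function(rg, p) {
  if (any(rg <= 0) || any(p <= 0)) stop("rg and p must be positive")
  rg * sqrt(5 / (2 + p^2))
}

#' Single-orientation form-factor amplitude of an ellipsoid of revolution
#'
#' F(q, alpha) = 3[sin(u) - u cos(u)]/u^3 with
#' u = q r sqrt(sin^2(alpha) + p^2 cos^2(alpha)), where alpha is the angle
#' between the symmetry axis and the scattering vector.  Normalized so that
#' F(0, alpha) = 1.
#'
#' @param q scattering-vector magnitudes, reciprocal angstroms (vector).
#' @param cos_alpha cosine of the orientation angle, in [-1, 1] (vector;
#'   recycled against `q`).
#' @param shape a [SubunitShape-class].
#' @return amplitude values.
#' @export
ellipsoidAmplitude <- function(q, cos_alpha, shape) {
  stopifnot(is(shape, "SubunitShape"))
  if (any(q < 0)) stop("q must be non-negative")
  if (any(abs(cos_alpha) > 1)) stop("|cos_alpha| must be <= 1")
  p <- shape@axial_ratio
  u <- q * shape@semi_axis * sqrt(1 + (p^2 - 1) * cos_alpha^2)
  sphereAmplitude(u)
}

#' Orientational moments of the ellipsoid amplitude
#'
#' Computes the isotropic averages <F(q)> and <|F(q)|^2> over the
#' orientation angle, integrating sin(alpha) d(alpha) on [0, pi/2] by
#' fixed-order Gauss-Legendre quadrature in cos(alpha).  Both moments tend
#' to 1 as q tends to 0.
#'
#' @param q scattering-vector magnitudes (vector).
#' @param shape a [SubunitShape-class].
#' @param order quadrature order (default 128, accurate far beyond the
#'   q-range of any SAS experiment for these smooth integrands).
#' @return list with numeric vectors `meanF` and `meanF2`.
#' @export
orientationalMoments <- function(q, shape, order = 128L) {
  stopifnot(is(shape, "SubunitShape"))
  gl <- gaussLegendre01(order)
  p <- shape@axial_ratio
  r <- shape@semi_axis
  # u: length(q) x order matrix of arguments
  scale <- sqrt(1 + (p^2 - 1) * gl$x^2)
  u <- outer(q * r, scale)
  f <- sphereAmplitude(u)
  dim(f) <- dim(u)
  list(meanF = as.vector(f %*% gl$w), meanF2 = as.vector(f^2 %*% gl$w))
}

#' Shape anisotropy factor beta(q)
#'
#' beta(q) = <F(q)>^2 / <|F(q)|^2>.  Equals 1 at q = 0 and identically 1
#' for a sphere (p = 1); lies in (0, 1] everywhere.
#'
#' @param q scattering-vector magnitudes (vector).
#' @param shape a [SubunitShape-class].
#' @return beta values.
#' @export
betaFactor <- function(q, shape) {
  if (abs(shape@axial_ratio - 1) < 1e-12) return(rep(1, length(q)))
  m <- orientationalMoments(q, shape)
  pmin(m$meanF^2 / m$meanF2, 1)
}

#' Debye inter-subunit structure factor from a distance matrix
#'
#' T(q) = (1/j) sum_k sum_l sinc(q D_kl) for the centre-of-mass separations
#' of a j-mer.  T(0) = j; T tends to 1 at high q.
#'
#' @param q scattering-vector magnitudes (vector).
#' @param distances symmetric j x j matrix of COM separations, zero
#'   diagonal, angstroms.
#' @return T(q) values.
#' @export
debyeStructureFactor <- function(q, distances) {
  distances <- as.matrix(distances)
  j <- nrow(distances)
  if (ncol(distances) != j ||
      any(abs(distances - t(distances)) > 1e-9 * max(1, max(distances))))
    stop("distances must be a symmetric square matrix")
  if (any(diag(distances) != 0)) stop("distances must have a zero diagonal")
  d <- distances[upper.tri(distances)]
  1 + (2 / j) * vapply(q, function(qi) sum(sinc(qi * d)), numeric(1))
}

#' Random-flight inter-subunit structure factor
#'
#' Closed form for subunits arranged as a freely jointed chain with fixed
#' neighbor distance D:
#' \deqn{T_j(q) = 1 + \frac{2}{j}\sum_{m=1}^{j-1}(j-m)
#'   \left[\frac{\sin qD}{qD}\right]^m.}
#' T_1 is identically 1; T_j(0) = j.  This is the ensemble average of the
#' Debye double sum over freely jointed chains, which the synthetic module
#' verifies by direct simulation.
#'
#' @param q scattering-vector magnitudes (vector).
#' @param j association number (integer >= 1).
#' @param D neighbor centre-of-mass distance, angstroms.
#' @return T_j(q) values.
#' @export
randomFlightStructureFactor <- function(q, j, D) {
  if (j < 1 || j != round(j)) stop("j must be a positive integer")
  if (D <= 0) stop("D must be positive")
  if (j == 1) return(rep(1, length(q)))
  s <- sinc(q * D)
  acc <- numeric(length(q))
  sm <- rep(1, length(q))
  for (m in seq_len(j - 1)) {
    sm <- sm * s
    acc <- acc + (j - m) * sm
  }
  1 + (2 / j) * acc
}

#' Precompute the aggregate model factors on a q grid
#'
#' Builds the [AggregateModel-class] holding beta(q) and T_j(q) for the
#' requested association numbers, with the neighbor distance fixed at
#' D = 2 rg of the subunit (the subunit's effective diameter).
#'
#' @param q grid, reciprocal angstroms.
#' @param shape a [SubunitShape-class].
#' @param j integer vector of association numbers to cover.
#' @param D neighbor distance override, angstroms (default 2 * rg; the
#'   override exists for sensitivity analysis only).
#' @return an [AggregateModel-class].
#' @export
aggregateModel <- function(q, shape, j, D = 2 * shape@rg) {
  stopifnot(is(shape, "SubunitShape"))
  j <- sort(unique(as.integer(j)))
  tf <- lapply(j, function(jj) randomFlightStructureFactor(q, jj, D))
  names(tf) <- as.character(j)
  new("AggregateModel", q = q, beta = betaFactor(q, shape),
      t_factors = tf, subunit = shape, neighbor_distance = D)
}

#' Decoupled scattering profile of a j-mer
#'
#' Under the decoupling approximation (subunit orientation independent of
#' position) the concentration-normalized j-mer profile is
#' \deqn{i_j(q) = i_1(q)\,[1 + \beta(q)\,(T_j(q) - 1)]}
#' so that i_j(0) = j i_1(0) and i_j tends to i_1 at high q, where the
#' inter-subunit interference dies out.
#'
#' @param i1 monomer normalized intensities on the model's q grid (numeric
#'   vector), or a [ScatteringProfile-class] on that grid.
#' @param j association number; must be present in the model.
#' @param model an [AggregateModel-class].
#' @return same type as `i1`, containing i_j(q).
#' @export
aggregateProfile <- function(i1, j, model) {
  stopifnot(is(model, "AggregateModel"))
  key <- as.character(as.integer(j))
  if (!key %in% names(model@t_factors))
    stop("association number ", key, " not present in the model")
  fac <- 1 + model@beta * (model@t_factors[[key]] - 1)
  if (is(i1, "ScatteringProfile")) {
    if (length(i1@q) != length(model@q) ||
        any(abs(i1@q - model@q) > 1e-9 * max(model@q)))
      stop("profile q grid does not match the model grid")
    i1@intensity <- i1@intensity * fac
    i1@sigma <- i1@sigma * fac
    return(i1)
  }
  if (length(i1) != length(model@q))
    stop("i1 length does not match the model q grid")
  i1 * fac
}

#' Gyration radius from atomic coordinates
#'
#' Electron-count-weighted root-mean-square distance of the atoms from
#' their electron-weighted centroid.  Used to compute reference gyration
#' radii from crystal structures for comparison with reconstructed values.
#'
#' @param atoms data.frame with columns `element` (chemical symbol) and
#'   `x`, `y`, `z` (angstroms), e.g. from [readAtoms()].
#' @return gyration radius, angstroms.
#' @examples
#' rgFromAtomicCoordinates(data.frame(element = c("C", "C"),
#'                                    x = c(-1, 1), y = 0, z = 0))  # 1 A
#' @export
rgFromAtomicCoordinates <- function(atoms) {
  need <- c("element", "x", "y", "z")
  if (!is.data.frame(atoms) || !all(need %in% names(atoms)))
    stop("atoms must be a data.frame with columns element, x, y, z")
  if (nrow(atoms) < 2) stop("at least two atoms are required")
  w <- electronCount(atoms$element)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  ctr <- colSums(xyz * w) / sum(w)
  d2 <- rowSums(sweep(xyz, 2, ctr)^2)
  sqrt(sum(w * d2) / sum(w))
}

#' Read atomic coordinates from a PDB file or an element/x/y/z table
#'
#' PDB files are parsed with \pkg{bio3d}; by default only protein/nucleic
#' ATOM records are kept and hydrogens are dropped (crystal structures
#' rarely resolve them).  Plain-text tables (CSV or whitespace) must carry
#' columns element, x, y, z.
#'
#' @param path file path; `.pdb` is parsed as PDB, anything else as a
#'   delimited table with a header.
#' @param het keep HETATM records of a PDB file (default FALSE).
#' @return data.frame with columns element, x, y, z.
#' @export
readAtoms <- function(path, het = FALSE) {
  if (!file.exists(path)) stop("cannot read ", path)
  if (grepl("\\.(pdb|ent)$", path, ignore.case = TRUE)) {
    pdb <- bio3d::read.pdb(path)
    a <- pdb$atom
    if (!het) a <- a[a$type == "ATOM", , drop = FALSE]
    el <- a$elesy
    if (is.null(el) || all(is.na(el)) || all(!nzchar(trimws(el))))
      el <- substr(trimws(a$elety), 1, 1)
    keep <- toupper(trimws(el)) != "H"
    data.frame(element = trimws(el)[keep], x = a$x[keep], y = a$y[keep],
               z = a$z[keep])
  } else {
    first <- readLines(path, n = 1)
    sep <- if (grepl(",", first)) "," else ""
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            comment.char = "#", stringsAsFactors = FALSE)
    need <- c("element", "x", "y", "z")
    if (!all(need %in% names(df)))
      stop("coordinate table must have columns element, x, y, z")
    df[, need]
  }
}
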