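# Small numerical kernels shared across the scattering models.

# sin(x)/x with a 6th-order series below |x| < 1e-3 to avoid cancellation.
sinc <- function(x) {
  out <- numeric(length(x))
  small <- abs(x) < 1e-3
  xs <- x[small]
  out[small] <- 1 - xs^2 / 6 + xs^4 / 120
  xl <- x[!small]
  out[!small] <- sin(xl) / xl
  out
}

# Normalized sphere amplitude 3[sin(u) - u cos(u)]/u^3, series below 1e-3.
sphereAmplitude <- function(u) {
  out <- numeric(length(u))
  small <- abs(u) < 1e-3
  us <- u[small]
  out[small] <- 1 - us^2 / 10 + us^4 / 280
  ul <- u[!small]
  out[!small] <- 3 * (sin(ul) - ul * cos(ul)) / ul^3
  out
}

# Cached Gauss-Legendre nodes/weights on [0, 1] (cos(alpha) variable of the
# orientational average; the sin(alpha) d(alpha) measure maps to d(cos alpha)).
.aucsas_env <- new.env(parent = emptyenv())

gaussLegendre01 <- function(n = 128L) {
  key <- paste0("gl", n)
  if (is.null(.aucsas_env[[key]])) {
    gl <- pracma::gaussLegendre(n, 0, 1)
    .aucsas_env[[key]] <- gl
  }
  .aucsas_env[[key]]
}

# Run `expr` under a temporarily seeded RNG, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

# Avogadro's number, mol^-1.
.NA_CONST <- 6.02214076e23

# Electron counts for the elements found in biomacromolecular coordinate
# files; used by rgFromAtomicCoordinates().
.ELECTRONS <- c(
  H = 1, D = 1, C = 6, N = 7, O = 8, F = 9, NA. = 11, MG = 12, P = 15, S = 16,
  CL = 17, K = 19, CA = 20, MN = 25, FE = 26, CO = 27, NI = 28, CU = 29,
  ZN = 30, SE = 34, BR = 35, I = 53
)

electronCount <- function(element) {
  key <- toupper(trimws(element))
  key[key == "NA"] <- "NA."
  z <- .ELECTRONS[key]
  if (anyNA(z)) {
    bad <- unique(element[is.na(z)])
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  }
  unname(z)
}
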