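#' Construct a Molecule
#'
#' Builds a \code{\linkS4class{Molecule}} from plain vectors.  Coordinates are
#' Cartesian Angstrom; no unit conversion happens anywhere in the package
#' (published EEM parameter conventions assume Angstrom).
#'
#' @param id molecule identifier string.
#' @param elements character vector of element symbols, one per atom.
#' @param coords numeric N x 3 matrix of coordinates (Angstrom).
#' @param bonds data.frame with columns \code{a}, \code{b} (1-based atom
#'   indices), \code{order} (1, 2 or 3) and optionally \code{aromatic}
#'   (logical, defaults to FALSE).  May be empty for an unbonded atom set.
#' @param formalCharges integer vector of per-atom formal charges (recycled
#'   scalar 0 by default).
#' @param totalCharge total molecular charge Q; defaults to the sum of the
#'   formal charges.
#' @return a \code{Molecule}.
#' @examples
#' m <- Molecule("water", c("O", "H", "H"),
#'               rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0)),
#'               data.frame(a = 1L, b = 2:3, order = 1L))
#' atomCount(m)
#' @export
Molecule <- function(id, elements, coords, bonds = NULL,
                     formalCharges = 0L, totalCharge = NULL) {
  coords <- matrix(as.numeric(coords), ncol = 3)
  n <- length(elements)
  stopifnot(nrow(coords) == n)
  formalCharges <- as.integer(rep_len(formalCharges, n))
  if (is.null(bonds) || NROW(bonds) == 0L) {
    bonds <- data.frame(a = integer(0), b = integer(0),
                        order = integer(0), aromatic = logical(0))
  } else {
    bonds <- as.data.frame(bonds)
    if (is.null(bonds$aromatic)) bonds$aromatic <- FALSE
    bonds <- data.frame(a = as.integer(bonds$a), b = as.integer(bonds$b),
                        order = as.integer(bonds$order),
                        aromatic = as.logical(bonds$aromatic))
  }
  atoms <- data.frame(element = as.character(elements),
                      x = coords[, 1], y = coords[, 2], z = coords[, 3],
                      formalCharge = formalCharges)
  if (is.null(totalCharge)) totalCharge <- sum(formalCharges)
  new("Molecule", id = as.character(id), atoms = atoms, bonds = bonds,
      totalCharge = as.numeric(totalCharge))
}

#' @rdname Molecule
#' @export
setMethod("atomCount", "Molecule", function(object) nrow(object@atoms))

#' @rdname Molecule
#' @export
setMethod("bondCount", "Molecule", function(object) nrow(object@bonds))

#' @rdname Molecule
#' @export
setMethod("moleculeId", "Molecule", function(object) object@id)

#' @rdname Molecule
#' @export
setMethod("atomCoords", "Molecule", function(object) {
  m <- as.matrix(object@atoms[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
})

#' @rdname Molecule
#' @export
setMethod("atomElements", "Molecule", function(object) object@atoms$element)

#' @rdname Molecule
#' @export
setMethod("formalCharges", "Molecule", function(object)
  object@atoms$formalCharge)

#' @rdname Molecule
#' @export
setMethod("totalCharge", "Molecule", function(object) object@totalCharge)

#' @rdname Molecule
#' @export
setMethod("show", "Molecule", function(object) {
  cat(sprintf("Molecule '%s': %d atoms, %d bonds, Q = %g\n",
              object@id, nrow(object@atoms), nrow(object@bonds),
              object@totalCharge))
  comp <- table(object@atoms$element)
  cat("  composition:",
      paste(sprintf("%s%d", names(comp), as.integer(comp)), collapse = " "),
      "\n")
  invisible(object)
})

#' @rdname distanceMatrix
#' @export
setMethod("distanceMatrix", "Molecule", function(object, minDist = 0.5) {
  D <- as.matrix(stats::dist(atomCoords(object)))
  dimnames(D) <- NULL
  diag(D) <- 0
  n <- nrow(D)
  if (n > 1L) {
    off <- D + diag(Inf, n)
    m <- which(off == min(off), arr.ind = TRUE)[1, ]
    if (off[m[1], m[2]] < minDist) {
      stop(sprintf(
        "degenerate geometry in molecule '%s': atoms %d and %d are %.4f A apart (< %.2f A)",
        object@id, min(m), max(m), off[m[1], m[2]], minDist))
    }
  }
  D
})
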