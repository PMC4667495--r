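#' @rdname Molecule
#' @param object a Molecule
#' @export
setGeneric("atomCount", function(object) standardGeneric("atomCount"))

#' @rdname Molecule
#' @export
setGeneric("bondCount", function(object) standardGeneric("bondCount"))

#' @rdname Molecule
#' @export
setGeneric("moleculeId", function(object) standardGeneric("moleculeId"))

#' @rdname Molecule
#' @export
setGeneric("atomCoords", function(object) standardGeneric("atomCoords"))

#' @rdname Molecule
#' @export
setGeneric("atomElements", function(object) standardGeneric("atomElements"))

#' @rdname Molecule
#' @export
setGeneric("formalCharges", function(object) standardGeneric("formalCharges"))

#' @rdname Molecule
#' @export
setGeneric("totalCharge", function(object) standardGeneric("totalCharge"))

#' Interatomic distance matrix
#'
#' Euclidean distances between all atom pairs of a molecule, in Angstrom.
#'
#' @param object a \code{Molecule}.
#' @param minDist minimum admissible off-diagonal distance (Angstrom);
#'   anything smaller is degenerate geometry and raises an error naming the
#'   atom pair.  The default 0.5 is below any physical bond length and guards
#'   against near-singular EEM matrices.
#' @return N x N symmetric numeric matrix with zero diagonal.
#' @export
setGeneric("distanceMatrix", function(object, minDist = 0.5)
  standardGeneric("distanceMatrix"))

#' @rdname EEMParameterSet
#' @param object an EEMParameterSet
#' @export
setGeneric("paramName", function(object) standardGeneric("paramName"))

#' @rdname EEMParameterSet
#' @export
setGeneric("paramKappa", function(object) standardGeneric("paramKappa"))

#' @rdname EEMParameterSet
#' @export
setGeneric("paramEntries", function(object) standardGeneric("paramEntries"))

#' @rdname ChargeResult
#' @param object a ChargeResult
#' @export
setGeneric("charges", function(object) standardGeneric("charges"))

#' @rdname ChargeResult
#' @export
setGeneric("chiBar", function(object) standardGeneric("chiBar"))
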