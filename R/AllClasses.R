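#' @import methods
NULL

.RECOGNISED_ELEMENTS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
  "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca",
  "Fe", "Zn", "Se", "Br", "I"
)

#' Molecule: atoms, bonds and total charge of one 3D structure
#'
#' An S4 container for a small molecule as EEM sees it: an ordered atom table
#' (element, Cartesian coordinates in Angstrom, integer formal charge), a bond
#' table (1-based atom indices, integer bond order 1-3, aromatic flag) and the
#' total molecular charge Q in elementary charges.  Aromatic input bonds are
#' stored with order 2 (see \code{\link{readSDF}}); only explicit bond
#' annotations are ever trusted, no aromaticity perception is run.
#'
#' @slot id character molecule identifier (SDF title line or record ordinal).
#' @slot atoms data.frame with columns \code{element}, \code{x}, \code{y},
#'   \code{z} (Angstrom) and \code{formalCharge} (integer e).
#' @slot bonds data.frame with columns \code{a}, \code{b} (1-based atom
#'   indices), \code{order} (integer in 1:3) and \code{aromatic} (logical).
#' @slot totalCharge numeric total molecular charge Q (elementary charges).
#'
#' @seealso \code{\link{Molecule}} constructor, \code{\link{readSDF}},
#'   \code{\link{distanceMatrix}}, \code{\link{assignAtomTypes}}
#' @exportClass Molecule
setClass("Molecule",
  representation(
    id = "character",
    atoms = "data.frame",
    bonds = "data.frame",
    totalCharge = "numeric"
  )
)

setValidity("Molecule", function(object) {
  msgs <- character(0)
  at <- object@atoms
  bd <- object@bonds
  need <- c("element", "x", "y", "z", "formalCharge")
  if (!all(need %in% names(at))) {
    return(paste("atoms must have columns", paste(need, collapse = ", ")))
  }
  if (nrow(at) < 1L) msgs <- c(msgs, "molecule must contain at least one atom")
  if (!all(grepl("^[A-Z][a-z]?$", at$element))) {
    msgs <- c(msgs, "element symbols must be IUPAC-style (e.g. 'C', 'Cl')")
  }
  if (!all(is.finite(c(at$x, at$y, at$z)))) {
    msgs <- c(msgs, "atom coordinates must be finite")
  }
  if (nrow(bd) > 0L) {
    needb <- c("a", "b", "order", "aromatic")
    if (!all(needb %in% names(bd))) {
      return(paste("bonds must have columns", paste(needb, collapse = ", ")))
    }
    if (any(bd$a == bd$b)) msgs <- c(msgs, "bond endpoints must differ")
    if (any(bd$a < 1L | bd$a > nrow(at) | bd$b < 1L | bd$b > nrow(at))) {
      msgs <- c(msgs, "bond atom index out of range")
    }
    if (!all(bd$order %in% 1:3)) msgs <- c(msgs, "bond order must be in {1,2,3}")
    if (any(bd$aromatic & bd$order != 2L)) {
      msgs <- c(msgs, "aromatic bonds must carry normalized order 2")
    }
    key <- paste(pmin(bd$a, bd$b), pmax(bd$a, bd$b))
    if (anyDuplicated(key)) msgs <- c(msgs, "duplicate bond between one atom pair")
  }
  if (length(object@id) != 1L) msgs <- c(msgs, "id must be a single string")
  if (length(object@totalCharge) != 1L || !is.finite(object@totalCharge)) {
    msgs <- c(msgs, "totalCharge must be a single finite number")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' EEM parameter set: global kappa plus per-atom-type (A, B)
#'
#' Holds the empirical parameters of the EEM model: the global distance
#' screening constant kappa and, for each atom type, the effective
#' electronegativity A and hardness B.  Atom-type keys are either specific
#' ("C2" = carbon with maximal bond order 2) or element-only wildcards ("C",
#' legacy sets parameterized for all bond orders).  When both exist the
#' specific key wins.  Only differences between A values affect charges
#' (gauge freedom); B must be positive for a solvable system.
#'
#' @slot name character set name.
#' @slot kappa numeric, positive screening constant.
#' @slot entries data.frame with columns \code{typeKey}, \code{A}, \code{B}.
#' @slot metadata named list of free-form provenance (e.g. reference charge
#'   scheme "B3LYP/6-311G/NPA").
#'
#' @seealso \code{\link{EEMParameterSet}} constructor,
#'   \code{\link{readParamset}}, \code{\link{validateParamset}},
#'   \code{\link{solveEEM}}
#' @exportClass EEMParameterSet
setClass("EEMParameterSet",
  representation(
    name = "character",
    kappa = "numeric",
    entries = "data.frame",
    metadata = "list"
  )
)

setValidity("EEMParameterSet", function(object) {
  msgs <- character(0)
  if (length(object@kappa) != 1L || !is.finite(object@kappa)) {
    msgs <- c(msgs, "kappa must be a single finite number")
  }
  en <- object@entries
  if (!all(c("typeKey", "A", "B") %in% names(en))) {
    return("entries must have columns typeKey, A, B")
  }
  if (nrow(en) > 0L) {
    ok <- grepl("^[A-Z][a-z]?[123]?$", en$typeKey)
    if (!all(ok)) {
      msgs <- c(msgs, paste("malformed type key(s):",
                            paste(en$typeKey[!ok], collapse = ", ")))
    }
    if (anyDuplicated(en$typeKey)) msgs <- c(msgs, "duplicate type key")
    if (!all(is.finite(en$A)) || !all(is.finite(en$B))) {
      msgs <- c(msgs, "A and B must be finite")
    }
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Charges and molecular electronegativity from one EEM solve
#'
#' @slot charges numeric vector of per-atom charges q (elementary charges),
#'   in atom order.
#' @slot chiBar numeric, the equalized molecular electronegativity solved
#'   alongside the charges.
#' @slot parameterSetName character, name of the parameter set used.
#'
#' @seealso \code{\link{solveEEM}}, \code{\link{writeCharges}}
#' @exportClass ChargeResult
setClass("ChargeResult",
  representation(
    charges = "numeric",
    chiBar = "numeric",
    parameterSetName = "character"
  )
)

setValidity("ChargeResult", function(object) {
  if (length(object@chiBar) != 1L) return("chiBar must be a single number")
  if (length(object@charges) < 1L) return("charges must be non-empty")
  if (!all(is.finite(object@charges))) return("charges must be finite")
  TRUE
})

#' Quality criteria of EEM charges against reference charges
#'
#' Pooled-over-atoms squared Pearson correlation, root mean square deviation
#' and mean absolute error between EEM and reference charges, together with
#' the pool size and the fraction of molecules the parameter set covered.
#'
#' @slot r2 numeric squared Pearson correlation (NA when undefined).
#' @slot rmsd numeric root mean square deviation, elementary charges.
#' @slot meanAbs numeric mean absolute error, elementary charges.
#' @slot nAtoms integer atoms pooled.
#' @slot nMolecules integer molecules pooled.
#' @slot coverageFraction numeric fraction of input molecules covered.
#' @slot r2Undefined logical, TRUE when either charge vector was constant.
#'
#' @seealso \code{\link{pooledQuality}}, \code{\link{validateOnTestSet}}
#' @exportClass QualityReport
setClass("QualityReport",
  representation(
    r2 = "numeric",
    rmsd = "numeric",
    meanAbs = "numeric",
    nAtoms = "integer",
    nMolecules = "integer",
    coverageFraction = "numeric",
    r2Undefined = "logical"
  )
)

setValidity("QualityReport", function(object) {
  msgs <- character(0)
  if (object@rmsd < 0 || object@meanAbs < 0) msgs <- c(msgs, "rmsd/meanAbs must be >= 0")
  if (!object@r2Undefined &&
      (object@r2 < -1e-12 || object@r2 > 1 + 1e-12)) {
    msgs <- c(msgs, "r2 must lie in [0,1]")
  }
  if (object@meanAbs > object@rmsd + 1e-9) {
    msgs <- c(msgs, "meanAbs cannot exceed rmsd")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' One training example for EEM parameterization
#'
#' A molecule together with per-atom reference charges (typically from a QM
#' population analysis) to which EEM parameters are fitted.
#'
#' @slot molecule a \code{Molecule}.
#' @slot refCharges numeric vector, one reference charge per atom.
#' @slot refChiBar numeric reference molecular electronegativity, or NA when
#'   the reference scheme provides none.  When every training example carries
#'   one, the parameterization anchors the absolute electronegativity scale
#'   (see \code{\link{fitLinearForKappa}}); EEM charges alone determine the
#'   parameters only up to a joint rescaling of (A, B, kappa).
#' @slot schemeLabel character label of the reference charge scheme.
#'
#' @seealso \code{\link{TrainingExample}} constructor,
#'   \code{\link{searchKappa}}
#' @exportClass TrainingExample
setClass("TrainingExample",
  representation(
    molecule = "Molecule",
    refCharges = "numeric",
    refChiBar = "numeric",
    schemeLabel = "character"
  )
)

setValidity("TrainingExample", function(object) {
  n <- nrow(object@molecule@atoms)
  if (length(object@refCharges) != n) {
    return("refCharges length must equal the atom count")
  }
  if (!all(is.finite(object@refCharges))) return("refCharges must be finite")
  if (length(object@refChiBar) != 1L) return("refChiBar must be a single value")
  gap <- abs(sum(object@refCharges) - object@molecule@totalCharge)
  if (gap > 0.01) {
    return(sprintf(
      "reference charges must conserve total charge (|sum q - Q| = %.4g > 0.01)",
      gap))
  }
  TRUE
})

#' Result of an EEM parameterization run
#'
#' @slot params fitted \code{EEMParameterSet}.
#' @slot quality \code{QualityReport} obtained by re-solving EEM with the
#'   fitted set on the training molecules (charge space, never the regression
#'   residual).
#' @slot kappaTrace data.frame with columns \code{kappa}, \code{objective},
#'   \code{stage} ("grid", "refine") recording every kappa evaluated.
#' @slot warnings character vector of fit warnings (rank deficiency, sparse
#'   types, excluded molecules).
#'
#' @seealso \code{\link{searchKappa}}
#' @exportClass FitResult
setClass("FitResult",
  representation(
    params = "EEMParameterSet",
    quality = "QualityReport",
    kappaTrace = "data.frame",
    warnings = "character"
  )
)

#' Coverage of a molecule collection by an EEM parameter set
#'
#' @slot total integer molecules examined (readable records).
#' @slot covered integer molecules whose every atom type resolves in the set.
#' @slot fraction numeric covered/total (0 when total is 0; see
#'   \code{emptyInput}).
#' @slot missingTypeTally named integer: for each unresolved type key, the
#'   number of molecules it excluded.
#' @slot unreadable integer records that failed to parse (counted separately;
#'   coverage is about atom types, not file hygiene).
#' @slot emptyInput logical flag set when no molecule was examined.
#'
#' @seealso \code{\link{coverageReport}}, \code{\link{moleculeIsCovered}}
#' @exportClass CoverageReport
setClass("CoverageReport",
  representation(
    total = "integer",
    covered = "integer",
    fraction = "numeric",
    missingTypeTally = "integer",
    unreadable = "integer",
    emptyInput = "logical"
  )
)

setValidity("CoverageReport", function(object) {
  if (object@covered > object@total) return("covered cannot exceed total")
  TRUE
})

#' Configuration of the kappa search
#'
#' @slot kappaGrid numeric c(lo, hi, step) coarse grid for kappa.
#' @slot refineTol numeric golden-section bracket width target.
#' @slot minAtomsPerType integer minimum atoms required to fit one type.
#' @slot objective character, "max_pooled_r2" or "min_pooled_rmsd".
#'
#' @seealso \code{\link{fitConfig}}, \code{\link{searchKappa}}
#' @exportClass FitConfig
setClass("FitConfig",
  representation(
    kappaGrid = "numeric",
    refineTol = "numeric",
    minAtomsPerType = "integer",
    objective = "character"
  )
)

setValidity("FitConfig", function(object) {
  g <- object@kappaGrid
  if (length(g) != 3L || g[1] <= 0 || g[3] <= 0 || g[2] <= g[1]) {
    return("kappaGrid must be c(lo, hi, step) with lo > 0, step > 0, hi > lo")
  }
  if (object@refineTol <= 0) return("refineTol must be positive")
  if (!object@objective %in% c("max_pooled_r2", "min_pooled_rmsd")) {
    return("objective must be 'max_pooled_r2' or 'min_pooled_rmsd'")
  }
  TRUE
})

#' Configuration of the synthetic molecule generator
#'
#' @slot seed integer master seed; per-molecule streams are derived from it
#'   so earlier molecules are unchanged when nMolecules grows.
#' @slot nMolecules integer number of molecules to generate.
#' @slot atomsRange integer c(min, max) atoms per molecule.
#' @slot elementPool data.frame with columns \code{element}, \code{order},
#'   \code{weight}: the (element, maximal bond order) pairs sampled and their
#'   relative frequencies.
#' @slot minPairDistance numeric minimum distance between any atom pair, Angstrom.
#' @slot bondLengthRange numeric c(lo, hi) bonded-pair distance range, Angstrom.
#' @slot chargeNoiseSigma numeric sd of Gaussian noise added to reference
#'   charges (projected back onto the conservation hyperplane), elementary charges.
#' @slot paramRanges list with elements \code{A}, \code{B}, \code{kappa}, each
#'   c(lo, hi), from which ground-truth parameters are drawn.
#'
#' @seealso \code{\link{generatorConfig}}, \code{\link{makeMolecule}},
#'   \code{\link{makeGroundTruth}}
#' @exportClass GeneratorConfig
setClass("GeneratorConfig",
  representation(
    seed = "integer",
    nMolecules = "integer",
    atomsRange = "integer",
    elementPool = "data.frame",
    minPairDistance = "numeric",
    bondLengthRange = "numeric",
    chargeNoiseSigma = "numeric",
    paramRanges = "list"
  )
)

setValidity("GeneratorConfig", function(object) {
  msgs <- character(0)
  if (object@atomsRange[1] < 1L || object@atomsRange[2] < object@atomsRange[1]) {
    msgs <- c(msgs, "atomsRange must be c(min, max) with 1 <= min <= max")
  }
  ep <- object@elementPool
  if (!all(c("element", "order", "weight") %in% names(ep))) {
    return("elementPool must have columns element, order, weight")
  }
  if (any(ep$weight <= 0)) msgs <- c(msgs, "pool weights must be positive")
  if (!all(ep$order %in% 1:3)) msgs <- c(msgs, "pool orders must be in {1,2,3}")
  if (object@bondLengthRange[1] >= object@bondLengthRange[2]) {
    msgs <- c(msgs, "bondLengthRange must be c(lo, hi) with lo < hi")
  }
  if (object@chargeNoiseSigma < 0) msgs <- c(msgs, "chargeNoiseSigma must be >= 0")
  for (nm in c("A", "B", "kappa")) {
    r <- object@paramRanges[[nm]]
    if (is.null(r) || length(r) != 2L || r[1] >= r[2]) {
      msgs <- c(msgs, sprintf("paramRanges$%s must be c(lo, hi) with lo < hi", nm))
    }
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})
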