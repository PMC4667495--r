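## Seeded generator of geometrically plausible molecules, ground-truth
## parameter sets and reference charges.  Geometry is plausibility-only
## (distance constraints): EEM depends only on distances, atom types and the
## total charge, so valence-level realism is deliberately not pursued.

#' Default (element, order) sampling pool
#'
#' The 17 atom types of drug-like training sets with their relative
#' frequencies (hydrogens dominate, then aromatic/double-bonded and single-
#' bonded carbon, then oxygen; halogens, phosphorus and sulphur are rare).
#'
#' @return data.frame with columns \code{element}, \code{order},
#'   \code{weight}.
#' @export
defaultElementPool <- function() {
  data.frame(
    element = c("H", "C", "C", "C", "N", "N", "N", "O", "O", "F",
                "P", "P", "S", "S", "Cl", "Br", "I"),
    order = c(1L, 1L, 2L, 3L, 1L, 2L, 3L, 1L, 2L, 1L,
              1L, 2L, 1L, 2L, 1L, 1L, 1L),
    weight = c(57119, 15220, 38097, 345, 4151, 3383, 345, 5016, 5793, 938,
               153, 251, 1034, 1391, 1084, 336, 1734))
}

#' Construct a generator configuration
#'
#' One master seed deterministically derives per-molecule RNG streams, so
#' growing \code{nMolecules} never reshuffles earlier molecules.
#'
#' @param seed integer master seed.
#' @param nMolecules molecules to generate.
#' @param atomsRange c(min, max) atoms per molecule.
#' @param elementPool data.frame(element, order, weight); defaults to
#'   \code{\link{defaultElementPool}}.
#' @param minPairDistance minimum distance between any two atoms (Angstrom).
#' @param bondLengthRange c(lo, hi) admissible bonded-pair distance (Angstrom).
#' @param chargeNoiseSigma sd of Gaussian noise added to reference charges
#'   (projected back onto the conservation hyperplane), elementary charges.
#' @param paramRanges list(A =, B =, kappa =) of c(lo, hi) ranges for
#'   ground-truth parameter sampling.
#' @return a \code{\linkS4class{GeneratorConfig}}.
#' @export
generatorConfig <- function(seed = 1L, nMolecules = 100L,
                            atomsRange = c(3L, 30L),
                            elementPool = defaultElementPool(),
                            minPairDistance = 1.0,
                            bondLengthRange = c(1.0, 1.8),
                            chargeNoiseSigma = 0,
                            paramRanges = list(A = c(1.5, 4.0),
                                               B = c(0.3, 1.6),
                                               kappa = c(0.1, 0.9))) {
  new("GeneratorConfig", seed = as.integer(seed),
      nMolecules = as.integer(nMolecules),
      atomsRange = as.integer(atomsRange),
      elementPool = elementPool,
      minPairDistance = as.numeric(minPairDistance),
      bondLengthRange = as.numeric(bondLengthRange),
      chargeNoiseSigma = as.numeric(chargeNoiseSigma),
      paramRanges = paramRanges)
}

## deterministic 32-bit stream derivation from (master seed, stream, item)
.derive_seed <- function(seed, stream, item) {
  as.integer((as.numeric(seed) * 48271 + stream * 1299721 + item * 7919) %%
               2147483587)
}

## evaluate expr under a local RNG state; global .Random.seed is untouched
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.rand_unit <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-8) return(v / n)
  }
}

## one generation attempt; NULL on embedding failure
.try_make_molecule <- function(config, index, attempt) {
  rng <- .derive_seed(config@seed, 1, index * 101 + attempt)
  .with_seed(rng, {
    nRange <- seq(config@atomsRange[1], config@atomsRange[2])
    n <- if (length(nRange) == 1L) nRange else sample(nRange, 1L)
    pool <- config@elementPool
    pick <- sample(nrow(pool), n, replace = TRUE, prob = pool$weight)
    element <- pool$element[pick]
    order <- pool$order[pick]
    ## feasibility fix-ups: a lone triple-bond atom has no order-3 partner,
    ## a lone double-bond atom (with no order-3 atoms) has no order-2 partner
    if (n == 1L) order[] <- 1L
    while (sum(order == 3L) == 1L) order[order == 3L] <- 2L
    if (sum(order == 3L) == 0L && sum(order == 2L) == 1L) order[order == 2L] <- 1L
    o3 <- which(order == 3L); o2 <- which(order == 2L); o1 <- which(order == 1L)
    placeOrder <- c(o3, o2, o1)
    ba <- integer(0); bb <- integer(0); bo <- integer(0)
    for (j in seq_along(o3)[-1]) {
      p <- o3[sample.int(j - 1L, 1L)]
      ba <- c(ba, p); bb <- c(bb, o3[j]); bo <- c(bo, 3L)
    }
    for (j in seq_along(o2)) {
      anchors <- c(o3, o2[seq_len(j - 1L)])
      if (length(anchors) == 0L) next   # first multi atom is the root
      p <- anchors[sample.int(length(anchors), 1L)]
      ba <- c(ba, p); bb <- c(bb, o2[j]); bo <- c(bo, 2L)
    }
    placed <- c(o3, o2)
    for (j in seq_along(o1)) {
      anchors <- c(placed, o1[seq_len(j - 1L)])
      if (length(anchors) == 0L) next
      p <- anchors[sample.int(length(anchors), 1L)]
      ba <- c(ba, p); bb <- c(bb, o1[j]); bo <- c(bo, 1L)
    }
    ## stochastic embedding along the spanning tree
    parent <- integer(n)
    for (k in seq_along(ba)) parent[bb[k]] <- ba[k]
    coords <- matrix(NA_real_, n, 3)
    coords[placeOrder[1], ] <- 0
    ok <- TRUE
    for (j in seq_along(placeOrder)[-1]) {
      i <- placeOrder[j]
      ppos <- coords[parent[i], ]
      good <- FALSE
      for (try in seq_len(300L)) {
        len <- stats::runif(1, config@bondLengthRange[1], config@bondLengthRange[2])
        pos <- ppos + len * .rand_unit()
        prev <- coords[placeOrder[seq_len(j - 1L)], , drop = FALSE]
        d2 <- rowSums((prev - matrix(pos, nrow(prev), 3, byrow = TRUE))^2)
        if (min(d2) >= config@minPairDistance^2) { good <- TRUE; break }
      }
      if (!good) { ok <- FALSE; break }
      coords[i, ] <- pos
    }
    if (!ok) return(NULL)
    ## extra ring-closing bonds: pairs whose embedded distance already lies
    ## in the bond-length window may gain an order-1 bond
    bonded <- paste(pmin(ba, bb), pmax(ba, bb))
    if (n > 2L) {
      D <- as.matrix(stats::dist(coords))
      for (i in seq_len(n - 1L)) {
        for (k in seq(i + 1L, n)) {
          if (D[i, k] >= config@bondLengthRange[1] &&
              D[i, k] <= config@bondLengthRange[2] &&
              !(paste(i, k) %in% bonded) &&
              stats::runif(1) < 0.3) {
            ba <- c(ba, i); bb <- c(bb, k); bo <- c(bo, 1L)
            bonded <- c(bonded, paste(i, k))
          }
        }
      }
    }
    Molecule(sprintf("synth_%d", index), element, coords,
             data.frame(a = ba, b = bb, order = bo))
  })
}

#' Generate one synthetic molecule
#'
#' Samples (element, maximal bond order) pairs from the pool, builds a
#' connected random spanning tree (plus occasional ring-closing order-1
#' bonds) whose bond orders reproduce the sampled types exactly under
#' \code{\link{assignAtomTypes}}, and embeds it in 3D so that bonded pairs
#' fall in the bond-length window and all pairs stay at least
#' \code{minPairDistance} apart.  Total charge is 0.  Repeated calls with
#' the same config and index return bit-identical molecules.
#'
#' @param config a \code{\link{generatorConfig}}.
#' @param index 1-based molecule index (selects the derived RNG stream).
#' @return a \code{Molecule}.
#' @export
makeMolecule <- function(config, index = 1L) {
  for (attempt in seq_len(30L)) {
    m <- .try_make_molecule(config, index, attempt)
    if (!is.null(m)) return(m)
  }
  stop(sprintf(
    "embedding failed for molecule %d after 30 restarts; loosen minPairDistance or bondLengthRange",
    index))
}

#' Generate a list of synthetic molecules
#'
#' @param config a \code{\link{generatorConfig}}.
#' @return list of \code{nMolecules} \code{Molecule} objects.
#' @export
makeMolecules <- function(config) {
  lapply(seq_len(config@nMolecules), function(i) makeMolecule(config, i))
}

#' Generate a ground-truth parameter set and training examples
#'
#' Samples ground-truth (A*, B*, kappa*) for every type in the pool from
#' \code{paramRanges}, generates \code{nMolecules} molecules and computes
#' their reference charges — and reference molecular electronegativities,
#' which anchor the parameter scale during fitting — by solving EEM under
#' the truth.  With
#' \code{chargeNoiseSigma > 0}, i.i.d. Gaussian noise is added and projected
#' back onto the conservation hyperplane (the noise mean is subtracted), so
#' the total charge is conserved exactly.  The rare molecule whose EEM
#' system is ill-conditioned under the truth is re-generated from the next
#' attempt of its own stream, keeping the run deterministic.
#'
#' @param config a \code{\link{generatorConfig}}.
#' @param trueKappa optional fixed ground-truth kappa (sampled from
#'   \code{paramRanges$kappa} when NULL).
#' @param trueParams optional complete \code{EEMParameterSet} to use as the
#'   truth (overrides sampling and \code{trueKappa}).
#' @return list with \code{params} (the ground-truth
#'   \code{EEMParameterSet}) and \code{examples} (list of
#'   \code{\linkS4class{TrainingExample}}).
#' @export
makeGroundTruth <- function(config, trueKappa = NULL, trueParams = NULL) {
  pool <- config@elementPool
  keys <- unique(paste0(pool$element, pool$order))
  if (is.null(trueParams)) {
    pr <- config@paramRanges
    truth <- .with_seed(.derive_seed(config@seed, 2, 0), {
      k <- if (is.null(trueKappa)) {
        stats::runif(1, pr$kappa[1], pr$kappa[2])
      } else {
        as.numeric(trueKappa)
      }
      EEMParameterSet("ground_truth", k,
                      data.frame(typeKey = keys,
                                 A = stats::runif(length(keys), pr$A[1], pr$A[2]),
                                 B = stats::runif(length(keys), pr$B[1], pr$B[2])),
                      metadata = list(scheme = "synthetic"))
    })
  } else {
    truth <- trueParams
  }
  examples <- vector("list", config@nMolecules)
  for (i in seq_len(config@nMolecules)) {
    res <- NULL
    for (attempt in seq_len(30L)) {
      m <- .try_make_molecule(config, i, attempt)
      if (is.null(m)) next
      r <- tryCatch(solveEEM(m, truth), error = function(e) NULL)
      if (!is.null(r)) { res <- list(m = m, r = r); break }
    }
    if (is.null(res)) {
      stop(sprintf("could not generate a solvable molecule for stream %d", i))
    }
    q <- res$r@charges
    if (config@chargeNoiseSigma > 0) {
      q <- .with_seed(.derive_seed(config@seed, 3, i), {
        e <- stats::rnorm(length(q), 0, config@chargeNoiseSigma)
        q + (e - mean(e))
      })
    }
    examples[[i]] <- TrainingExample(res$m, q, refChiBar = res$r@chiBar,
                                     schemeLabel = "synthetic")
  }
  list(params = truth, examples = examples)
}
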