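## Quality criteria comparing EEM charges with reference (QM) charges:
## squared Pearson correlation R^2, root mean square deviation, and mean
## absolute error, pooled over atoms.

.as_pair <- function(qEEM, qRef) {
  qEEM <- as.numeric(qEEM); qRef <- as.numeric(qRef)
  if (length(qEEM) != length(qRef) || length(qEEM) < 1L) {
    stop("charge vectors must have equal, positive length")
  }
  list(e = qEEM, r = qRef)
}

#' Squared Pearson correlation between EEM and reference charges
#'
#' Symmetric in its two arguments and invariant to affine rescaling of
#' either.  A constant vector leaves the correlation undefined: this is an
#' error (not 0, not 1) — use \code{\link{pooledQuality}} for the flagged
#' variant.
#'
#' @param qEEM numeric vector of EEM charges.
#' @param qRef numeric vector of reference charges, same length.
#' @return squared Pearson correlation in [0, 1].
#' @export
rSquared <- function(qEEM, qRef) {
  p <- .as_pair(qEEM, qRef)
  if (stats::sd(p$e) == 0 || stats::sd(p$r) == 0) {
    stop("undefined statistic: squared correlation with a constant charge vector")
  }
  stats::cor(p$e, p$r)^2
}

#' Root mean square deviation between EEM and reference charges
#'
#' sqrt(sum((qEEM - qRef)^2) / N) with N the number of atoms pooled.
#'
#' @inheritParams rSquared
#' @return RMSD in elementary charges, >= 0.
#' @export
rmsd <- function(qEEM, qRef) {
  p <- .as_pair(qEEM, qRef)
  sqrt(mean((p$e - p$r)^2))
}

#' Mean absolute deviation between EEM and reference charges
#'
#' sum(|qEEM - qRef|) / N.  Always <= the RMSD of the same pair.
#'
#' @inheritParams rSquared
#' @return mean absolute error in elementary charges, >= 0.
#' @export
meanAbsDev <- function(qEEM, qRef) {
  p <- .as_pair(qEEM, qRef)
  mean(abs(p$e - p$r))
}

#' Pooled quality criteria over many molecules
#'
#' Concatenates the atoms of all supplied charge pairs and computes one
#' R^2 / RMSD / mean-absolute-error triple over the pool (the headline,
#' set-level aggregation).  Atoms of uncovered molecules never enter: the
#' caller passes only covered pairs and the coverage fraction.
#'
#' @param pairs list of pairs; each element is a list with numeric elements
#'   \code{qEEM} and \code{qRef} of equal length (a \code{moleculeId} entry
#'   is carried along but unused here).
#' @param coverageFraction fraction of input molecules covered (1 by
#'   default; populated by \code{\link{validateOnTestSet}}).
#' @return a \code{\linkS4class{QualityReport}}.  When either pooled vector
#'   is constant, R^2 is NA with the \code{r2Undefined} flag set.
#' @export
pooledQuality <- function(pairs, coverageFraction = 1) {
  if (length(pairs) < 1L) stop("pooledQuality needs at least one charge pair")
  e <- unlist(lapply(pairs, function(p) .as_pair(p$qEEM, p$qRef)$e),
              use.names = FALSE)
  r <- unlist(lapply(pairs, function(p) p$qRef), use.names = FALSE)
  undef <- (stats::sd(e) == 0 || stats::sd(r) == 0)
  new("QualityReport",
      r2 = if (undef) NA_real_ else stats::cor(e, r)^2,
      rmsd = sqrt(mean((e - r)^2)),
      meanAbs = mean(abs(e - r)),
      nAtoms = length(e),
      nMolecules = length(pairs),
      coverageFraction = as.numeric(coverageFraction),
      r2Undefined = undef)
}

#' @rdname QualityReport
#' @param object a QualityReport
#' @export
setMethod("show", "QualityReport", function(object) {
  cat(sprintf(
    "QualityReport: R2 = %s, RMSD = %.4f e, meanAbs = %.4f e (%d atoms, %d molecules, coverage %.3f)\n",
    if (object@r2Undefined) "undefined" else sprintf("%.4f", object@r2),
    object@rmsd, object@meanAbs, object@nAtoms, object@nMolecules,
    object@coverageFraction))
  invisible(object)
})

#' Per-molecule quality distribution summary
#'
#' Alongside the pooled headline numbers, summarizes the distribution of
#' per-molecule R^2 / RMSD / mean-absolute-error (min, quartiles, max).
#' Molecules with constant charge vectors are skipped for R^2 and counted.
#'
#' @inheritParams pooledQuality
#' @return data.frame with one row per statistic and columns min, q25,
#'   median, q75, max, n.
#' @export
perMoleculeQuality <- function(pairs) {
  if (length(pairs) < 1L) stop("perMoleculeQuality needs at least one charge pair")
  r2s <- numeric(0); rms <- numeric(0); mad_ <- numeric(0)
  for (p in pairs) {
    pe <- .as_pair(p$qEEM, p$qRef)
    rms <- c(rms, sqrt(mean((pe$e - pe$r)^2)))
    mad_ <- c(mad_, mean(abs(pe$e - pe$r)))
    if (stats::sd(pe$e) > 0 && stats::sd(pe$r) > 0) {
      r2s <- c(r2s, stats::cor(pe$e, pe$r)^2)
    }
  }
  qs <- function(x) {
    if (!length(x)) return(c(NA, NA, NA, NA, NA, 0))
    c(unname(stats::quantile(x, c(0, 0.25, 0.5, 0.75, 1))), length(x))
  }
  out <- rbind(r2 = qs(r2s), rmsd = qs(rms), meanAbs = qs(mad_))
  colnames(out) <- c("min", "q25", "median", "q75", "max", "n")
  as.data.frame(out)
}

#' Write a quality report table as TSV
#'
#' One row per parameter set: set_name, r2, rmsd, mean_abs, coverage.
#'
#' @param reports named list of \code{QualityReport} (names are set names).
#' @param file output path or connection.
#' @export
writeQualityTable <- function(reports, file) {
  df <- data.frame(
    set_name = names(reports),
    r2 = vapply(reports, function(r) r@r2, numeric(1)),
    rmsd = vapply(reports, function(r) r@rmsd, numeric(1)),
    mean_abs = vapply(reports, function(r) r@meanAbs, numeric(1)),
    coverage = vapply(reports, function(r) r@coverageFraction, numeric(1)))
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
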