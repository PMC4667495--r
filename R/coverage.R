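#' Can a parameter set handle a molecule?
#'
#' TRUE iff every atom's type resolves in the set under the shared
#' resolution rule (specific key first, then bare-element wildcard) — exactly
#' the condition under which \code{\link{solveEEM}} does not raise a
#' missing-parameter error.
#'
#' @param m a \code{Molecule}.
#' @param P an \code{EEMParameterSet}.
#' @return list with \code{covered} (logical) and \code{missingTypes}
#'   (character vector of distinct unresolved type keys, empty when covered).
#' @export
moleculeIsCovered <- function(m, P) {
  ty <- assignAtomTypes(m)
  idx <- resolveTypeKeys(ty, P)
  miss <- sort(unique(ty[is.na(idx)]))
  list(covered = length(miss) == 0L, missingTypes = miss)
}

#' Coverage of a molecule collection by a parameter set
#'
#' Single pass over the collection, constant memory per molecule, tallying
#' which missing atom types excluded how many molecules.  Unreadable SDF
#' records are counted separately, never silently dropped: coverage is about
#' atom types, not file hygiene.
#'
#' @param molecules list of \code{Molecule}, or a path to an SDF file
#'   (scanned record by record with \code{\link{readSDFRecords}}).
#' @param P an \code{EEMParameterSet}.
#' @return a \code{\linkS4class{CoverageReport}}.
#' @examples
#' p <- EEMParameterSet("toy", 0.44,
#'        data.frame(typeKey = c("H1", "C1"), A = c(2.4, 2.5),
#'                   B = c(0.96, 0.6)))
#' eth <- Molecule("ethane-heavy", c("C", "C"),
#'                 rbind(c(0, 0, 0), c(1.54, 0, 0)),
#'                 data.frame(a = 1L, b = 2L, order = 1L))
#' coverageReport(list(eth), p)
#' @export
coverageReport <- function(molecules, P) {
  errs <- character(0)
  if (is.character(molecules) && length(molecules) == 1L) {
    recs <- readSDFRecords(file = molecules, keepErrors = TRUE)
    molecules <- recs$molecules
    errs <- recs$errors
  }
  if (is(molecules, "Molecule")) molecules <- list(molecules)
  total <- 0L
  covered <- 0L
  tally <- integer(0)
  for (m in molecules) {
    total <- total + 1L
    cv <- moleculeIsCovered(m, P)
    if (cv$covered) {
      covered <- covered + 1L
    } else {
      for (k in cv$missingTypes) {
        if (is.na(tally[k])) tally[k] <- 0L
        tally[k] <- tally[k] + 1L
      }
    }
  }
  new("CoverageReport",
      total = total, covered = covered,
      fraction = if (total > 0L) covered / total else 0,
      missingTypeTally = tally,
      unreadable = length(errs),
      emptyInput = total == 0L)
}

#' @rdname CoverageReport
#' @param object a CoverageReport
#' @export
setMethod("show", "CoverageReport", function(object) {
  if (object@emptyInput) {
    cat("CoverageReport: empty input (no molecules examined)\n")
    return(invisible(object))
  }
  cat(sprintf("CoverageReport: %d/%d molecules covered (%.1f %%), %d unreadable record(s)\n",
              object@covered, object@total, 100 * object@fraction,
              object@unreadable))
  if (length(object@missingTypeTally)) {
    t <- sort(object@missingTypeTally, decreasing = TRUE)
    cat("  missing types:",
        paste(sprintf("%s (%d)", names(t), t), collapse = ", "), "\n")
  }
  invisible(object)
})

#' Write a coverage report row as TSV
#'
#' Columns set_name, total, covered, fraction, unreadable, top_missing_types.
#'
#' @param report a \code{CoverageReport}.
#' @param setName parameter-set name for the first column.
#' @param file output path or connection.
#' @export
writeCoverageTable <- function(report, setName, file) {
  t <- sort(report@missingTypeTally, decreasing = TRUE)
  top <- paste(utils::head(sprintf("%s:%d", names(t), t), 5L), collapse = ",")
  df <- data.frame(set_name = setName, total = report@total,
                   covered = report@covered, fraction = report@fraction,
                   unreadable = report@unreadable,
                   top_missing_types = if (nzchar(top)) top else "-")
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
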