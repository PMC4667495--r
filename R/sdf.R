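## MDL SDF V2000 reading/writing.  Only explicit annotations are trusted:
## aromatic bond type 4 is normalized to order 2 with the aromatic flag set
## (aromatic atoms belong to X2 types); Kekule single bonds in rings are NOT
## promoted.  V3000 records are rejected.

.fw <- function(line, from, to) {
  if (nchar(line) < from) "" else trimws(substr(line, from, min(to, nchar(line))))
}

.parse_int <- function(s) suppressWarnings(as.integer(s))
.parse_num <- function(s) suppressWarnings(as.numeric(s))

## old-style atom-block charge codes (column 37-39): 0 none, 1 +3, 2 +2,
## 3 +1, 4 doublet radical (charge 0), 5 -1, 6 -2, 7 -3
.CHARGE_CODE <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
                  `5` = -1L, `6` = -2L, `7` = -3L)

#' Read molecules from an MDL SDF (V2000) file
#'
#' Parses zero or more concatenated V2000 records.  Coordinates are taken
#' verbatim (Angstrom).  Bond type 4 (aromatic dialect) is normalized to
#' order 2 with the aromatic flag set; bond types outside \{1,2,3,4\} are a
#' parse error.  \code{M  CHG} property lines populate formal charges and,
#' when present, supersede the atom-block charge column.  The molecule id is
#' the title line, or the record ordinal when the title is blank.
#'
#' @param file path to an SDF file (ignored when \code{text} is given).
#' @param text optional character vector of lines (or a single string with
#'   embedded newlines) to parse instead of a file.
#' @return list of \code{\linkS4class{Molecule}}.
#' @seealso \code{\link{writeSDF}}, \code{\link{readSDFRecords}} for the
#'   error-tolerant variant used by coverage scans.
#' @export
readSDF <- function(file = NULL, text = NULL) {
  recs <- readSDFRecords(file = file, text = text, keepErrors = FALSE)
  recs$molecules
}

#' Read SDF records, keeping per-record parse errors
#'
#' Like \code{\link{readSDF}} but, with \code{keepErrors = TRUE}, a malformed
#' record does not abort the scan: it is recorded as unreadable (with its
#' message) and parsing resumes at the next record terminator.  Used by
#' \code{\link{coverageReport}}, where coverage is about atom types, not file
#' hygiene.
#'
#' @inheritParams readSDF
#' @param keepErrors logical; FALSE turns the first record error into a stop().
#' @return list with elements \code{molecules} (list of Molecule) and
#'   \code{errors} (character vector, one message per unreadable record).
#' @export
readSDFRecords <- function(file = NULL, text = NULL, keepErrors = TRUE) {
  if (is.null(text)) {
    stopifnot(!is.null(file))
    lines <- readLines(file, warn = FALSE)
  } else {
    lines <- strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE)[[1]]
  }
  mols <- list()
  errs <- character(0)
  p <- 1L
  ordinal <- 0L
  nL <- length(lines)
  while (p <= nL) {
    ## skip stray blank lines between records
    while (p <= nL && !nzchar(trimws(lines[p])) &&
           (p + 3L > nL || !nzchar(trimws(paste(lines[p:min(p + 3L, nL)], collapse = ""))))) {
      p <- p + 1L
    }
    if (p > nL) break
    if (all(!nzchar(trimws(lines[p:nL])))) break
    ordinal <- ordinal + 1L
    res <- tryCatch(.parse_sdf_record(lines, p, ordinal),
                    error = function(e) e)
    if (inherits(res, "error")) {
      if (!keepErrors) stop(res)
      errs <- c(errs, conditionMessage(res))
      ## resync: jump past the next "$$$$" line (or to EOF)
      term <- p
      while (term <= nL && !startsWith(lines[term], "$$$$")) term <- term + 1L
      p <- term + 1L
    } else {
      mols[[length(mols) + 1L]] <- res$molecule
      p <- res$next_line
    }
  }
  list(molecules = mols, errors = errs)
}

.parse_sdf_record <- function(lines, p, ordinal) {
  nL <- length(lines)
  if (p + 3L > nL) {
    stop(sprintf("record %d: unterminated record (header truncated at line %d)",
                 ordinal, nL))
  }
  title <- trimws(lines[p])
  counts <- lines[p + 3L]
  if (grepl("V3000", counts, fixed = TRUE)) {
    stop(sprintf("record %d (line %d): V3000 records are not supported",
                 ordinal, p + 3L))
  }
  na <- .parse_int(.fw(counts, 1, 3))
  nb <- .parse_int(.fw(counts, 4, 6))
  if (is.na(na) || is.na(nb) || na < 0L || nb < 0L) {
    stop(sprintf("record %d (line %d): malformed counts line '%s'",
                 ordinal, p + 3L, counts))
  }
  if (p + 3L + na + nb > nL) {
    stop(sprintf("record %d: unterminated record (atom/bond block runs past end of input)",
                 ordinal))
  }
  elements <- character(na)
  coords <- matrix(0, na, 3)
  oldChg <- integer(na)
  for (i in seq_len(na)) {
    ln <- lines[p + 3L + i]
    x <- .parse_num(.fw(ln, 1, 10))
    y <- .parse_num(.fw(ln, 11, 20))
    z <- .parse_num(.fw(ln, 21, 30))
    el <- .fw(ln, 32, 34)
    if (anyNA(c(x, y, z)) || !nzchar(el)) {
      stop(sprintf("record %d (line %d): malformed atom line '%s'",
                   ordinal, p + 3L + i, ln))
    }
    elements[i] <- el
    coords[i, ] <- c(x, y, z)
    code <- .parse_int(.fw(ln, 37, 39))
    if (!is.na(code) && as.character(code) %in% names(.CHARGE_CODE)) {
      oldChg[i] <- .CHARGE_CODE[[as.character(code)]]
    }
  }
  ba <- integer(nb); bb <- integer(nb); bo <- integer(nb); bar <- logical(nb)
  for (i in seq_len(nb)) {
    ln <- lines[p + 3L + na + i]
    a <- .parse_int(.fw(ln, 1, 3))
    b <- .parse_int(.fw(ln, 4, 6))
    t <- .parse_int(.fw(ln, 7, 9))
    if (anyNA(c(a, b, t))) {
      stop(sprintf("record %d (line %d): malformed bond line '%s'",
                   ordinal, p + 3L + na + i, ln))
    }
    if (a < 1L || a > na || b < 1L || b > na) {
      stop(sprintf("record %d (line %d): bond references atom %d of %d",
                   ordinal, p + 3L + na + i, max(a, b), na))
    }
    if (!t %in% c(1L, 2L, 3L, 4L)) {
      stop(sprintf("record %d (line %d): bond type %d outside {1,2,3,4}",
                   ordinal, p + 3L + na + i, t))
    }
    ba[i] <- a; bb[i] <- b
    if (t == 4L) { bo[i] <- 2L; bar[i] <- TRUE } else bo[i] <- t
  }
  ## property block up to M  END
  q <- p + 4L + na + nb
  chgPairs <- NULL
  sawEnd <- FALSE
  while (q <= nL) {
    ln <- lines[q]
    if (startsWith(ln, "M  END")) { sawEnd <- TRUE; q <- q + 1L; break }
    if (startsWith(ln, "$$$$")) break
    if (startsWith(ln, "M  CHG")) {
      tok <- strsplit(trimws(substr(ln, 7, nchar(ln))), "\\s+")[[1]]
      vals <- .parse_int(tok)
      if (anyNA(vals) || length(vals) < 3L || (length(vals) - 1L) %% 2L != 0L) {
        stop(sprintf("record %d (line %d): malformed M  CHG line", ordinal, q))
      }
      idx <- vals[seq(2L, length(vals), by = 2L)]
      chg <- vals[seq(3L, length(vals), by = 2L)]
      if (any(idx < 1L | idx > na)) {
        stop(sprintf("record %d (line %d): M  CHG atom index out of range",
                     ordinal, q))
      }
      chgPairs <- rbind(chgPairs, cbind(idx, chg))
    }
    q <- q + 1L
  }
  if (!sawEnd && (na > 0L || nb > 0L)) {
    stop(sprintf("record %d: unterminated record (no 'M  END')", ordinal))
  }
  ## data items until $$$$
  while (q <= nL && !startsWith(lines[q], "$$$$")) q <- q + 1L
  nextLine <- if (q <= nL) q + 1L else q
  fc <- oldChg
  if (!is.null(chgPairs)) {
    fc <- integer(na)          # M  CHG supersedes the atom-block column
    fc[chgPairs[, 1]] <- chgPairs[, 2]
  }
  id <- if (nzchar(title)) title else as.character(ordinal)
  bonds <- data.frame(a = ba, b = bb, order = bo, aromatic = bar)
  list(molecule = Molecule(id, elements, coords, bonds, fc),
       next_line = nextLine)
}

#' Write molecules to an MDL SDF (V2000) file
#'
#' Aromatic-flagged bonds are written with bond type 4 so that a
#' read-write-read cycle preserves the bond annotation; all other bonds carry
#' their integer order.  Non-zero formal charges are emitted as \code{M  CHG}
#' lines.  Coordinates are written with 4 decimals (the SDF field precision).
#'
#' @param molecules a \code{Molecule} or list of them.
#' @param file output path or connection.
#' @return invisibly, the number of records written.
#' @export
writeSDF <- function(molecules, file) {
  if (is(molecules, "Molecule")) molecules <- list(molecules)
  out <- character(0)
  for (m in molecules) {
    at <- m@atoms
    bd <- m@bonds
    out <- c(out,
             m@id,
             "  EEMCharges",
             "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                     nrow(at), nrow(bd)))
    out <- c(out, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                          at$x, at$y, at$z, at$element))
    if (nrow(bd) > 0L) {
      btype <- ifelse(bd$aromatic, 4L, bd$order)
      out <- c(out, sprintf("%3d%3d%3d  0", bd$a, bd$b, btype))
    }
    chgIdx <- which(at$formalCharge != 0L)
    for (start in seq(1L, length.out = ceiling(length(chgIdx) / 8))) {
      grp <- chgIdx[seq((start - 1L) * 8L + 1L, min(start * 8L, length(chgIdx)))]
      out <- c(out, paste0(sprintf("M  CHG%3d", length(grp)),
                           paste(sprintf("%4d%4d", grp, at$formalCharge[grp]),
                                 collapse = "")))
    }
    out <- c(out, "M  END", "$$$$")
  }
  writeLines(out, file)
  invisible(length(molecules))
}
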