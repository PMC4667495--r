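## Plain-text charge files.  One block per molecule:
##   header:  <id> <N> <Q> <chiBar>
##   then one line per atom:  <index(1-based)> <element> <typeKey> <charge>
## Blocks are separated by a blank line; charges carry 9 decimals so a
## write-read cycle reproduces them far below 5e-7.

#' Write per-atom charges to a plain-text charge file
#'
#' @param molecules a \code{Molecule} or list of them.
#' @param results matching \code{\linkS4class{ChargeResult}} or list of them;
#'   each must hold exactly one charge per atom of its molecule.
#' @param file output path or connection.
#' @return invisibly, the number of blocks written.
#' @seealso \code{\link{readCharges}}
#' @export
writeCharges <- function(molecules, results, file) {
  if (is(molecules, "Molecule")) molecules <- list(molecules)
  if (is(results, "ChargeResult")) results <- list(results)
  stopifnot(length(molecules) == length(results))
  out <- character(0)
  for (k in seq_along(molecules)) {
    m <- molecules[[k]]
    r <- results[[k]]
    n <- nrow(m@atoms)
    if (length(r@charges) != n) {
      stop(sprintf(
        "charge/atom count mismatch for molecule '%s': %d charges for %d atoms",
        m@id, length(r@charges), n))
    }
    id <- gsub("\\s+", "_", m@id)
    ty <- assignAtomTypes(m)
    out <- c(out,
             sprintf("%s %d %g %.9f", id, n, m@totalCharge, r@chiBar),
             sprintf("%d %s %s %.9f", seq_len(n), m@atoms$element, ty,
                     r@charges),
             "")
  }
  writeLines(out, file)
  invisible(length(molecules))
}

#' Read a plain-text charge file
#'
#' @param file path or connection (ignored when \code{text} is given).
#' @param text optional character vector of lines to parse instead.
#' @return named list (by molecule id) of records, each a list with
#'   \code{id}, \code{n}, \code{totalCharge}, \code{chiBar} and a data.frame
#'   \code{atoms} (columns \code{index}, \code{element}, \code{typeKey},
#'   \code{charge}).
#' @seealso \code{\link{writeCharges}}, \code{\link{refChargeVectors}}
#' @export
readCharges <- function(file = NULL, text = NULL) {
  if (is.null(text)) {
    lines <- readLines(file, warn = FALSE)
  } else {
    lines <- strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE)[[1]]
  }
  recs <- list()
  p <- 1L
  nL <- length(lines)
  while (p <= nL) {
    if (!nzchar(trimws(lines[p]))) { p <- p + 1L; next }
    hdr <- strsplit(trimws(lines[p]), "\\s+")[[1]]
    if (length(hdr) != 4L) {
      stop(sprintf("charge file line %d: malformed header '%s'", p, lines[p]))
    }
    id <- hdr[1]
    n <- suppressWarnings(as.integer(hdr[2]))
    Q <- suppressWarnings(as.numeric(hdr[3]))
    chi <- suppressWarnings(as.numeric(hdr[4]))
    if (is.na(n) || is.na(Q)) {
      stop(sprintf("charge file line %d: malformed header '%s'", p, lines[p]))
    }
    if (p + n > nL) stop(sprintf("charge file: block '%s' truncated", id))
    tab <- data.frame(index = integer(n), element = character(n),
                      typeKey = character(n), charge = numeric(n))
    for (i in seq_len(n)) {
      tok <- strsplit(trimws(lines[p + i]), "\\s+")[[1]]
      if (length(tok) != 4L) {
        stop(sprintf("charge file line %d: malformed atom line", p + i))
      }
      tab$index[i] <- as.integer(tok[1])
      tab$element[i] <- tok[2]
      tab$typeKey[i] <- tok[3]
      tab$charge[i] <- as.numeric(tok[4])
    }
    recs[[id]] <- list(id = id, n = n, totalCharge = Q, chiBar = chi,
                       atoms = tab)
    p <- p + n + 1L
  }
  recs
}

#' Extract reference-charge vectors keyed by molecule id
#'
#' Convenience for feeding a charge file into the parameterization: returns
#' a named list of numeric charge vectors.
#'
#' @inheritParams readCharges
#' @return named list of numeric vectors.
#' @export
refChargeVectors <- function(file = NULL, text = NULL) {
  lapply(readCharges(file = file, text = text), function(r) r$atoms$charge)
}
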