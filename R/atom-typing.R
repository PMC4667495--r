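#' Assign EEM atom types (element + maximal bond order)
#'
#' The unit of EEM parameterization is the atom type: the element symbol
#' followed by the maximal bond order over the atom's incident bonds ("C2" is
#' a carbon with at least one double bond; aromatic atoms fall in X2 types
#' because aromatic input bonds are stored with order 2).  Isolated atoms
#' (no bonds) get order 1 — an unbonded atom has no multiple bond.  Unknown
#' elements still produce a typed key; whether a parameter set covers them is
#' decided downstream.
#'
#' @param m a \code{\linkS4class{Molecule}}.
#' @return character vector of type keys, one per atom, in atom order.
#' @examples
#' eth <- Molecule("ethane-heavy", c("C", "C"),
#'                 rbind(c(0, 0, 0), c(1.54, 0, 0)),
#'                 data.frame(a = 1L, b = 2L, order = 1L))
#' assignAtomTypes(eth)   # "C1" "C1"
#' @export
assignAtomTypes <- function(m) {
  n <- nrow(m@atoms)
  maxOrder <- rep(1L, n)
  bd <- m@bonds
  if (nrow(bd) > 0L) {
    for (i in seq_len(nrow(bd))) {
      o <- bd$order[i]
      if (o > maxOrder[bd$a[i]]) maxOrder[bd$a[i]] <- o
      if (o > maxOrder[bd$b[i]]) maxOrder[bd$b[i]] <- o
    }
  }
  paste0(m@atoms$element, maxOrder)
}

#' Atom-type occurrence histogram over a molecule collection
#'
#' For each atom type: the total number of atoms carrying it and the number
#' of molecules containing at least one such atom.  Atom counts sum to the
#' total atom count of the collection.
#'
#' @param molecules list of \code{Molecule}.
#' @return data.frame with columns \code{typeKey}, \code{atomCount},
#'   \code{moleculeCount}, sorted by decreasing atom count.
#' @seealso \code{\link{writeTypeHistogram}}
#' @export
typeHistogram <- function(molecules) {
  if (is(molecules, "Molecule")) molecules <- list(molecules)
  ac <- integer(0)
  mc <- integer(0)
  for (m in molecules) {
    ty <- assignAtomTypes(m)
    t1 <- table(ty)
    for (k in names(t1)) {
      if (is.na(ac[k])) { ac[k] <- 0L; mc[k] <- 0L }
      ac[k] <- ac[k] + as.integer(t1[[k]])
      mc[k] <- mc[k] + 1L
    }
  }
  df <- data.frame(typeKey = if (is.null(names(ac))) character(0) else names(ac),
                   atomCount = as.integer(ac),
                   moleculeCount = as.integer(mc))
  df[order(-df$atomCount, df$typeKey), , drop = FALSE]
}

#' Write an atom-type histogram as TSV
#'
#' Columns \code{typeKey}, \code{atomCount}, \code{moleculeCount}.
#'
#' @param histogram output of \code{\link{typeHistogram}}.
#' @param file output path or connection.
#' @export
writeTypeHistogram <- function(histogram, file) {
  utils::write.table(histogram, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(NULL)
}
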