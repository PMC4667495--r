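#' Construct an EEM parameter set
#'
#' @param name set name (free text, no newlines).
#' @param kappa global screening constant, must be positive for a usable set.
#' @param entries data.frame with columns \code{typeKey} ("C2" style specific
#'   keys or bare-element wildcards like "C"), \code{A} (effective
#'   electronegativity) and \code{B} (effective hardness).  A and B are in the
#'   units of the reference-charge convention with distances in Angstrom; the
#'   package never converts units.
#' @param metadata named list of provenance strings (e.g.
#'   \code{list(scheme = "B3LYP/6-311G/NPA")}).
#' @return an \code{\linkS4class{EEMParameterSet}}.
#' @examples
#' p <- EEMParameterSet("toy", 0.44,
#'        data.frame(typeKey = c("H1", "C1", "C2", "O1", "O2"),
#'                   A = c(2.4, 2.5, 2.6, 3.1, 3.2),
#'                   B = c(0.96, 0.6, 0.7, 1.1, 1.2)))
#' validateParamset(p)
#' @export
EEMParameterSet <- function(name, kappa, entries, metadata = list()) {
  entries <- data.frame(typeKey = as.character(entries$typeKey),
                        A = as.numeric(entries$A),
                        B = as.numeric(entries$B))
  new("EEMParameterSet", name = as.character(name), kappa = as.numeric(kappa),
      entries = entries, metadata = metadata)
}

#' @rdname EEMParameterSet
#' @export
setMethod("paramName", "EEMParameterSet", function(object) object@name)

#' @rdname EEMParameterSet
#' @export
setMethod("paramKappa", "EEMParameterSet", function(object) object@kappa)

#' @rdname EEMParameterSet
#' @export
setMethod("paramEntries", "EEMParameterSet", function(object) object@entries)

#' @rdname EEMParameterSet
#' @export
setMethod("show", "EEMParameterSet", function(object) {
  cat(sprintf("EEMParameterSet '%s': kappa = %g, %d atom-type entries\n",
              object@name, object@kappa, nrow(object@entries)))
  cat("  types:", paste(object@entries$typeKey, collapse = " "), "\n")
  if (length(object@metadata)) {
    cat("  metadata:",
        paste(sprintf("%s=%s", names(object@metadata),
                      unlist(object@metadata)), collapse = "; "), "\n")
  }
  invisible(object)
})

#' Resolve atom-type keys against a parameter set
#'
#' Resolution rule shared by the solver and the coverage scan: a specific key
#' ("C2") matches its own entry; otherwise the bare-element wildcard ("C")
#' matches, if present.  A specific entry always beats a wildcard.
#'
#' @param typeKeys character vector of atom-type keys.
#' @param P an \code{EEMParameterSet}.
#' @return integer vector of row indices into \code{paramEntries(P)}, with
#'   \code{NA} for unresolved keys.
#' @export
resolveTypeKeys <- function(typeKeys, P) {
  en <- P@entries$typeKey
  idx <- match(typeKeys, en)
  miss <- is.na(idx)
  if (any(miss)) {
    bare <- sub("[123]$", "", typeKeys[miss])
    idx[miss] <- match(bare, en)
  }
  idx
}

#' Validate an EEM parameter set
#'
#' Checks the conditions the EEM system needs to be solvable and returns all
#' findings instead of stopping: the caller decides.  Error-level findings:
#' any B <= 0 (unphysical hardness), kappa <= 0, malformed or duplicate keys,
#' orders outside \{1,2,3\}, no entries at all.  Info-level: an element having
#' both a wildcard and specific entries (legal; the specific key wins).
#'
#' @param P an \code{EEMParameterSet}.
#' @return data.frame with columns \code{level} ("error" or "info") and
#'   \code{message}; zero rows for a clean set.
#' @export
validateParamset <- function(P) {
  lv <- character(0); ms <- character(0)
  add <- function(level, msg) {
    lv <<- c(lv, level); ms <<- c(ms, msg)
  }
  en <- P@entries
  if (nrow(en) == 0L) add("error", "parameter set has no entries")
  if (!is.finite(P@kappa) || P@kappa <= 0) {
    add("error", sprintf("kappa = %g must be positive", P@kappa))
  }
  bad <- !grepl("^[A-Z][a-z]?[123]?$", en$typeKey)
  for (k in en$typeKey[bad]) {
    add("error", sprintf("malformed type key '%s' (order must be 1, 2 or 3)", k))
  }
  for (k in unique(en$typeKey[duplicated(en$typeKey)])) {
    add("error", sprintf("duplicate type key '%s'", k))
  }
  nb <- which(!(en$B > 0))
  for (i in nb) {
    add("error", sprintf("B(%s) = %g must be positive", en$typeKey[i], en$B[i]))
  }
  el <- sub("[123]$", "", en$typeKey)
  wild <- en$typeKey == el
  for (e in unique(el[wild])) {
    if (any(!wild & el == e)) {
      add("info", sprintf(
        "element %s has both a wildcard and specific entries; specific keys win", e))
    }
  }
  data.frame(level = lv, message = ms)
}

#' Read an EEM parameter set file
#'
#' Format: UTF-8 plain text, \code{#} comments, first non-comment line
#' \code{kappa <float>}, then one entry per line
#' \code{<typeKey> <A> <B>} (whitespace separated).  Leading comments of the
#' form \code{# key: value} are collected into the metadata (\code{name} is
#' special-cased into the set name).
#'
#' @param file path or connection (ignored when \code{text} is given).
#' @param text optional character vector of lines to parse instead.
#' @param name fallback set name when the file carries none.
#' @return an \code{\linkS4class{EEMParameterSet}}.
#' @seealso \code{\link{writeParamset}}, \code{\link{validateParamset}}
#' @export
readParamset <- function(file = NULL, text = NULL, name = "unnamed") {
  if (is.null(text)) {
    lines <- readLines(file, warn = FALSE)
  } else {
    lines <- strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE)[[1]]
  }
  metadata <- list()
  kappa <- NA_real_
  keys <- character(0); A <- numeric(0); B <- numeric(0)
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    if (startsWith(ln, "#")) {
      mm <- regmatches(ln, regexec("^#\\s*([A-Za-z_][A-Za-z0-9_]*)\\s*:\\s*(.*)$", ln))[[1]]
      if (length(mm) == 3L) {
        if (mm[2] == "name") name <- mm[3] else metadata[[mm[2]]] <- mm[3]
      }
      next
    }
    tok <- strsplit(ln, "\\s+")[[1]]
    if (is.na(kappa)) {
      if (length(tok) != 2L || tolower(tok[1]) != "kappa") {
        stop(sprintf("parameter file line %d: expected 'kappa <value>', got '%s'",
                     i, ln))
      }
      kappa <- suppressWarnings(as.numeric(tok[2]))
      if (is.na(kappa)) {
        stop(sprintf("parameter file line %d: non-numeric kappa '%s'", i, tok[2]))
      }
      next
    }
    if (length(tok) != 3L) {
      stop(sprintf("parameter file line %d: expected '<type> <A> <B>', got '%s'",
                   i, ln))
    }
    a <- suppressWarnings(as.numeric(tok[2]))
    b <- suppressWarnings(as.numeric(tok[3]))
    if (is.na(a) || is.na(b)) {
      stop(sprintf("parameter file line %d: non-numeric A/B in '%s'", i, ln))
    }
    if (tok[1] %in% keys) {
      stop(sprintf("parameter file line %d: duplicate type key '%s'", i, tok[1]))
    }
    keys <- c(keys, tok[1]); A <- c(A, a); B <- c(B, b)
  }
  if (is.na(kappa)) stop("parameter file: missing 'kappa' line")
  EEMParameterSet(name, kappa, data.frame(typeKey = keys, A = A, B = B),
                  metadata = metadata)
}

#' Write an EEM parameter set file
#'
#' Refuses an invalid set (see \code{\link{validateParamset}}).  Output is
#' deterministic: name and metadata as leading comments, kappa first, entries
#' sorted by element then order (wildcards before specific keys), 17
#' significant digits so read-write-read is a lossless fixed point.
#'
#' @param P an \code{EEMParameterSet}.
#' @param file output path or connection.
#' @export
writeParamset <- function(P, file) {
  v <- validateParamset(P)
  if (any(v$level == "error")) {
    stop(paste(c("refusing to write invalid parameter set:",
                 v$message[v$level == "error"]), collapse = "\n  "))
  }
  en <- P@entries
  el <- sub("[123]$", "", en$typeKey)
  ord <- ifelse(en$typeKey == el, 0L, as.integer(sub("^[A-Z][a-z]?", "", en$typeKey)))
  en <- en[order(el, ord), , drop = FALSE]
  out <- c(sprintf("# name: %s", P@name))
  for (k in names(P@metadata)) {
    out <- c(out, sprintf("# %s: %s", k, P@metadata[[k]]))
  }
  out <- c(out, sprintf("kappa %.17g", P@kappa),
           sprintf("%-4s %.17g %.17g", en$typeKey, en$A, en$B))
  writeLines(out, file)
  invisible(NULL)
}
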