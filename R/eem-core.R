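#' @rdname ChargeResult
#' @export
setMethod("charges", "ChargeResult", function(object) object@charges)

#' @rdname ChargeResult
#' @export
setMethod("chiBar", "ChargeResult", function(object) object@chiBar)

#' @rdname ChargeResult
#' @export
setMethod("show", "ChargeResult", function(object) {
  cat(sprintf("ChargeResult (%s): %d charges, sum = %.6f, chiBar = %.6f\n",
              object@parameterSetName, length(object@charges),
              sum(object@charges), object@chiBar))
  invisible(object)
})

.resolve_or_stop <- function(m, P) {
  ty <- assignAtomTypes(m)
  idx <- resolveTypeKeys(ty, P)
  if (anyNA(idx)) {
    miss <- sort(unique(ty[is.na(idx)]))
    stop(sprintf(
      "missing EEM parameters in set '%s' for atom type(s): %s (molecule '%s')",
      P@name, paste(miss, collapse = ", "), m@id),
      call. = FALSE)
  }
  idx
}

#' Assemble the EEM matrix equation for one molecule
#'
#' Builds the (N+1) x (N+1) linear system whose solution is the vector
#' (q_1, ..., q_N, chiBar): atom row i carries the hardness B_i on the
#' diagonal, the screened interaction kappa / R_ij off the diagonal and -1 in
#' the last column; the last row (all ones, final 0) enforces total-charge
#' conservation.  The right-hand side is (-A_1, ..., -A_N, Q).
#'
#' @param m a \code{Molecule}.
#' @param D its distance matrix (from \code{\link{distanceMatrix}}); computed
#'   on the fly when NULL.
#' @param P an \code{\linkS4class{EEMParameterSet}}; every atom type must
#'   resolve (wildcards allowed), otherwise a missing-parameter error lists
#'   the offending type keys.
#' @param minDist passed to \code{\link{distanceMatrix}} when D is NULL.
#' @return list with \code{matrix} ((N+1) x (N+1)) and \code{rhs}
#'   (length N+1).
#' @export
buildEEMSystem <- function(m, D = NULL, P, minDist = 0.5) {
  idx <- .resolve_or_stop(m, P)
  if (is.null(D)) D <- distanceMatrix(m, minDist = minDist)
  n <- nrow(m@atoms)
  A <- P@entries$A[idx]
  B <- P@entries$B[idx]
  M <- matrix(0, n + 1L, n + 1L)
  if (n > 1L) {
    Dinv <- 1 / D
    diag(Dinv) <- 0
    M[seq_len(n), seq_len(n)] <- P@kappa * Dinv
  }
  diag(M)[seq_len(n)] <- B
  M[seq_len(n), n + 1L] <- -1
  M[n + 1L, seq_len(n)] <- 1
  list(matrix = M, rhs = c(-A, m@totalCharge))
}

#' Solve the EEM system for one molecule
#'
#' Dense direct solve with partial pivoting (molecules are at most a few
#' hundred atoms).  A condition estimate above \code{maxCondition} refuses the
#' solve rather than return garbage; charge conservation holds to 1e-10 by
#' construction of the constraint row.
#'
#' @inheritParams buildEEMSystem
#' @param maxCondition condition-number guard (1-norm estimate), default 1e10.
#' @return a \code{\linkS4class{ChargeResult}}.
#' @examples
#' p <- EEMParameterSet("toy", 0.44,
#'        data.frame(typeKey = c("O1", "H1"), A = c(3.2, 2.4),
#'                   B = c(1.1, 0.96)))
#' w <- Molecule("water", c("O", "H", "H"),
#'               rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0)),
#'               data.frame(a = 1L, b = 2:3, order = 1L))
#' r <- solveEEM(w, p)
#' sum(charges(r))   # 0, the total charge
#' @export
solveEEM <- function(m, P, minDist = 0.5, maxCondition = 1e10) {
  sys <- buildEEMSystem(m, P = P, minDist = minDist)
  kap <- tryCatch(kappa(sys$matrix, exact = FALSE),
                  error = function(e) Inf)
  if (!is.finite(kap) || kap > maxCondition) {
    stop(sprintf(
      "EEM matrix for molecule '%s' is singular or ill-conditioned (condition estimate %.3g)",
      m@id, kap), call. = FALSE)
  }
  sol <- solve(sys$matrix, sys$rhs)
  n <- length(sol) - 1L
  new("ChargeResult", charges = sol[seq_len(n)], chiBar = sol[n + 1L],
      parameterSetName = P@name)
}
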