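## Shared fixtures and independent oracles.  Oracles are literal, loop-based
## transcriptions, deliberately kept separate from the package's vectorized
## implementations.

## hand-written ethanol (CH3-CH2-OH): 9 atoms, 8 single bonds, neutral
ethanol_sdf_text <- function() {
  c("ethanol",
    "  fixture",
    "",
    "  9  8  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    1.5200    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    2.0400    1.3300    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
    "    3.0000    1.3300    0.2000 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "   -0.3900    1.0300    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "   -0.3900   -0.5100    0.8900 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "   -0.3900   -0.5100   -0.8900 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "    1.9100   -0.5100    0.8900 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "    1.9100   -0.5100   -0.8900 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "  1  2  1  0",
    "  2  3  1  0",
    "  3  4  1  0",
    "  1  5  1  0",
    "  1  6  1  0",
    "  1  7  1  0",
    "  2  8  1  0",
    "  2  9  1  0",
    "M  END",
    "$$$$")
}

helium_sdf_text <- function() {
  c("", "", "",
    "  1  0  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 He  0  0  0  0  0  0  0  0  0  0  0  0",
    "M  END",
    "$$$$")
}

## planar six-ring with alternating aromatic (type 4 -> order 2) bonds
benzene_like_molecule <- function() {
  ang <- 2 * pi * (0:5) / 6
  Molecule("ring", rep("C", 6), cbind(1.39 * cos(ang), 1.39 * sin(ang), 0),
           data.frame(a = 1:6, b = c(2:6, 1L), order = 2L, aromatic = TRUE))
}

## uniformly random valid parameter set over the given type keys
random_paramset <- function(keys, name = "random") {
  EEMParameterSet(name, stats::runif(1, 0.1, 0.9),
                  data.frame(typeKey = keys,
                             A = stats::runif(length(keys), 1.5, 4.0),
                             B = stats::runif(length(keys), 0.3, 1.6)))
}

all_pool_keys <- function() {
  p <- defaultElementPool()
  unique(paste0(p$element, p$order))
}

## --- independent metric oracles: literal loop transcriptions -------------
bf_r2 <- function(e, r) {
  me <- sum(e) / length(e); mr <- sum(r) / length(r)
  num <- 0; de <- 0; dr <- 0
  for (i in seq_along(e)) {
    num <- num + (e[i] - me) * (r[i] - mr)
    de <- de + (e[i] - me)^2
    dr <- dr + (r[i] - mr)^2
  }
  num^2 / (de * dr)
}

bf_rmsd <- function(e, r) {
  acc <- 0
  for (i in seq_along(e)) acc <- acc + (e[i] - r[i])^2
  sqrt(acc / length(e))
}

bf_mad <- function(e, r) {
  acc <- 0
  for (i in seq_along(e)) acc <- acc + abs(e[i] - r[i])
  acc / length(e)
}

## --- independent distance oracle -----------------------------------------
bf_distance_matrix <- function(coords) {
  n <- nrow(coords)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      D[i, j] <- sqrt(sum((coords[i, ] - coords[j, ])^2))
    }
  }
  D
}

## --- independent energy-minimization oracle ------------------------------
## minimizes E(q) = sum_i (A_i q_i + B_i q_i^2 / 2)
##               + (kappa / 2) sum_{i != j} q_i q_j / R_ij
## subject to sum(q) = Q, via nlminb on a null-space parametrization.
## Only defined when the hardness matrix is positive definite on the
## conservation plane; returns NULL otherwise.
oracle_energy_charges <- function(m, P) {
  ty <- assignAtomTypes(m)
  idx <- resolveTypeKeys(ty, P)
  en <- paramEntries(P)
  A <- en$A[idx]; B <- en$B[idx]
  kap <- paramKappa(P)
  X <- atomCoords(m)
  n <- nrow(X)
  Q <- totalCharge(m)
  D <- bf_distance_matrix(X)
  energy <- function(q) {
    e <- 0
    for (i in seq_len(n)) e <- e + A[i] * q[i] + 0.5 * B[i] * q[i]^2
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i != j) e <- e + 0.5 * kap * q[i] * q[j] / D[i, j]
      }
    }
    e
  }
  grad <- function(q) {
    g <- numeric(n)
    for (i in seq_len(n)) {
      g[i] <- A[i] + B[i] * q[i]
      for (j in seq_len(n)) if (j != i) g[i] <- g[i] + kap * q[j] / D[i, j]
    }
    g
  }
  if (n == 1L) return(Q)
  ## orthonormal basis of the conservation plane
  Z <- qr.Q(qr(cbind(rep(1, n))), complete = TRUE)[, -1, drop = FALSE]
  H <- diag(B)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j) H[i, j] <- kap / D[i, j]
  ev <- eigen(crossprod(Z, H %*% Z), symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-8) return(NULL)     # no minimizer on the plane
  q0 <- rep(Q / n, n)
  gr <- function(u) as.numeric(crossprod(Z, grad(q0 + as.numeric(Z %*% u))))
  ## conjugate gradients with exact line search: the gradient is affine in u,
  ## so the curvature along d is gr(u + d) - gr(u); converges to machine
  ## precision in at most dim steps on this convex quadratic
  u <- numeric(n - 1L)
  g <- gr(u)
  d <- -g
  for (it in seq_len(10L * (n - 1L))) {
    if (sqrt(sum(g^2)) < 1e-13) break
    Hd <- gr(u + d) - gr(u)
    curv <- sum(d * Hd)
    if (curv <= 0) break
    alpha <- -sum(g * d) / curv
    u <- u + alpha * d
    gNew <- gr(u)
    beta <- sum(gNew^2) / sum(g^2)
    g <- gNew
    d <- if (it %% (n - 1L) == 0L) -g else -g + beta * d
  }
  q0 + as.numeric(Z %*% u)
}

## small helper: examples for fit tests over a reduced common-type pool
recovery_pool <- function(keys = c("H1", "C1", "C2", "O1", "O2")) {
  p <- defaultElementPool()
  p[paste0(p$element, p$order) %in% keys, , drop = FALSE]
}

strip_chibar <- function(examples) {
  lapply(examples, function(e)
    TrainingExample(e@molecule, e@refCharges, schemeLabel = e@schemeLabel))
}
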