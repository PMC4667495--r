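test_that("the assembled system has the equalization layout", {
  ## one atom: [[B, -1], [1, 0]], rhs (-A, Q)
  p1 <- EEMParameterSet("t", 0.4, data.frame(typeKey = "He1", A = 2, B = 1))
  m1 <- Molecule("he", "He", rbind(c(0, 0, 0)), totalCharge = 1)
  sys <- buildEEMSystem(m1, P = p1)
  expect_equal(sys$matrix, rbind(c(1, -1), c(1, 0)))
  expect_equal(sys$rhs, c(-2, 1))

  ## two atoms at R = 2 with kappa = 0.4: off-diagonals kappa / R = 0.2
  p2 <- EEMParameterSet("t", 0.4,
                        data.frame(typeKey = c("H1", "F1"), A = c(2, 3),
                                   B = c(1, 1.2)))
  m2 <- Molecule("hf", c("H", "F"), rbind(c(0, 0, 0), c(0, 0, 2)))
  sys2 <- buildEEMSystem(m2, P = p2)
  expect_equal(sys2$matrix,
               rbind(c(1.0, 0.2, -1), c(0.2, 1.2, -1), c(1, 1, 0)))
  expect_equal(sys2$rhs, c(-2, -3, 0))
})

test_that("missing parameters raise an error naming the uncovered types", {
  p <- EEMParameterSet("noSe", 0.4,
                       data.frame(typeKey = c("H1", "C1"), A = c(2, 2.5),
                                  B = c(1, 0.7)))
  m <- Molecule("sel", c("Se", "H"), rbind(c(0, 0, 0), c(0, 0, 1.5)),
                data.frame(a = 1L, b = 2L, order = 1L))
  expect_error(buildEEMSystem(m, P = p), "Se1")
  expect_error(solveEEM(m, p), "missing EEM parameters")
})

test_that("closed forms: single atom, symmetric and asymmetric diatomics", {
  p1 <- EEMParameterSet("t", 0.4, data.frame(typeKey = "He1", A = 2, B = 1))
  m1 <- Molecule("he", "He", rbind(c(0, 0, 0)), totalCharge = 1)
  r1 <- solveEEM(m1, p1)
  expect_equal(charges(r1), 1)
  expect_equal(chiBar(r1), 3)     # B*Q + A

  ## identical atoms, Q = 0: symmetry forces q = 0 and chiBar = A
  ph <- EEMParameterSet("t", 0.4, data.frame(typeKey = "H1", A = 2.3, B = 0.9))
  mh <- Molecule("h2", c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 0.74)))
  rh <- solveEEM(mh, ph)
  expect_equal(charges(rh), c(0, 0), tolerance = 1e-14)
  expect_equal(chiBar(rh), 2.3)

  ## heteronuclear: q1 = (A2 - A1) / (B1 + B2 - 2 kappa / R)
  p2 <- EEMParameterSet("t", 0.4,
                        data.frame(typeKey = c("X1", "Y1"), A = c(2, 3),
                                   B = c(1, 1)))
  m2 <- Molecule("xy", c("X", "Y"), rbind(c(0, 0, 0), c(0, 0, 2)))
  r2 <- solveEEM(m2, p2)
  expect_equal(charges(r2), c(0.625, -0.625), tolerance = 1e-12)
  expect_equal(chiBar(r2), 2.5, tolerance = 1e-12)
})

test_that("charges sum to the total molecular charge on random inputs", {
  cfg <- generatorConfig(seed = 11L, nMolecules = 100L)
  keys <- all_pool_keys()
  set.seed(11)
  worst <- 0
  for (i in seq_len(100L)) {
    m <- makeMolecule(cfg, i)
    P <- random_paramset(keys)
    r <- tryCatch(solveEEM(m, P), error = function(e) NULL)
    if (is.null(r)) next                    # condition guard refused
    worst <- max(worst, abs(sum(charges(r)) - totalCharge(m)))
  }
  expect_lt(worst, 1e-10)
})

test_that("solved charges minimize the EEM energy on the conservation plane", {
  cfg <- generatorConfig(seed = 23L, nMolecules = 12L, atomsRange = c(3L, 15L))
  keys <- all_pool_keys()
  set.seed(23)
  tested <- 0L
  for (i in seq_len(12L)) {
    m <- makeMolecule(cfg, i)
    q_opt <- NULL
    for (draw in seq_len(40L)) {
      P <- random_paramset(keys)
      q_opt <- oracle_energy_charges(m, P)   # NULL when E is not convex there
      if (!is.null(q_opt)) break
    }
    if (is.null(q_opt)) next
    expect_lt(max(abs(charges(solveEEM(m, P)) - q_opt)), 1e-8)
    tested <- tested + 1L
  }
  expect_gte(tested, 10L)
})

test_that("a uniform shift of all A leaves charges and shifts chiBar exactly", {
  cfg <- generatorConfig(seed = 41L, nMolecules = 10L)
  keys <- all_pool_keys()
  set.seed(41)
  P <- random_paramset(keys)
  en <- paramEntries(P)
  shift <- 0.37
  P2 <- EEMParameterSet("shifted", paramKappa(P),
                        transform(en, A = A + shift))
  for (i in seq_len(10L)) {
    m <- makeMolecule(cfg, i)
    r1 <- tryCatch(solveEEM(m, P), error = function(e) NULL)
    if (is.null(r1)) next
    r2 <- solveEEM(m, P2)
    expect_lt(max(abs(charges(r1) - charges(r2))), 1e-12)
    expect_equal(chiBar(r2) - chiBar(r1), shift, tolerance = 1e-10)
  }
})

test_that("charges follow atom permutations and ignore rigid motions", {
  cfg <- generatorConfig(seed = 67L, nMolecules = 8L)
  keys <- all_pool_keys()
  set.seed(67)
  P <- random_paramset(keys)
  ## a fixed rotation (about z by 0.7 rad) plus translation
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  for (i in seq_len(8L)) {
    m <- makeMolecule(cfg, i)
    r0 <- tryCatch(solveEEM(m, P), error = function(e) NULL)
    if (is.null(r0)) next
    perm <- sample(atomCount(m))
    inv <- order(perm)
    bd <- m@bonds
    mp <- Molecule(moleculeId(m), atomElements(m)[perm],
                   atomCoords(m)[perm, , drop = FALSE],
                   data.frame(a = inv[bd$a], b = inv[bd$b], order = bd$order,
                              aromatic = bd$aromatic))
    expect_equal(charges(solveEEM(mp, P)), charges(r0)[perm],
                 tolerance = 1e-10)
    mt <- Molecule(moleculeId(m), atomElements(m),
                   atomCoords(m) %*% t(R) +
                     matrix(c(1, -2, 3), atomCount(m), 3, byrow = TRUE),
                   bd)
    expect_lt(max(abs(charges(solveEEM(mt, P)) - charges(r0))), 1e-10)
  }
})

test_that("a singular system is refused, not answered with garbage", {
  ## equal rows: B = kappa / R makes the two atom rows identical
  p <- EEMParameterSet("sing", 0.8,
                       data.frame(typeKey = "H1", A = 2, B = 0.4))
  m <- Molecule("h2", c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 2)))
  expect_error(solveEEM(m, p), "ill-conditioned|singular")
})
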