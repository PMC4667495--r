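test_that("a minimal single-atom SDF record parses", {
  mols <- readSDF(text = helium_sdf_text())
  expect_length(mols, 1L)
  m <- mols[[1]]
  expect_equal(atomCount(m), 1L)
  expect_equal(bondCount(m), 0L)
  expect_equal(totalCharge(m), 0)
  expect_equal(atomElements(m), "He")
  expect_equal(moleculeId(m), "1")   # blank title -> record ordinal
})

test_that("the hand-written ethanol fixture parses with the expected counts", {
  m <- readSDF(text = ethanol_sdf_text())[[1]]
  expect_equal(moleculeId(m), "ethanol")
  expect_equal(atomCount(m), 9L)
  expect_equal(bondCount(m), 8L)
  expect_true(all(m@bonds$order == 1L))
  expect_equal(totalCharge(m), 0)
  expect_equal(sort(table(atomElements(m)), decreasing = TRUE),
               sort(table(c(rep("H", 6), rep("C", 2), "O")), decreasing = TRUE))
  expect_equal(atomCoords(m)[2, ], c(1.52, 0, 0))
})

test_that("structural parse errors name the record and offending line", {
  bad <- ethanol_sdf_text()
  bad[14] <- " 99  3  1  0"       # bond to atom 99 of 9
  expect_error(readSDF(text = bad), "atom 99 of 9")
  expect_error(readSDF(text = bad), "record 1")

  bad2 <- ethanol_sdf_text()
  bad2[14] <- "  1  2  5  0"      # bond type 5
  expect_error(readSDF(text = bad2), "bond type 5")

  bad3 <- ethanol_sdf_text()
  bad3[4] <- " xx  8  0  0  0  0  0  0  0  0999 V2000"
  expect_error(readSDF(text = bad3), "malformed counts")

  v3 <- ethanol_sdf_text()
  v3[4] <- sub("V2000", "V3000", v3[4])
  expect_error(readSDF(text = v3), "V3000")

  trunc <- ethanol_sdf_text()[1:10]  # atom block runs past the end
  expect_error(readSDF(text = trunc), "unterminated")
})

test_that("aromatic bond type 4 is normalized to order 2 with the flag set", {
  txt <- ethanol_sdf_text()
  txt[14] <- "  1  2  4  0"
  m <- readSDF(text = txt)[[1]]
  expect_equal(m@bonds$order[1], 2L)
  expect_true(m@bonds$aromatic[1])
  expect_false(any(m@bonds$aromatic[-1]))
})

test_that("M CHG lines populate formal charges and the total charge", {
  txt <- ethanol_sdf_text()
  txt <- append(txt, "M  CHG  2   3  -1   1   1", after = 21L)  # before M  END
  m <- readSDF(text = txt)[[1]]
  expect_equal(formalCharges(m)[3], -1L)
  expect_equal(formalCharges(m)[1], 1L)
  expect_equal(sum(formalCharges(m)), 0L)
  expect_equal(totalCharge(m), 0)
})

test_that("multi-record files parse record by record and keep ordinal ids", {
  txt <- c(helium_sdf_text(), ethanol_sdf_text(), helium_sdf_text())
  mols <- readSDF(text = txt)
  expect_length(mols, 3L)
  expect_equal(vapply(mols, moleculeId, character(1)), c("1", "ethanol", "3"))
  ## error-tolerant scan counts unreadable records separately
  txt2 <- txt
  txt2[15] <- " 99  3  1  0"
  recs <- readSDFRecords(text = txt2)
  expect_length(recs$molecules, 2L)
  expect_length(recs$errors, 1L)
})

test_that("SDF write-read roundtrip preserves structure to field precision", {
  cfg <- generatorConfig(seed = 104L, nMolecules = 6L)
  mols <- makeMolecules(cfg)
  mols[[2]]@atoms$formalCharge[1] <- 1L
  mols[[2]]@totalCharge <- 1
  f <- withr::local_tempfile(fileext = ".sdf")
  writeSDF(mols, f)
  back <- readSDF(f)
  expect_length(back, length(mols))
  for (k in seq_along(mols)) {
    expect_equal(atomCount(back[[k]]), atomCount(mols[[k]]))
    expect_equal(atomElements(back[[k]]), atomElements(mols[[k]]))
    bd <- function(m) {
      b <- m@bonds
      key <- paste(pmin(b$a, b$b), pmax(b$a, b$b), b$order, b$aromatic)
      sort(key)
    }
    expect_equal(bd(back[[k]]), bd(mols[[k]]))
    expect_equal(atomCoords(back[[k]]), atomCoords(mols[[k]]), tolerance = 1e-4)
    expect_equal(totalCharge(back[[k]]), totalCharge(mols[[k]]))
  }
})

test_that("an independent SDF reader agrees on the written file", {
  suppressPackageStartupMessages(requireNamespace("ChemmineR"))
  m <- readSDF(text = ethanol_sdf_text())[[1]]
  f <- withr::local_tempfile(fileext = ".sdf")
  writeSDF(m, f)
  sdf <- ChemmineR::read.SDFset(f)
  ab <- ChemmineR::atomblock(sdf[[1]])
  expect_equal(nrow(ab), 9L)
  expect_equal(unname(ab[, 1:3]), unname(atomCoords(m)), tolerance = 1e-4)
  expect_equal(nrow(ChemmineR::bondblock(sdf[[1]])), 8L)
})

test_that("distance matrix matches the brute-force double loop", {
  ## axis-aligned pair and a Pythagorean triangle first
  m2 <- Molecule("pair", c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 2)))
  expect_identical(distanceMatrix(m2)[1, 2], 2)
  m3 <- Molecule("tri", c("C", "C", "C"),
                 rbind(c(0, 0, 0), c(3, 0, 0), c(0, 4, 0)))
  D3 <- distanceMatrix(m3)
  expect_equal(sort(D3[upper.tri(D3)]), c(3, 4, 5))
  expect_true(all(diag(D3) == 0))
  ## property over seeded random molecules
  cfg <- generatorConfig(seed = 7L, nMolecules = 100L)
  for (i in seq_len(100L)) {
    m <- makeMolecule(cfg, i)
    D <- distanceMatrix(m)
    expect_equal(D, bf_distance_matrix(atomCoords(m)), tolerance = 1e-12)
    expect_identical(D, t(D))
  }
})

test_that("degenerate geometry is refused with the atom pair named", {
  m <- Molecule("clash", c("C", "C"), rbind(c(0, 0, 0), c(0.3, 0, 0)))
  expect_error(distanceMatrix(m), "atoms 1 and 2")
  expect_error(distanceMatrix(m), "degenerate")
  ## configurable threshold
  expect_silent(distanceMatrix(m, minDist = 0.2))
})

test_that("charge files roundtrip at printed precision", {
  cfg <- generatorConfig(seed = 55L, nMolecules = 1L, atomsRange = c(20L, 20L))
  m <- makeMolecule(cfg, 1L)
  set.seed(99)
  q <- rnorm(20); q <- q - mean(q)
  r <- new("ChargeResult", charges = q, chiBar = 2.5,
           parameterSetName = "t")
  f <- withr::local_tempfile(fileext = ".chg")
  writeCharges(m, r, f)
  back <- readCharges(f)
  expect_length(back, 1L)
  rec <- back[[moleculeId(m)]]
  expect_equal(rec$n, 20L)
  expect_lt(max(abs(rec$atoms$charge - q)), 5e-7)
  expect_equal(rec$chiBar, 2.5, tolerance = 1e-9)
  expect_equal(rec$atoms$typeKey, assignAtomTypes(m))
})

test_that("charge writing refuses a length mismatch and handles one atom", {
  m1 <- Molecule("he", "He", rbind(c(0, 0, 0)), totalCharge = 1)
  r1 <- new("ChargeResult", charges = 1.0, chiBar = 3.0,
            parameterSetName = "t")
  f <- withr::local_tempfile(fileext = ".chg")
  writeCharges(m1, r1, f)
  lines <- readLines(f)
  expect_equal(sum(nzchar(lines)), 2L)
  expect_match(lines[2], "1\\.000000")
  rbad <- new("ChargeResult", charges = c(0.5, 0.5), chiBar = 0,
              parameterSetName = "t")
  expect_error(writeCharges(m1, rbad, f), "mismatch")
})
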