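alanine_pdb <- c(
  "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
  "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C",
  "ATOM      3  C   ALA A   1      10.675   6.719  -4.147  1.00  0.00           C",
  "ATOM      4  O   ALA A   1       9.581   7.190  -4.493  1.00  0.00           O",
  "ATOM      5  CB  ALA A   1      11.891   4.630  -4.717  1.00  0.00           C",
  "END")

test_that("PDB reading yields authored residues and separates HETATM", {
  rec <- readReceptor(alanine_pdb)
  expect_s4_class(rec, "ReceptorStructure")
  expect_equal(nrow(atomTable(rec)), 5)
  expect_equal(nrow(residueKeys(rec)), 1)
  expect_equal(residueKeys(rec)$resname, "ALA")
  expect_equal(residueKeys(rec)$resno, 1)
  expect_equal(nrow(heteroAtoms(rec)), 0)

  withHet <- c(alanine_pdb[1:5],
    "HETATM    6  O1  LIG A 900       1.000   2.000   3.000  1.00  0.00           O",
    "END")
  rec2 <- readReceptor(withHet)
  expect_equal(nrow(atomTable(rec2)), 5)
  expect_equal(nrow(heteroAtoms(rec2)), 1)
  expect_equal(heteroAtoms(rec2)$resname, "LIG")
})

test_that("PDB write-then-read reproduces coordinates to 3 decimals", {
  fx <- makePocketFixture(6, 2, 3, seed = 4)
  rec <- fx$receptor
  rec2 <- readReceptor(writeReceptor(rec))
  expect_equal(nrow(atomTable(rec2)), nrow(atomTable(rec)))
  expect_equal(as.matrix(atomTable(rec2)[, c("x", "y", "z")]),
               round(as.matrix(atomTable(rec)[, c("x", "y", "z")]), 3),
               ignore_attr = TRUE)
  expect_equal(residueKeys(rec2), residueKeys(rec), ignore_attr = TRUE)
})

test_that("PDB format errors are reported with context", {
  expect_error(readReceptor(c("HEADER junk", "END")), "no ATOM/HETATM")
  bad <- alanine_pdb
  bad[3] <- "ATOM      3  C   ALA A   1      10.6xx   6.719  -4.147  1.00  0.00           C"
  expect_error(readReceptor(bad), "line 3")
})

test_that("altloc resolution keeps highest occupancy, ties prefer A", {
  two <- c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BALA A   1       1.000   0.000   0.000  0.60  0.00           C",
    "END")
  expect_message(rec <- readReceptor(two), "alternate locations")
  expect_equal(nrow(atomTable(rec)), 1)
  expect_equal(atomTable(rec)$x, 1.000)

  tie <- sub("0.40", "0.60", two, fixed = TRUE)
  expect_message(rec2 <- readReceptor(tie), "alternate locations")
  expect_equal(atomTable(rec2)$x, 0.000)
})

ethanol_sdf <- c("ethanol", "  synth", "",
  "  3  2  0  0  0  0  0  0  0  0999 V2000",
  "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
  "    1.5200    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
  "    2.2000    1.2000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
  "  1  2  1  0  0  0  0",
  "  2  3  1  0  0  0  0",
  "M  END", "$$$$")

ethanol_mol2 <- c("@<TRIPOS>MOLECULE", "ethanol", "3 2 1 0 0", "SMALL",
  "NO_CHARGES", "", "@<TRIPOS>ATOM",
  "      1 C1          0.0000    0.0000    0.0000 C.3     1  LIG    0.0000",
  "      2 C2          1.5200    0.0000    0.0000 C.3     1  LIG    0.0000",
  "      3 O1          2.2000    1.2000    0.0000 O.3     1  LIG    0.0000",
  "@<TRIPOS>BOND",
  "     1     1     2    1",
  "     2     2     3    1")

test_that("ligand reading populates atoms and bonds from both formats", {
  sdf <- readLigand(ethanol_sdf)
  expect_equal(nrow(atomTable(sdf)), 3)
  expect_equal(nrow(bondMatrix(sdf)), 2)
  expect_equal(atomTable(sdf)$element, c("C", "C", "O"))

  mol2 <- readLigand(ethanol_mol2)
  expect_equal(atomTable(mol2)$element, atomTable(sdf)$element)
  expect_equal(as.matrix(atomTable(mol2)[, c("x", "y", "z")]),
               as.matrix(atomTable(sdf)[, c("x", "y", "z")]),
               ignore_attr = TRUE)
  expect_equal(bondMatrix(mol2), bondMatrix(sdf))
})

test_that("ligand reading errors and warnings", {
  empty <- c("empty", "", "",
             "  0  0  0  0  0  0  0  0  0  0999 V2000", "M  END", "$$$$")
  expect_error(readLigand(empty), "zero-atom")
  expect_error(readLigand(c("just", "text")), "format")
  multi <- c(ethanol_mol2, ethanol_mol2)
  expect_warning(g <- readLigand(multi), "first")
  expect_equal(nrow(atomTable(g)), 3)
})

test_that("missing bond block falls through to perception with a warning", {
  nobonds <- c("@<TRIPOS>MOLECULE", "ethanol", "3 0 1 0 0", "SMALL",
    "NO_CHARGES", "", "@<TRIPOS>ATOM",
    "      1 C1          0.0000    0.0000    0.0000 C.3     1  LIG  0.0",
    "      2 C2          1.5200    0.0000    0.0000 C.3     1  LIG  0.0",
    "      3 O1          2.2000    1.2000    0.0000 O.3     1  LIG  0.0")
  expect_warning(g <- readLigand(nobonds), "perceiving bonds")
  expect_equal(nrow(bondMatrix(g)), 2)
})

test_that("MOL2 writer round-trips a graph", {
  fx <- makePocketFixture(4, 2, 2, seed = 9)
  g2 <- readLigand(fx$ligandText)
  expect_equal(atomTable(g2)$element, atomTable(fx$ligand)$element)
  expect_equal(bondMatrix(g2), bondMatrix(fx$ligand))
  expect_equal(as.matrix(atomTable(g2)[, c("x", "y", "z")]),
               round(as.matrix(atomTable(fx$ligand)[, c("x", "y", "z")]), 4),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("bond perception follows the covalent-radius rule", {
  cc <- data.frame(element = c("C", "C"), x = c(0, 1.54), y = 0, z = 0)
  expect_equal(nrow(perceiveBonds(cc)), 1)
  cc$x[2] <- 4.0
  expect_equal(nrow(perceiveBonds(cc)), 0)
  expect_error(perceiveBonds(data.frame(element = "Xx", x = 0, y = 0, z = 0)),
               "Xx")
})

test_that("bond perception on ideal benzene finds all 12 bonds", {
  ang <- 2 * pi * (0:5) / 6
  ring <- data.frame(element = "C", x = 1.39 * cos(ang),
                     y = 1.39 * sin(ang), z = 0)
  hs <- data.frame(element = "H", x = 2.48 * cos(ang),
                   y = 2.48 * sin(ang), z = 0)
  atoms <- rbind(ring, hs)
  b <- perceiveBonds(atoms)
  expect_equal(nrow(b), 12)
  # brute-force pairwise check of the same rule
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  radii <- c(C = 0.76, H = 0.31)
  expected <- 0
  for (i in 1:(nrow(atoms) - 1)) for (j in (i + 1):nrow(atoms)) {
    d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (d >= 0.4 && d <= radii[atoms$element[i]] + radii[atoms$element[j]] + 0.45)
      expected <- expected + 1
  }
  expect_equal(nrow(b), expected)
})

test_that("bond perception is invariant to atom reordering", {
  set.seed(42)
  for (rep in 1:5) {
    g <- random_molecule(sample(3:8, 1), seed = 100 + rep)
    a <- atomTable(g)
    b1 <- perceiveBonds(a)
    perm <- sample(nrow(a))
    b2 <- perceiveBonds(a[perm, , drop = FALSE])
    # compare as unordered sets of original-index pairs
    key <- function(b, map = seq_len(nrow(a))) {
      if (!nrow(b)) return(character(0))
      apply(b, 1, function(r) paste(sort(map[r]), collapse = "-"))
    }
    expect_setequal(key(b2, perm), key(b1))
  }
})

test_that("RMSD series reading handles XVG, CSV and unit conversion", {
  xvg <- c("# GROMACS-style comments", "@ title \"rmsd\"",
           "1 0.10", "2 0.20", "3 0.15")
  s_nm <- readRmsdSeries(xvg, unit = "nm")
  expect_equal(seriesValues(s_nm), c(1.0, 2.0, 1.5))
  csv <- c("time,rmsd", "1,1.0", "2,2.0", "3,1.5")
  s_a <- readRmsdSeries(csv, unit = "angstrom")
  expect_equal(seriesValues(s_a), c(1.0, 2.0, 1.5))
  expect_equal(seriesValues(s_nm), seriesValues(readRmsdSeries(xvg, "angstrom")) * 10)
  expect_equal(seriesTimes(s_nm), c(1, 2, 3))
})

test_that("RMSD series reading rejects malformed input", {
  expect_error(readRmsdSeries(c("2 0.2", "1 0.1"), "nm"),
               "strictly increasing")
  expect_error(readRmsdSeries("1 0.1", "nm"), "at least 2")
  expect_error(readRmsdSeries(c("1 a", "2 b", "3 c"), "nm"), "non-numeric")
})
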