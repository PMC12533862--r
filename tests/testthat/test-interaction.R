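# minimal single-residue receptor with one heavy atom at a given distance
.one_atom_receptor <- function(dist, element = "O", extraH = NULL) {
  atoms <- data.frame(element = element, name = "OD1", x = dist, y = 0,
                      z = 0, is_hydrogen = element == "H", chain = "A",
                      resno = 75L, insert = "", resname = "ASN",
                      stringsAsFactors = FALSE)
  if (!is.null(extraH)) atoms <- rbind(atoms, extraH)
  new("ReceptorStructure", atoms = atoms,
      hetero = atoms[0, , drop = FALSE])
}

.one_atom_ligand <- function() {
  MolecularGraph(data.frame(element = "C", name = "C1", x = 0, y = 0, z = 0),
                 NULL, provenance = "synthetic")
}

test_that("close contact is a hard 5 Angstrom gate on min heavy distance", {
  lig <- .one_atom_ligand()
  hit <- findCloseContacts(lig, .one_atom_receptor(4.9), cutoff = 5)
  expect_true(hit$contact)
  expect_equal(hit$min_dist, 4.9)

  miss <- findCloseContacts(lig, .one_atom_receptor(5.1), cutoff = 5)
  expect_false(miss$contact)
  # context reporting extends to cutoff + 2
  expect_equal(nrow(findCloseContacts(lig, .one_atom_receptor(7.5), 5)), 0)
  expect_error(findCloseContacts(
    MolecularGraph(data.frame(element = "H", name = "H1",
                              x = 0, y = 0, z = 0), NULL),
    .one_atom_receptor(3)), "heavy")
})

test_that("contact set grows monotonically with the cutoff", {
  fx <- makePocketFixture(7, 3, 5, seed = 31)
  prev <- 0
  for (cut in c(3, 4, 5, 6, 8)) {
    cc <- findCloseContacts(fx$ligand, fx$receptor, cutoff = cut)
    n <- sum(cc$contact)
    expect_gte(n, prev)
    prev <- n
  }
})

# N-H donor ligand; acceptor placement chosen by the caller
.nh_ligand <- function() {
  # N at origin, H along +x at 1.0 A; acceptor placement handled by caller
  MolecularGraph(data.frame(
    element = c("N", "H"), name = c("N1", "H1"),
    x = c(0, 1.0), y = 0, z = 0, stringsAsFactors = FALSE),
    rbind(c(1, 2)), provenance = "synthetic")
}

test_that("hydrogen bonds obey distance and angle gates", {
  lig <- .nh_ligand()
  # acceptor on the N-H axis: angle 180, H...A = 1.9
  hb <- detectHBonds(lig, .one_atom_receptor(2.9))
  expect_equal(nrow(hb), 1)
  expect_equal(hb$dist_HA, 1.9, tolerance = 1e-9)
  expect_gte(hb$angle, 170)

  # same H...A distance but a ~90 degree D-H-A angle: rejected
  atoms <- data.frame(element = "O", name = "OD1", x = 1.0, y = 1.9, z = 0,
                      is_hydrogen = FALSE, chain = "A", resno = 75L,
                      insert = "", resname = "ASN", stringsAsFactors = FALSE)
  rec90 <- new("ReceptorStructure", atoms = atoms,
               hetero = atoms[0, , drop = FALSE])
  expect_equal(nrow(detectHBonds(lig, rec90)), 0)
})

test_that("heavy-atom fallback applies only when the donor partner lacks H", {
  # bare ligand N (no hydrogens anywhere): fallback on D-A distance
  bare <- MolecularGraph(data.frame(element = "N", name = "N1",
                                    x = 0, y = 0, z = 0), NULL)
  hb <- detectHBonds(bare, .one_atom_receptor(3.2))
  expect_equal(nrow(hb), 1)
  expect_true(is.na(hb$angle))
  hb2 <- detectHBonds(bare, .one_atom_receptor(3.2),
                      hbondCriteria(heavyAtomFallback = FALSE))
  expect_equal(nrow(hb2), 0)
  # out of D-A range: nothing even under fallback
  expect_equal(nrow(detectHBonds(bare, .one_atom_receptor(3.6))), 0)
})

test_that("planted pocket fixtures recover exactly the planted interactions", {
  set.seed(99)
  for (seed in 1:8) {
    nk <- sample(0:9, 1)
    nh <- if (nk > 0) sample(0:nk, 1) else 0
    fx <- makePocketFixture(nk, nh, nDecoys = 4, seed = 600 + seed)
    cc <- findCloseContacts(fx$ligand, fx$receptor, cutoff = 5)
    got <- cc[cc$contact, c("chain", "resno", "resname")]
    want <- fx$groundTruth$contactResidues[, c("chain", "resno", "resname")]
    expect_equal(got[order(got$resno), ], want[order(want$resno), ],
                 ignore_attr = TRUE)
    hb <- detectHBonds(fx$ligand, fx$receptor)
    expect_equal(sort(hb$resno), sort(fx$groundTruth$hbondResidues$resno))
  }
})

test_that("key-residue score and overlap follow the weighted formula", {
  # no contacts at all
  fx0 <- makePocketFixture(0, 0, 5, seed = 41)
  r0 <- keyResidueScore(fx0$ligand, fx0$receptor)
  expect_equal(interactionScore(r0), 0)
  expect_equal(keyResidueOverlap(r0), 0)

  # all 9 key residues H-bonded: score 18, overlap 1 under default weights
  fx9 <- makePocketFixture(9, 9, 3, seed = 42)
  r9 <- keyResidueScore(fx9$ligand, fx9$receptor)
  expect_equal(interactionScore(r9), 18)
  expect_equal(keyResidueOverlap(r9), 1.0)

  # 3 H-bonded + 2 contact-only of 9: score 2*3 + 1*2 = 8, overlap 5/9
  fx5 <- makePocketFixture(5, 3, 4, seed = 43)
  r5 <- keyResidueScore(fx5$ligand, fx5$receptor)
  expect_equal(interactionScore(r5), 8)
  expect_equal(keyResidueOverlap(r5), 5 / 9)

  # custom weights flow through the score but not the overlap
  rw <- keyResidueScore(fx5$ligand, fx5$receptor,
                        weights = c(hbond = 5, contact = 0.5))
  expect_equal(interactionScore(rw), 5 * 3 + 0.5 * 2)
  expect_equal(keyResidueOverlap(rw), 5 / 9)
})

test_that("score is invariant to key-list ordering and bounded by weights", {
  fx <- makePocketFixture(6, 2, 3, seed = 44)
  spec <- sglt2KeyResidues()
  set.seed(7)
  shuffled <- keyResidueSpec(spec@residues[sample(9), ])
  a <- keyResidueScore(fx$ligand, fx$receptor, spec)
  b <- keyResidueScore(fx$ligand, fx$receptor, shuffled)
  expect_equal(interactionScore(a), interactionScore(b))
  expect_equal(keyResidueOverlap(a), keyResidueOverlap(b))
  expect_lte(interactionScore(a), 2 * 9)
  expect_gte(keyResidueOverlap(a), 0)
  expect_lte(keyResidueOverlap(a), 1)
})

test_that("key residues absent from the receptor warn and count unengaged", {
  fx <- makePocketFixture(2, 1, 0, seed = 45)
  # receptor truncated to the two planted residues only
  at <- atomTable(fx$receptor)
  trimmed <- new("ReceptorStructure",
                 atoms = at[at$resno %in% c(75, 80), , drop = FALSE],
                 hetero = at[0, , drop = FALSE])
  expect_warning(r <- keyResidueScore(fx$ligand, trimmed), "absent")
  expect_equal(keyResidueOverlap(r), 2 / 9)
})
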