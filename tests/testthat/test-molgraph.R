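test_that("SMILES parse recovers atom, bond and aromaticity counts", {
  g <- parseSmiles("ClCCl")
  expect_equal(atomCount(g), 3)
  expect_equal(bondCount(g), 2)
  expect_equal(sum(atoms(g)$aromatic), 0)
  expect_true(all(bonds(g)$order == 1))

  # 2,4-dichlorophenol, written Kekule
  g2 <- parseSmiles("C1=CC(=C(C=C1Cl)Cl)O")
  expect_equal(atomCount(g2), 9)
  expect_equal(sum(atoms(g2)$aromatic), 6)

  # chlorinated methoxycinnamic acid: 14 heavy atoms, exactly one Cl
  g3 <- parseSmiles("COC1=C(C=C(C=C1)C=CC(=O)O)Cl")
  expect_equal(atomCount(g3), 14)
  expect_equal(sum(atoms(g3)$element == "Cl"), 1)
})

test_that("malformed SMILES report the offending position, valence violations error", {
  expect_error(parseSmiles("C1CC"), "unclosed ring")
  expect_error(parseSmiles("C(C"), "unclosed branch")
  expect_error(parseSmiles("CC)"), "position 3")
  expect_error(parseSmiles("C$C"), "position 2")
  expect_error(parseSmiles(""), "non-empty")
  expect_error(parseSmiles("C(C)(C)(C)(C)C"), "valence")
  expect_error(parseSmiles("Cl=C"), "valence")
  expect_error(parseSmiles("[Xe]"), "unsupported element")
})

test_that("Kekule and aromatic writings normalize to the same graph", {
  a <- parseSmiles("c1ccccc1")
  k <- parseSmiles("C1=CC=CC=C1")
  expect_equal(sum(atoms(k)$aromatic), 6)
  expect_equal(sort(atoms(a)$hcount), sort(atoms(k)$hcount))
  expect_equal(sort(bonds(a)$order), sort(bonds(k)$order))
  # quinones must not aromatize: ring pi count is 4
  q <- parseSmiles("C1=C(C(=O)C(=CC1=O)Cl)Cl")
  expect_equal(sum(atoms(q)$aromatic), 0)
  # the biphenyl inter-ring bond stays single
  bp <- parseSmiles("c1ccc(c2ccccc2)cc1")
  expect_equal(sum(bonds(bp)$order == 1.5), 12)
  expect_equal(sum(bonds(bp)$order == 1), 1)
})

test_that("electron states follow element valence and hydrogen suppression", {
  es <- electronStates(parseSmiles("CCl"))
  expect_equal(es$delta, c(1, 1))
  expect_equal(es$deltav, c(1, 7))
  expect_equal(es$quantum, c(2, 3))

  es2 <- electronStates(parseSmiles("CC"))
  expect_equal(es2$delta, c(1, 1))
  expect_equal(es2$deltav, c(1, 1))

  # symmetric diol: both oxygens identical
  es3 <- electronStates(parseSmiles("OCCO"))
  expect_equal(es3[1, ], es3[4, ], ignore_attr = TRUE)

  expect_error(electronStates(parseSmiles("[Se]")), "unsupported")
})

test_that("E-state atom types are a deterministic function of the bond environment", {
  ty <- estateAtomTypes(parseSmiles("c1ccccc1Cl"))
  expect_equal(sum(ty == "aasC"), 1)
  expect_equal(sum(ty == "aaCH"), 5)
  expect_equal(sum(ty == "sCl"), 1)
  expect_equal(estateAtomTypes(parseSmiles("CN(C)C"))[2], "sssN")
  expect_equal(estateAtomTypes(parseSmiles("CC(C)=O"))[4], "dO")
  # partition: one symbol per heavy atom
  for (sm in fixtureSmiles()) {
    g <- parseSmiles(sm)
    expect_length(estateAtomTypes(g), atomCount(g))
  }
})

test_that("distance matrix equals BFS on random molecules and is metric", {
  set.seed(71)
  sms <- genMolecules(generatorConfig(n = 20, seed = 71))
  for (sm in sms) {
    g <- parseSmiles(sm)
    D <- distanceMatrix(g)
    expect_equal(D, bfsDistances(g))
    expect_equal(D, t(D))
    expect_true(all(diag(D) == 0))
    n <- nrow(D)
    if (n >= 3) {
      trip <- sample(n, 3)
      expect_lte(D[trip[1], trip[3]], D[trip[1], trip[2]] + D[trip[2], trip[3]])
    }
  }
})

test_that("write-parse round trip preserves the molecular graph", {
  for (sm in fixtureSmiles()) {
    g <- parseSmiles(sm)
    g2 <- parseSmiles(writeSmiles(g))
    expect_equal(graphSignature(g2), graphSignature(g), label = sm)
  }
  # randomized rewritings of a branched aromatic stay isomorphic
  g <- parseSmiles("COC1=C(C=C(C=C1)C=CC(=O)O)Cl")
  sig <- graphSignature(g)
  set.seed(99)
  for (k in 1:50) {
    alt <- writeSmiles(g, shuffle = TRUE)
    expect_equal(graphSignature(parseSmiles(alt)), sig, label = alt)
  }
})

test_that("nominal molecular weight uses integer isotope-free masses", {
  expect_equal(nominalMW(parseSmiles("CCl")), 12 + 3 + 35)          # CH3Cl = 50
  expect_equal(nominalMW(parseSmiles("c1ccccc1Cl")), 6 * 12 + 5 + 35) # 112
})
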