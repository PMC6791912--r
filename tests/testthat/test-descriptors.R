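test_that("carbon-type counts classify hybridization and carbon neighbors", {
  expect_equal(unname(carbonTypes(parseSmiles("C=C"))["C1SP2"]), 2)
  expect_equal(unname(carbonTypes(parseSmiles("c1ccccc1"))["C2SP2"]), 6)
  ct <- carbonTypes(parseSmiles("CC(C)(C)C"))
  expect_equal(unname(ct["C1SP3"]), 4)
  expect_equal(unname(ct["C4SP3"]), 1)
  # sums over k equal the total carbons of each hybridization
  g <- parseSmiles("CC(=O)c1ccc(Cl)cc1")
  ct2 <- carbonTypes(g)
  expect_equal(sum(ct2), sum(atoms(g)$element == "C"))
})

test_that("pi path counts equal exhaustive enumeration", {
  # two 8-bond paths in n-decane, all orders 1
  expect_equal(unname(piPathCounts(parseSmiles("CCCCCCCCCC"))["piPC8"]), log(3))
  # longest simple path in a 6-ring has 5 bonds
  expect_equal(unname(piPathCounts(parseSmiles("c1ccccc1"))["piPC8"]), 0)
  # a single heavy atom supports no paths
  expect_true(all(piPathCounts(parseSmiles("C")) == 0))
  for (sm in fixtureSmiles()) {
    g <- parseSmiles(sm)
    expect_equal(unname(piPathCounts(g, 10L)), log(1 + brutePathSums(g, 10L)),
                 tolerance = 1e-12, label = sm)
  }
})

test_that("Barysz VE1 matches the closed form and a dense brute force", {
  # ethane: matrix [[0,1],[1,0]], principal eigenvector (1,1)/sqrt(2)
  expect_equal(baryszVE1(parseSmiles("CC"), "mass"), sqrt(2), tolerance = 1e-12)
  expect_equal(baryszVE1(parseSmiles("CC"), "atomic-number"), sqrt(2), tolerance = 1e-12)
  # all-carbon molecule: mass and atomic-number weightings coincide
  expect_equal(baryszVE1(parseSmiles("CCCC"), "mass"),
               baryszVE1(parseSmiles("CCCC"), "atomic-number"), tolerance = 1e-12)
  # acyclic (unique-shortest-path) molecules against the brute force
  for (sm in c("CCCCl", "CCC(=O)Cl", "CC(C)CO", "CCSC", "ClCCCl")) {
    g <- parseSmiles(sm)
    expect_equal(baryszVE1(g, "mass"), bruteBaryszVE1(g, "mass"),
                 tolerance = 1e-10, label = sm)
    expect_equal(baryszVE1(g, "atomic-number"), bruteBaryszVE1(g, "atomic-number"),
                 tolerance = 1e-10, label = sm)
  }
  expect_warning(baryszVE1(parseSmiles("CC.CC")), "largest component")
  expect_error(suppressWarnings(baryszVE1(parseSmiles("C.C"))), "at least 2")
})

test_that("ETA_Shape_Y is the degree-3 alpha fraction", {
  expect_equal(etaShapeY(parseSmiles("CCCC")), 0)
  expect_equal(etaShapeY(parseSmiles("CC(C)C")), 0.25)
  set.seed(8)
  for (sm in genMolecules(generatorConfig(n = 25, seed = 8))) {
    v <- etaShapeY(parseSmiles(sm))
    expect_gte(v, 0); expect_lte(v, 1)
  }
})

test_that("Galvez charge indices match the loop-wise brute force", {
  expect_equal(galvezChargeIndex(parseSmiles("CC"), 1), 0)
  # order beyond the graph diameter
  expect_equal(galvezChargeIndex(parseSmiles("CCC"), 7), 0)
  for (sm in c("CCC", "CCCCl", "c1ccccc1Cl", "CC(C)CO")) {
    g <- parseSmiles(sm)
    for (k in 1:4)
      expect_equal(galvezChargeIndex(g, k), bruteGalvez(g, k),
                   tolerance = 1e-10, label = paste(sm, k))
  }
})

test_that("rule-based counts follow the documented acceptor and saturated-H rules", {
  expect_equal(unname(simpleCounts(parseSmiles("c1ccccc1"))["nHBAcc"]), 0)
  expect_equal(unname(simpleCounts(parseSmiles("CC(C)=O"))["nHBAcc"]), 1)
  expect_equal(unname(simpleCounts(parseSmiles("CC"))["nHCsatu"]), 6)
  # pyridine N accepts, amide N does not (its carbonyl O does)
  expect_equal(unname(simpleCounts(parseSmiles("c1ccncc1"))["nHBAcc"]), 1)
  expect_equal(unname(simpleCounts(parseSmiles("CC(=O)NC"))["nHBAcc"]), 1)
})

test_that("descriptors are invariant to how the SMILES is written", {
  set.seed(31)
  for (sm in c("COC1=C(C=C(C=C1)C=CC(=O)O)Cl", "CC(C)(C)c1ccc(Cl)cc1",
               "CCC(=O)OCC(Cl)C")) {
    g <- parseSmiles(sm)
    ref <- computeDescriptors(g)
    for (k in 1:17) {
      alt <- writeSmiles(g, shuffle = TRUE)
      expect_equal(computeDescriptors(parseSmiles(alt)), ref,
                   tolerance = 1e-9, label = alt)
    }
  }
})

test_that("descriptor matrices record failures as missing rows, never drop them", {
  dm <- computeDescriptorMatrix(c("CCl", "CCCl", "c1ccccc1Cl"),
                                descriptors = c("nsCl", "piPC2", "VE1_Dzm",
                                                "ETA_Shape_Y", "nHBAcc"))
  expect_equal(dim(descriptorValues(dm)), c(3, 5))
  expect_false(anyNA(descriptorValues(dm)))
  expect_true(all(descriptorProvenance(dm) == "native"))

  expect_warning(
    dm2 <- computeDescriptorMatrix(c("CCl", "not-a-smiles", "CCCl"),
                                   ids = c("a", "b", "c")),
    "failed")
  expect_true(all(is.na(descriptorValues(dm2)["b", ])))
  expect_false(anyNA(descriptorValues(dm2)[c("a", "c"), ]))
  expect_error(suppressWarnings(computeDescriptorMatrix(c("$$", "%%"))),
               "every compound")
})

test_that("imported descriptor CSVs align with native matrices on compound id", {
  csv <- tempfile(fileext = ".csv")
  writeLines(c("Name,XLogP,ATS0m,nRing",
               "a,1.25,10.5,1",
               "b,NA,3.5,0"), csv)
  dm <- importDescriptorCsv(csv)
  expect_equal(dim(descriptorValues(dm)), c(2, 3))
  expect_true(is.na(descriptorValues(dm)["b", "XLogP"]))
  expect_true(all(descriptorProvenance(dm) == "imported"))

  native <- computeDescriptorMatrix(c("CCl", "CCCl"), ids = c("b", "a"))
  merged <- mergeDescriptors(native, dm)
  expect_equal(sort(compoundIds(merged)), c("a", "b"))
  expect_equal(ncol(descriptorValues(merged)),
               ncol(descriptorValues(native)) + 3)
  expect_equal(descriptorValues(merged)["a", "XLogP"], 1.25)

  writeLines(c("Foo,X", "a,1"), csv)
  expect_error(importDescriptorCsv(csv), "format error")
})
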