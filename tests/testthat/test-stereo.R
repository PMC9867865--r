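test_that("true tetrahedral detection follows the four-substituent rules", {
  # four distinct substituents: direct true center
  m <- stereoModel("FC(Cl)Br")
  expect_length(m@trueCenters, 1L)
  expect_identical(m@trueCenters[[1]]$kind, "tet")

  # two identical valence-1 neighbors (implicit hydrogens): rejected
  expect_length(stereoModel("CCC")@trueCenters, 0L)
  expect_length(stereoModel("CCC")@paraCenters, 0L)

  # two identical CH3 branches swapped by a center-fixing automorphism:
  # rejected as true (and not retained as para without true centers)
  m <- stereoModel("CC(Cl)C")  # 2-chloropropane: center has two CH3
  expect_length(m@trueCenters, 0L)
})

test_that("true cis/trans detection pairs potential half-centers", {
  expect_length(stereoModel("C=C")@trueCenters, 0L)      # two H per half
  m <- stereoModel("CC=CC")                              # 2-butene
  expect_length(m@trueCenters, 1L)
  expect_identical(m@trueCenters[[1]]$kind, "ct")
  expect_identical(nrow(stereoisomers("CC=CC")), 2L)
  expect_identical(bruteStereoCount("CC=CC"), 2L)
  # double bond inside a cycle carries no stereochemistry
  expect_length(stereoModel("C1CCC=CC1")@trueCenters, 0L)
  # cumulated double bonds: the middle atom has two double bonds
  expect_length(stereoModel("CC=C=CC")@trueCenters, 0L)
})

test_that("ClC(Br)CC(Br)Cl shows the meso merge and the enantiomer pair", {
  st <- stereoisomers("ClC(Br)CC(Br)Cl", inputOrder = TRUE)
  expect_identical(nrow(st), 3L)
  expect_setequal(st$config, c("[0,0]", "[0,1]", "[1,0]"))  # [1,1] merged
  expect_true(all(st$nTet == 2L))
  meso <- st[st$config == "[0,0]", ]
  expect_true(is.na(meso$enantiomer))
  expect_identical(st$enantiomer[st$config == "[0,1]"],
                   which(st$config == "[1,0]"))
  expect_identical(st$enantiomer[st$config == "[1,0]"],
                   which(st$config == "[0,1]"))
})

test_that("BrC=CC=CBr merges [0,1] with [1,0] and writes chained slashes", {
  st <- stereoisomers("BrC=CC=CBr", inputOrder = TRUE)
  expect_identical(nrow(st), 3L)
  expect_setequal(st$config, c("[0,0]", "[0,1]", "[1,1]"))
  expect_true(all(st$nCt == 2L))
  expect_true(all(is.na(st$enantiomer)))   # no tetrahedral centers
  ciscis <- st$smiles[st$config == "[1,1]"]
  # never the invalid double slash; structurally the cis,cis diene
  expect_false(grepl("\\\\/|/\\\\", ciscis))
  expect_true(rdkitAvailable())
  expect_identical(rdkitCanonical(c(ciscis, "Br/C=C\\C=C/Br"))[1],
                   rdkitCanonical("Br/C=C\\C=C/Br"))
})

test_that("identity permutation leaves configuration vectors unchanged", {
  g <- parseSmiles("ClC(Br)CC(Br)Cl")
  aut <- graphAutomorphisms(g)
  plan <- attr(g, "plan")
  model <- molenum:::.detectCenters(g, aut, plan)
  maps <- molenum:::.centerMaps(model, aut, g)
  idIdx <- which(vapply(aut, function(p) all(p == seq_along(p)), logical(1)))
  for (v in list(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L))) {
    expect_identical(molenum:::.transportConfig(v, maps[[idIdx]]), v)
  }
  # the end-to-end flip transfers configurations with odd parity here:
  # [0,0] maps to [1,1] (the Fig. 6-style meso identification)
  flipIdx <- which(vapply(aut, function(p) any(p != seq_along(p)), logical(1)))
  expect_identical(molenum:::.transportConfig(c(0L, 0L), maps[[flipIdx]]),
                   c(1L, 1L))
})

test_that("group action closure: transported vectors canonicalize to a reported one", {
  for (smi in c("ClC(Br)CC(Br)Cl", "BrC=CC=CBr", "CC(Cl)C(Br)CC")) {
    g <- parseSmiles(smi)
    aut <- graphAutomorphisms(g)
    plan <- attr(g, "plan")
    model <- molenum:::.detectCenters(g, aut, plan)
    expect_length(model@paraCenters, 0L)   # true-only closure check
    maps <- molenum:::.centerMaps(model, aut, g)
    reported <- molenum:::.enumerateTrue(length(model@trueCenters), maps)
    keys <- vapply(reported, paste, "", collapse = ",")
    for (v in reported) for (map in maps) {
      t <- molenum:::.transportConfig(v, map)
      canon <- t
      for (m2 in maps) {
        t2 <- molenum:::.transportConfig(t, m2)
        if (molenum:::.lexLess(t2, canon)) canon <- t2
      }
      expect_true(paste(canon, collapse = ",") %in% keys)
    }
  }
})

test_that("para stereocenters are retained at midpoints and counted like the oracle", {
  # pentane-2,3,4-triol-like symmetry: the central atom is a retained para
  # center and the total count exceeds the true-center count alone
  m <- stereoModel("CC(O)C(O)C(O)C")
  expect_length(m@trueCenters, 2L)
  expect_length(m@paraCenters, 1L)
  st <- stereoisomers("CC(O)C(O)C(O)C")
  expect_identical(nrow(st), 4L)
  expect_gt(nrow(st), 3L)  # more than the 3 from two true centers alone
  expect_identical(bruteStereoCount("CC(O)C(O)C(O)C"), 4L)

  # 2,3,4-trichloropentane: the d/l pair has an inactive central center
  st2 <- stereoisomers("CC(Cl)C(Cl)C(Cl)C")
  expect_identical(nrow(st2), 4L)
  expect_identical(sum(grepl("-1", st2$config, fixed = TRUE)), 2L)
  expect_identical(sort(st2$nTet), c(2L, 2L, 3L, 3L))

  # no true stereocenters and no cycles: nothing retained
  expect_length(stereoModel("CC(C)C")@paraCenters, 0L)

  # ring-only para centers are not considered (stated limitation)
  st3 <- stereoisomers("CC1CCC(C)CC1")  # 1,4-dimethylcyclohexane
  expect_identical(nrow(st3), 1L)
})

test_that("enantiomer pairing is an involution and meso forms are self-images", {
  st <- stereoisomers("CC(Cl)C(Br)CC")   # two true tetrahedral centers
  expect_identical(nrow(st), 4L)
  for (i in seq_len(nrow(st))) {
    j <- st$enantiomer[i]
    if (!is.na(j)) expect_identical(st$enantiomer[j], i)
  }
  # cis/trans-only molecule reports no enantiomer
  expect_true(all(is.na(stereoisomers("CC=CC")$enantiomer)))
  # single tetrahedral center: [0] and [1] are each other's enantiomers
  st1 <- stereoisomers("CC(Cl)Br")
  expect_identical(nrow(st1), 2L)
  expect_identical(st1$enantiomer, c(2L, 1L))
})

test_that("stereoisomer counts are bounded by the stereocenter count", {
  for (f in c("C6H12", "C4H8Br2")) {
    for (rec in records(enumerateIsomers(f))) {
      nC <- length(rec$stereo)
      expect_gte(nC, 1L)
      m <- stereoModel(rec$isomer)
      nCenters <- length(m@trueCenters) + length(m@paraCenters)
      expect_lte(nC, 2^nCenters)
      if (nCenters == 0L) expect_identical(nC, 1L)
    }
  }
})
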