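test_that("the formula mini-language parses integers, lists, ranges and united atoms", {
  f <- parseFormula("C[1-20]H[4-42]")
  expect_identical(f@free$C, 1:20)
  expect_identical(f@free$H, 4:42)

  f <- parseFormula("H[0,2,4,5]")
  expect_identical(f@free$H, c(0L, 2L, 4L, 5L))

  f <- parseFormula("{CH1}1{CH2}2{OH1}3")
  expect_identical(nrow(f@fixed), 3L)
  cf <- expandFormula(f)
  expect_length(cf, 1L)
  expect_identical(cf[[1]]$label, "C3H8O3")
  expect_identical(cf[[1]]$counts[["H"]], 8L)

  # a count defaults to one
  expect_identical(expandFormula("CH4O")[[1]]$label, "CH4O")
})

test_that("malformed formulas fail with positioned errors", {
  expect_error(parseFormula("C2Xx3"), "position 3")
  expect_error(parseFormula("C[]"), "empty count-set")
  expect_error(parseFormula("C[4-2]"), "descending")
  expect_error(parseFormula("{CH5}1"), "exceeds valence")
  expect_error(parseFormula("C2C3"), "twice")
  expect_error(parseFormula(""), "empty formula")
})

test_that("expansion prunes odd-valence and impossible combinations", {
  # C1H[3-5]: only H4 has an even valence sum
  cf <- expandFormula("C1H[3-5]")
  expect_length(cf, 1L)
  expect_identical(cf[[1]]$label, "CH4")
  # too many hydrogens: negative unsaturations pruned
  expect_length(expandFormula("C2H8"), 0L)
})

test_that("property filters accept and reject on the isomer's computed values", {
  rs0 <- restrictionSet()
  hexane <- parseSmiles("CCCCCC")
  cyclohexane <- parseSmiles("C1CCCCC1")
  expect_true(passesFilters(hexane, rs0))
  expect_true(passesFilters(cyclohexane, rs0))
  expect_true(passesFilters(hexane, restrictionSet(unsaturations = 0)))
  expect_false(passesFilters(cyclohexane, restrictionSet(cycles = 0)))
  expect_true(passesFilters(cyclohexane, restrictionSet(cycles = 1)))
  expect_false(passesFilters(parseSmiles("C#CC"),
                             restrictionSet(tripleBonds = 0)))
  expect_true(passesFilters(hexane, restrictionSet(totalBonds = 5)))
})

test_that("acyclic C5H8Br2 isomers all hold exactly one double bond", {
  e <- enumerateIsomers("C5H8Br2", restrictionSet(cycles = 0), stereo = FALSE)
  for (rec in records(e)) {
    A <- adjacency(rec$isomer)
    expect_identical(sum(A[upper.tri(A)] == 2L), 1L)
    expect_identical(cycleCount(A), 0L)
  }
})

test_that("the saturated-alkane filter run reproduces the constitutional series", {
  rs <- restrictionSet(unsaturations = 0)
  got <- countIsomers("C[1-8]H[2-18]", rs, stereo = FALSE)$constitutional
  expect_identical(got, 1L + 1L + 1L + 2L + 3L + 5L + 9L + 18L)
})

test_that("substructure counting follows the one-atom-overlap convention", {
  expect_identical(countSubstructure("CCCC", "CC"), 3L)
  expect_identical(countSubstructure("CCCC", "CCC"), 1L)
  expect_error(substructure(atoms = character(0), stack = integer(0)), "empty")
  # wildcard and pinned-hydrogen pattern atoms
  expect_identical(countSubstructure("CC(C)O",
    substructure(atoms = c("*", "O"), stack = 1L)), 1L)
  expect_identical(countSubstructure("CCO",
    substructure(atoms = c("{CH3}", "{CH2}"), stack = 1L)), 1L)
  expect_identical(countSubstructure("CCO",
    substructure(atoms = c("{CH3}", "{CH3}"), stack = 1L)), 0L)
  # bond orders must match exactly
  expect_identical(countSubstructure("C=CC", substructure(smiles = "C=C")), 1L)
  expect_identical(countSubstructure("CCC", substructure(smiles = "C=C")), 0L)
  # every molecule contains itself
  for (rec in records(enumerateIsomers("C4H8O1", stereo = FALSE))) {
    g <- rec$isomer@graph
    pat <- substructure(atoms = sprintf("{%sH%d}", atomTable(g)$symbol,
                                        atomTable(g)$nH),
                        stack = t(adjacency(g))[lower.tri(adjacency(g))])
    expect_gte(countSubstructure(g, pat), 1L)
  }
})

test_that("substructure occurrence restrictions filter enumerated isomers", {
  rs <- restrictionSet(cycles = 0,
    substructures = list(substructure(smiles = "CO", count = 0)))
  e <- enumerateIsomers("C3H8O1", rs, stereo = FALSE)
  expect_identical(length(records(e)), 0L)  # every acyclic C3H8O has a C-O bond
  rs2 <- restrictionSet(cycles = 0,
    substructures = list(substructure(smiles = "CO", count = 1:9)))
  e2 <- enumerateIsomers("C3H8O1", rs2, stereo = FALSE)
  expect_identical(length(records(e2)), 3L)
})

test_that("alternating six-ring deduplication keeps one Kekule form", {
  # benzene and pyridine: the two Kekule matrices are related by a ring
  # symmetry, so the canonical enumeration already reports one isomer, with
  # or without the extra recognition
  rs <- restrictionSet(cycles = 1, doubleBonds = 3, singleBonds = 3)
  with_ <- enumerateIsomers("C6H6", rs, stereo = FALSE, aromaticDedup = TRUE)
  without <- enumerateIsomers("C6H6", rs, stereo = FALSE)
  expect_identical(length(records(with_)), length(records(without)))
  benz <- canonicalSmiles(parseSmiles("C1=CC=CC=C1"))
  expect_identical(sum(vapply(records(with_), `[[`, "", "smiles") == benz), 1L)
  withP <- enumerateIsomers("C5H5N1", rs, stereo = FALSE, aromaticDedup = TRUE)
  pyr <- canonicalSmiles(parseSmiles("C1=CC=NC=C1"))
  expect_identical(sum(vapply(records(withP), `[[`, "", "smiles") == pyr), 1L)

  # ortho-disubstituted rings DO have two non-isomorphic Kekule matrices:
  # exactly one of the pair is kept as the representative
  g1 <- parseSmiles("ClC1=C(Cl)C=CC=C1")  # Cl carbons doubly bonded
  g2 <- parseSmiles("ClC1=CC=CC=C1Cl")    # Cl carbons singly bonded
  expect_false(canonicalSmiles(g1) == canonicalSmiles(g2))
  expect_identical(sum(molenum:::.kekuleRepresentative(g1, canonicalSmiles(g1)),
                       molenum:::.kekuleRepresentative(g2, canonicalSmiles(g2))),
                   1L)

  # in a full enumeration the ortho pair collapses to a single record
  rs2 <- restrictionSet(cycles = 1, doubleBonds = 3, singleBonds = 5)
  w0 <- enumerateIsomers("C6H4Cl2", rs2, stereo = FALSE)
  w1 <- enumerateIsomers("C6H4Cl2", rs2, stereo = FALSE, aromaticDedup = TRUE)
  expect_identical(length(records(w0)) - length(records(w1)), 1L)
  ortho <- vapply(c(canonicalSmiles(g1), canonicalSmiles(g2)), function(s)
    sum(vapply(records(w1), `[[`, "", "smiles") == s), 0L)
  expect_identical(sum(ortho), 1L)

  # molecules without alternating six-rings pass unchanged
  satRing <- enumerateIsomers("C6H12", restrictionSet(cycles = 1),
                              stereo = FALSE, aromaticDedup = TRUE)
  satRing0 <- enumerateIsomers("C6H12", restrictionSet(cycles = 1),
                               stereo = FALSE)
  expect_identical(length(records(satRing)), length(records(satRing0)))
})

test_that("restriction and substructure files round-trip through the readers", {
  rf <- tempfile()
  writeLines(c("# saturated and acyclic", "unsaturations 0", "cycles = 0",
               "max_bond_order 3"), rf)
  rs <- readRestrictions(rf)
  expect_identical(rs@unsaturations, 0L)
  expect_identical(rs@cycles, 0L)
  expect_identical(rs@maxBondOrder, 3L)
  expect_error(readRestrictions({f <- tempfile(); writeLines("bogus 1", f); f}),
               "unknown restriction")

  sf <- tempfile()
  writeLines(c("name etherlink", "smiles COC", "count 1-2", "",
               "name gemdiol", "atoms {OH1} C {OH1}", "stack 1 0 1",
               "count 0"), sf)
  subs <- readSubstructures(sf)
  expect_length(subs, 2L)
  expect_identical(subs[[1]]$name, "etherlink")
  expect_identical(subs[[1]]$count, 1:2)
  expect_identical(subs[[2]]$count, 0L)
  expect_identical(countSubstructure("OC(O)CC", subs[[2]]), 1L)
})
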