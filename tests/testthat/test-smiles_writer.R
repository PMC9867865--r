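test_that("canonical ranking is trivial for methane and invariant for isobutane", {
  ch4 <- molecularGraph(data.frame(symbol = "C", nH = 4L), matrix(0L, 1, 1))
  expect_identical(canonicalRanking(ch4), 1L)
  expect_identical(canonicalSmiles(ch4), "C")

  a <- parseSmiles("C(C)(C)C")   # central carbon first
  b <- parseSmiles("CC(C)C")     # central carbon second
  expect_identical(canonicalSmiles(a), canonicalSmiles(b))

  ethane <- parseSmiles("CC")
  expect_identical(canonicalSmiles(ethane), "CC")
})

test_that("relabeled molecules receive identical canonical strings", {
  set.seed(42)
  checked <- 0L
  for (f in c("C6H10", "C4H8O1")) {
    for (rec in records(enumerateIsomers(f, stereo = FALSE))) {
      g <- rec$isomer@graph
      n <- nrow(atomTable(g))
      for (k in 1:5) {
        p <- sample(n)
        g2 <- molecularGraph(atomTable(g)[p, ], adjacency(g)[p, p])
        expect_identical(canonicalSmiles(g2), rec$smiles)
        checked <- checked + 1L
      }
    }
  }
  expect_gte(checked, 500L)
})

test_that("every emitted string parses back to an isomorphic united graph", {
  # internal round trip: reparse and re-canonicalize
  for (f in c("C6H12", "C4H9N1", "C3H4O2")) {
    for (rec in records(enumerateIsomers(f, stereo = FALSE))) {
      g2 <- parseSmiles(rec$smiles)
      expect_identical(canonicalSmiles(g2), rec$smiles)
      # same formula content
      a1 <- atomTable(rec$isomer)
      a2 <- atomTable(g2)
      expect_identical(sort(paste(a1$symbol, a1$nH)),
                       sort(paste(a2$symbol, a2$nH)))
      expect_identical(sort(adjacency(g2)[upper.tri(adjacency(g2))]),
                       sort(adjacency(rec$isomer)[upper.tri(adjacency(rec$isomer))]))
    }
  }
})

test_that("an independent parser accepts every string and confirms uniqueness", {
  expect_true(rdkitAvailable())
  e1 <- enumerationSmiles(enumerateIsomers("C7H16"))
  e2 <- enumerationSmiles(enumerateIsomers("C5H8Br2"))
  e3 <- enumerationSmiles(enumerateIsomers("C3H8O3"))
  const <- c(e1$constitutional, e2$constitutional, e3$constitutional)
  ster <- c(e1$stereo, e2$stereo, e3$stereo)
  cc <- rdkitCanonical(const)
  cs <- rdkitCanonical(ster)
  expect_false(any(cc == "INVALID"))
  expect_false(any(cs == "INVALID"))
  # no two distinct isomers share a structure; no string repeats
  expect_identical(anyDuplicated(cc), 0L)
  expect_identical(anyDuplicated(cs), 0L)
})

test_that("distinct stereoisomer strings parse to distinguishable parities", {
  expect_true(rdkitAvailable())
  st <- stereoisomers("ClC(Br)CC(Br)Cl", inputOrder = TRUE)
  canon <- rdkitCanonical(st$smiles)
  expect_identical(anyDuplicated(canon), 0L)
  # enantiomer strings must differ yet share the achiral skeleton
  skeleton <- rdkitCanonical(gsub("@+", "", st$smiles))
  expect_identical(length(unique(skeleton)), 1L)
})

test_that("the constrained glycerol formula gives the two published structures", {
  e <- enumerateIsomers("{CH1}1{CH2}2{OH1}3")
  smi <- vapply(records(e), `[[`, "", "smiles")
  expect_length(smi, 2L)
  want <- c("OCC(O)CO", "OCCC(O)O")
  got <- unname(vapply(smi, function(s) canonicalSmiles(parseSmiles(s)), ""))
  expect_setequal(got, unname(vapply(want, function(s)
    canonicalSmiles(parseSmiles(s)), "")))
  # and no stereoisomers for either
  expect_true(all(vapply(records(e), function(r)
    length(r$stereo) == 1L && r$stereo[[1]]$ntet == 0L, logical(1))))
})

test_that("ring closures, bond symbols and branches survive parsing", {
  for (smi in c("C1CCCCC1", "C=1C=CC=CC=1", "C#CC", "CC(C)(C)C",
                "C1CC1CC(=O)O")) {
    g <- parseSmiles(smi)
    s <- canonicalSmiles(g)
    expect_identical(canonicalSmiles(parseSmiles(s)), s)
  }
  expect_error(parseSmiles("C1CC"), "unclosed ring")
  expect_error(parseSmiles("C(C"), "unbalanced")
  expect_error(parseSmiles("CX"), "unexpected")
})
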