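test_that("lexCompare reads the upper triangle row-wise and first difference decides", {
  A <- randomSymmetricMatrix(4)
  expect_identical(lexCompare(A, A), 0L)

  B <- matrix(0L, 3, 3)
  C <- matrix(0L, 3, 3)
  B[1, 2] <- B[2, 1] <- 1L
  C[1, 3] <- C[3, 1] <- 1L
  expect_identical(lexCompare(B, C), 1L)
  expect_identical(lexCompare(C, B), -1L)

  expect_error(lexCompare(B, matrix(0L, 4, 4)), "dimension")

  set.seed(101)
  for (k in 1:50) {
    A <- randomSymmetricMatrix(5)
    B <- randomSymmetricMatrix(5)
    ua <- t(A)[lower.tri(A)]  # upper triangle read row-wise
    ub <- t(B)[lower.tri(B)]
    d <- ua - ub
    nz <- which(d != 0)
    want <- if (!length(nz)) 0L else as.integer(sign(d[nz[1]]))
    expect_identical(lexCompare(A, B), want)
  }
})

test_that("lexCompare is a total order on random triples", {
  set.seed(77)
  for (k in 1:30) {
    A <- randomSymmetricMatrix(4)
    B <- randomSymmetricMatrix(4)
    C <- randomSymmetricMatrix(4)
    expect_identical(lexCompare(A, B), -lexCompare(B, A))
    if (lexCompare(A, B) <= 0 && lexCompare(B, C) <= 0)
      expect_lte(lexCompare(A, C), 0)
  }
})

test_that("applyPermutation is a group action with the inverse property", {
  set.seed(5)
  A <- randomSymmetricMatrix(6)
  n <- 6L
  expect_identical(applyPermutation(A, seq_len(n)), A)
  p <- sample(n)
  inv <- integer(n)
  inv[p] <- seq_len(n)
  expect_identical(applyPermutation(applyPermutation(A, p), inv), A)
  # action property: applying p then q equals applying q[p]
  q <- sample(n)
  expect_identical(applyPermutation(applyPermutation(A, p), q),
                   applyPermutation(A, q[p]))
  # row-sum multiset preserved
  expect_identical(sort(rowSums(applyPermutation(A, p))), sort(rowSums(A)))
  expect_error(applyPermutation(A, c(1L, 1L, 2L, 3L, 4L, 5L)), "permutation")
})

test_that("automorphisms leave the adjacency matrix unchanged", {
  g <- parseSmiles("CCCCC")  # n-pentane: end-to-end flip only
  aut <- graphAutomorphisms(g)
  expect_length(aut, 2L)
  for (p in aut) {
    expect_identical(applyPermutation(adjacency(g), p), adjacency(g))
  }
  # group closed under composition and inverse
  keys <- vapply(aut, paste, "", collapse = ",")
  for (p in aut) for (q in aut) {
    expect_true(paste(q[p], collapse = ",") %in% keys)
    inv <- integer(length(p))
    inv[p] <- seq_along(p)
    expect_true(paste(inv, collapse = ",") %in% keys)
  }
})

test_that("isConnected agrees with a union-find oracle", {
  expect_true(isConnected(matrix(0L, 1, 1)))
  expect_false(isConnected(matrix(0L, 2, 2)))
  blockDiag <- matrix(0L, 4, 4)
  blockDiag[1, 2] <- blockDiag[2, 1] <- 1L
  blockDiag[3, 4] <- blockDiag[4, 3] <- 1L
  expect_false(isConnected(blockDiag))

  unionFind <- function(A) {
    n <- nrow(A)
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (j > i && A[i, j] > 0) parent[find(i)] <- find(j)
    }
    length(unique(vapply(seq_len(n), find, 0L))) == 1L
  }
  set.seed(9)
  for (k in 1:60) {
    n <- sample(2:10, 1)
    A <- matrix(0L, n, n)
    ut <- which(upper.tri(A))
    A[sample(ut, size = rbinom(1, length(ut), 0.25))] <- 1L
    A[lower.tri(A)] <- t(A)[lower.tri(A)]
    expect_identical(isConnected(A), unionFind(A))
  }
})

test_that("unsaturations follows the degree-sum closed form", {
  expect_equal(unsaturations("CH4"), 0)
  expect_equal(unsaturations("C2H4"), 1)
  expect_equal(unsaturations("C5H8Br2"), 1)
  expect_equal(unsaturations(c(C = 2, H = 6, O = 1)), 0)
  expect_error(unsaturations(c(C = 1, H = 3)), "odd")
})

test_that("unsaturations equals rings plus weighted multiple bonds on every isomer", {
  for (f in c("C5H8Br2", "C4H6O1")) {
    u <- unsaturations(f)
    for (rec in records(enumerateIsomers(f, stereo = FALSE))) {
      A <- adjacency(rec$isomer)
      ut <- A[upper.tri(A)]
      expect_identical(cycleCount(A) + sum(ut == 2L) + 2L * sum(ut == 3L), as.integer(u))
    }
  }
})

test_that("cycleCount is the cyclomatic number of the simple skeleton", {
  butane <- parseSmiles("CCCC")
  expect_identical(cycleCount(butane), 0L)
  ring6 <- parseSmiles("C1CCCCC1")
  expect_identical(cycleCount(ring6), 1L)
  # bicyclic 4-atom graph: 5 distinct bonded pairs -> 2 cycles
  A <- matrix(0L, 4, 4)
  for (e in list(c(1, 2), c(2, 3), c(3, 4), c(4, 1), c(1, 3))) {
    A[e[1], e[2]] <- 1L
    A[e[2], e[1]] <- 1L
  }
  expect_identical(cycleCount(A), 2L)
  # a double bond is not a cycle
  expect_identical(cycleCount(parseSmiles("C=C")), 0L)
  expect_error(cycleCount(matrix(0L, 2, 2)), "connected")
})

test_that("molecular graph validity enforces symmetry and completed degrees", {
  at <- data.frame(symbol = c("C", "C"), nH = c(3L, 3L))
  A <- matrix(c(0L, 1L, 1L, 0L), 2, 2)
  g <- molecularGraph(at, A)
  expect_s4_class(g, "MolecularGraph")
  expect_error(molecularGraph(at, matrix(c(0L, 2L, 2L, 0L), 2, 2)),
               "row sums")
  bad <- A
  bad[1, 2] <- 2L
  expect_error(molecularGraph(at, bad), "symmetric")
})
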