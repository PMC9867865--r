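# Shared test helpers: third-party SMILES oracle (RDKit via python),
# exhaustive permutation utilities, and corpus builders.

# batched RDKit canonicalization; returns "INVALID" for unparsable strings
rdkitCanonical <- function(smiles) {
  inf <- tempfile()
  outf <- tempfile()
  writeLines(smiles, inf)
  script <- sprintf('
from rdkit import Chem
out = []
for line in open("%s"):
    s = line.strip()
    m = Chem.MolFromSmiles(s)
    out.append("INVALID" if m is None else Chem.MolToSmiles(m))
open("%s", "w").write("\\n".join(out) + "\\n")
', inf, outf)
  sf <- tempfile(fileext = ".py")
  writeLines(script, sf)
  status <- system2("python", sf, stdout = FALSE, stderr = FALSE)
  if (status != 0L) stop("python/RDKit oracle call failed")
  readLines(outf)
}

rdkitAvailable <- local({
  ok <- NULL
  function() {
    if (is.null(ok)) {
      ok <<- tryCatch(identical(rdkitCanonical("CC"), "CC"),
                      error = function(e) FALSE)
    }
    ok
  }
})

# all type-preserving permutations of a graph's atoms (exhaustive)
allTypePermutations <- function(g) {
  at <- atomTable(g)
  key <- paste(at$symbol, at$nH)
  n <- length(key)
  permsOf <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in permsOf(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  blocks <- split(seq_len(n), key)
  res <- list(integer(0))
  slots <- integer(0)
  for (b in blocks) {
    slots <- c(slots, b)
    res <- unlist(lapply(res, function(cm)
      lapply(permsOf(b), function(p) c(cm, p))), recursive = FALSE)
  }
  lapply(res, function(cm) {
    q <- integer(n)
    q[slots] <- cm
    pi <- integer(n)
    pi[q] <- seq_len(n)
    pi
  })
}

# random symmetric bond-order matrix with zero diagonal
randomSymmetricMatrix <- function(n, maxOrder = 3L) {
  A <- matrix(0L, n, n)
  ut <- which(upper.tri(A))
  A[ut] <- sample(0:maxOrder, length(ut), replace = TRUE)
  A[lower.tri(A)] <- t(A)[lower.tri(A)]
  A
}

# every molecular formula over the given elements with at most maxHeavy
# heavy atoms and a feasible (even-valence, tree-capacity) hydrogen count
formulaSweep <- function(elements, valences, maxHeavy) {
  grids <- lapply(elements, function(e) 0:maxHeavy)
  names(grids) <- elements
  hm <- do.call(expand.grid, grids)
  hm <- hm[rowSums(hm) >= 1 & rowSums(hm) <= maxHeavy, , drop = FALSE]
  out <- character(0)
  for (r in seq_len(nrow(hm))) {
    counts <- as.integer(hm[r, ])
    sumval <- sum(counts * valences)
    nheavy <- sum(counts)
    maxH <- sumval - 2L * (nheavy - 1L)
    if (maxH < 0L) next
    for (h in seq(sumval %% 2L, maxH, by = 2L)) {
      parts <- paste0(elements, ifelse(counts > 0, counts, ""))[counts > 0]
      out <- c(out, paste0(paste(parts, collapse = ""),
                           if (h > 0) paste0("H", h) else ""))
    }
  }
  out
}

# constitutional + stereo SMILES of an enumeration, as two character vectors
enumerationSmiles <- function(e) {
  const <- vapply(records(e), `[[`, "", "smiles")
  ster <- unlist(lapply(records(e), function(r)
    vapply(r$stereo, `[[`, "", "smiles")))
  list(constitutional = const, stereo = ster)
}
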