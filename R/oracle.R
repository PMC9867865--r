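#' @include enumerate.R
NULL

# ---------------------------------------------------------------------------
# Brute-force reference implementations used by the test suite to certify
# correctness on small instances.  They deliberately share no machinery with
# the production path: constitutional counting uses a plain odometer over
# the upper triangle with exhaustive-permutation canonicalization, and the
# stereo count enumerates raw parity assignments deduplicated as orbits of
# the automorphism group, with parity transport derived from sorted-index
# reference neighbor orders.
# ---------------------------------------------------------------------------

#' Brute-force constitutional isomer enumeration (test oracle)
#'
#' Enumerates every upper-triangle filling compatible with the valences,
#' keeps connected graphs, and removes isomorphic duplicates by exhaustive
#' type-preserving permutation canonicalization.  Exact but exponential;
#' refuses partitions above seven united atoms.
#'
#' @param x a formula string, a concrete formula from [expandFormula()], or
#'   a single partition from [distributeHydrogens()]
#' @param maxBondOrder maximum bond order
#' @return list with \code{count} and \code{graphs} (list of
#'   [MolecularGraph-class] representatives)
#' @export
bruteConstitutional <- function(x, maxBondOrder = 3L) {
  parts <- if (is.data.frame(x)) list(x) else {
    if (is.character(x)) {
      cf <- expandFormula(x)
      if (length(cf) != 1L)
        stop("formula does not expand to a single concrete formula")
      x <- cf[[1]]
    }
    distributeHydrogens(x)
  }
  graphs <- list()
  for (part in parts) {
    atoms <- .partitionAtoms(part)
    if (nrow(atoms) > 7L)
      stop("brute-force oracle is capped at 7 united atoms")
    mats <- cpp_brute_constitutional(as.integer(atoms$effValence),
                                     as.integer(atoms$type),
                                     as.integer(maxBondOrder))
    for (M in mats) {
      graphs[[length(graphs) + 1L]] <- molecularGraph(
        atoms[, c("symbol", "nH", "valence", "effValence")], M)
    }
  }
  list(count = length(graphs), graphs = graphs)
}

# all type-preserving permutations of a graph's atoms that fix the adjacency
# matrix, found by filtering the full product of block permutations
.bruteAutomorphisms <- function(graph) {
  A <- graph@adjacency
  n <- nrow(A)
  key <- .typeKey(graph@atoms)
  blocks <- split(seq_len(n), key)
  permsOf <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in permsOf(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  combos <- list(integer(0))
  slots <- integer(0)
  for (b in blocks) {
    slots <- c(slots, b)
    pb <- permsOf(b)
    combos <- unlist(lapply(combos, function(cmb)
      lapply(pb, function(p) c(cmb, p))), recursive = FALSE)
  }
  out <- list()
  for (cmb in combos) {
    p <- integer(n)
    p[slots] <- cmb   # atoms in block slots are mapped within their block
    if (identical(A[p, p], A)) {
      # A[p,p] == A  <=>  relabeling by p^-1 fixes A; store the inverse so
      # the result satisfies applyPermutation(A, pi) == A
      pi <- integer(n)
      pi[p] <- seq_len(n)
      out[[length(out) + 1L]] <- pi
    }
  }
  out
}

#' Brute-force stereoisomer count (test oracle)
#'
#' Assigns all parity combinations to every candidate tetrahedral atom and
#' every eligible double bond, and counts the orbits of the assignments under
#' the automorphism group with parity transport (sign of the induced
#' permutation of sorted-index reference neighbor tuples).  Acyclic molecules
#' of at most seven united atoms.
#'
#' @param graph a [MolecularGraph-class] or SMILES string
#' @return integer stereoisomer count (1 for molecules without stereocenters)
#' @export
bruteStereoCount <- function(graph) {
  if (is.character(graph)) graph <- parseSmiles(graph)
  at <- graph@atoms
  A <- graph@adjacency
  n <- nrow(at)
  if (n > 8L) stop("brute-force stereo oracle is capped at 8 united atoms")
  if (cycleCount(A) > 0L) stop("brute-force stereo oracle requires an acyclic molecule")

  # candidate elements: parity of a center with >= 2 hydrogens is always
  # annihilated by the hydrogen swap, so such centers are dropped up front
  tets <- integer(0)
  for (u in seq_len(n)) {
    if (at$valence[u] != 4L || at$nH[u] >= 2L) next
    nb <- which(A[u, ] > 0)
    if (length(nb) + at$nH[u] == 4L && all(A[u, nb] == 1L))
      tets <- c(tets, u)
  }
  dbs <- list()
  eligibleHalf <- function(u) {
    if (at$valence[u] != 4L || at$nH[u] >= 2L) return(FALSE)
    nb <- which(A[u, ] > 0)
    sum(A[u, nb] == 2L) == 1L && !any(A[u, nb] > 2L) &&
      sum(A[u, nb] == 1L) + at$nH[u] == 2L
  }
  for (u in seq_len(n)) for (v in seq_len(n)) {
    if (v > u && A[u, v] == 2L && eligibleHalf(u) && eligibleHalf(v))
      dbs[[length(dbs) + 1L]] <- c(u, v)
  }
  k <- length(tets) + length(dbs)
  if (k == 0L) return(1L)

  # reference neighbor orders: ascending atom index, implicit hydrogen last
  refTet <- lapply(tets, function(u) {
    nb <- sort(which(A[u, ] > 0))
    c(as.list(nb), if (at$nH[u] == 1L) list("H"))
  })
  refDir <- lapply(dbs, function(d) {
    vapply(d, function(u) {
      s <- sort(which(A[u, ] == 1L))
      if (length(s)) s[1] else NA_integer_   # NA: hydrogen is the reference
    }, 0L)
  })

  aut <- .bruteAutomorphisms(graph)
  transport <- function(vec, p) {
    out <- integer(k)
    for (i in seq_along(tets)) {
      src <- match(which(p == tets[i]), tets)
      img <- lapply(refTet[[src]], function(e)
        if (identical(e, "H")) "H" else p[e])
      sigma <- vapply(seq_along(img), function(m)
        which(vapply(refTet[[i]], identical, logical(1), img[[m]]))[1], 0L)
      out[i] <- if (.permParity(sigma)) 1L - vec[src] else vec[src]
    }
    for (i in seq_along(dbs)) {
      di <- dbs[[i]]
      srcAtoms <- c(which(p == di[1]), which(p == di[2]))
      src <- which(vapply(dbs, function(d) setequal(d, srcAtoms), logical(1)))
      dsrc <- dbs[[src]]
      matched <- 0L
      for (m in 1:2) {
        h <- dsrc[m]
        kImg <- match(p[h], di)
        a <- refDir[[src]][m]
        b <- refDir[[i]][kImg]
        same <- if (is.na(a) || is.na(b)) is.na(a) && is.na(b) else p[a] == b
        if (same) matched <- matched + 1L
      }
      val <- vec[length(tets) + src]
      out[length(tets) + i] <- if (matched == 1L) 1L - val else val
    }
    out
  }
  seen <- character(0)
  for (v in 0:(2^k - 1L)) {
    vec <- as.integer(bitwAnd(bitwShiftR(v, (k - 1L):0L), 1L))
    best <- vec
    for (p in aut) {
      t <- transport(vec, p)
      if (.lexLess(t, best)) best <- t
    }
    seen <- c(seen, paste(best, collapse = ""))
  }
  length(unique(seen))
}
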