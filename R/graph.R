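#' @include AllClasses.R
NULL

#' Construct a molecular graph
#'
#' @param atoms data.frame with at least \code{symbol} and \code{nH};
#'   \code{valence} and \code{effValence} are filled in from the element table
#'   when missing
#' @param adjacency symmetric integer matrix of bond orders
#' @return a validated [MolecularGraph-class]
#' @export
molecularGraph <- function(atoms, adjacency) {
  if (is.null(atoms$valence)) atoms$valence <- .elementValence(atoms$symbol)
  if (is.null(atoms$effValence)) atoms$effValence <- atoms$valence - atoms$nH
  adjacency <- as.matrix(adjacency)
  storage.mode(adjacency) <- "integer"
  new("MolecularGraph", atoms = atoms, adjacency = adjacency)
}

# united-atom type key used for "identical neighbor" tests and permutation
# type preservation
.typeKey <- function(atoms) paste(atoms$symbol, atoms$nH, atoms$valence)

#' Lexicographic comparison of adjacency matrices
#'
#' Reads both matrices row by row over the upper triangle, from top left to
#' bottom right; the first differing entry decides.
#'
#' @param A,B symmetric integer matrices of equal dimension
#' @return -1, 0 or 1 if \code{A} is smaller than, equal to, or larger than
#'   \code{B}
#' @export
lexCompare <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (!all(dim(A) == dim(B))) stop("lexCompare: dimension mismatch")
  storage.mode(A) <- "integer"; storage.mode(B) <- "integer"
  cpp_lex_compare(A, B)
}

#' Apply an atom-index permutation to an adjacency matrix
#'
#' Relabels atoms so that the result satisfies
#' \code{result[p[i], p[j]] == A[i, j]}.
#'
#' @param A adjacency matrix (or [MolecularGraph-class])
#' @param p integer permutation vector
#' @return permuted adjacency matrix
#' @export
applyPermutation <- function(A, p) {
  if (is(A, "MolecularGraph")) A <- A@adjacency
  n <- nrow(A)
  if (length(p) != n || !setequal(p, seq_len(n)))
    stop("applyPermutation: p is not a permutation of the atom indices")
  B <- matrix(0L, n, n)
  B[p, p] <- A
  B
}

#' Connectivity test
#'
#' Depth-first search from the first vertex using a last-in-first-out stack;
#' any nonzero entry counts as an edge.
#'
#' @param A adjacency matrix or [MolecularGraph-class]
#' @return TRUE iff every vertex is reachable from vertex 1
#' @export
isConnected <- function(A) {
  if (is(A, "MolecularGraph")) A <- A@adjacency
  n <- nrow(A)
  if (n <= 1L) return(TRUE)
  seen <- logical(n)
  stack <- 1L
  seen[1L] <- TRUE
  while (length(stack)) {
    u <- stack[length(stack)]
    stack <- stack[-length(stack)]
    nb <- which(A[u, ] > 0 & !seen)
    seen[nb] <- TRUE
    stack <- c(stack, nb)
  }
  all(seen)
}

#' Number of independent cycles
#'
#' Cyclomatic number of the simple-graph skeleton: bonded pairs minus atoms
#' plus one.  Bond multiplicity is ignored, so a double bond is not a cycle.
#'
#' @param graph a [MolecularGraph-class] or adjacency matrix (must be
#'   connected)
#' @return integer cycle count
#' @export
cycleCount <- function(graph) {
  A <- if (is(graph, "MolecularGraph")) graph@adjacency else graph
  if (!isConnected(A)) stop("cycleCount: graph is not connected")
  E <- sum(A[upper.tri(A)] > 0)
  E - nrow(A) + 1L
}

# tally of bonded pairs by bond order (1..4)
.bondTally <- function(A) {
  ut <- A[upper.tri(A)]
  c(total = sum(ut > 0), vapply(1:4, function(k) sum(ut == k), 0L))
}

# edges lying on a cycle: removal keeps the graph connected
.ringEdges <- function(A) {
  n <- nrow(A)
  out <- matrix(FALSE, n, n)
  if (cycleCount(A) == 0L) return(out)
  idx <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1]; j <- idx[k, 2]
    B <- A
    B[i, j] <- 0L; B[j, i] <- 0L
    if (isConnected(B)) {
      out[i, j] <- TRUE
      out[j, i] <- TRUE
    }
  }
  out
}

# all-pairs shortest-path distances over the simple skeleton (BFS per vertex)
.graphDistances <- function(A) {
  n <- nrow(A)
  D <- matrix(NA_integer_, n, n)
  for (s in seq_len(n)) {
    d <- rep(NA_integer_, n)
    d[s] <- 0L
    frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (u in frontier) {
        nb <- which(A[u, ] > 0 & is.na(d))
        d[nb] <- d[u] + 1L
        nxt <- c(nxt, nb)
      }
      frontier <- nxt
    }
    D[s, ] <- d
  }
  D
}

#' Automorphism group of a molecular graph
#'
#' All type-preserving atom permutations leaving the adjacency matrix
#' unchanged (identity included).  For graphs in canonical labeling this is a
#' by-product of the canonicity test; this function computes it for an
#' arbitrary labeling.
#'
#' @param graph a [MolecularGraph-class]
#' @return list of integer permutation vectors
#' @export
graphAutomorphisms <- function(graph) {
  at <- graph@atoms
  n <- nrow(at)
  key <- .typeKey(at)
  ord <- order(key)  # contiguous type blocks, any fixed order
  A <- graph@adjacency[ord, ord, drop = FALSE]
  type <- as.integer(factor(key[ord], levels = unique(key[ord])))
  perms <- cpp_automorphisms(A, type)
  # conjugate back into the original labeling: if pi_B is an automorphism of
  # the reordered matrix, ord o pi_B o ord^-1 is one of the original
  inv <- integer(n)
  inv[ord] <- seq_len(n)
  lapply(perms, function(p) ord[p[inv]])
}
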