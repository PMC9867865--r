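#' @include graph.R
NULL

.asCountSet <- function(x) {
  if (is.null(x)) return(integer(0))
  if (is.character(x)) return(.parseCountSet(gsub("\\[|\\]", "", x)))
  sort(unique(as.integer(x)))
}

#' Build a restriction set
#'
#' Each restriction is a set of admissible values, given as an integer
#' vector or a count-set string (\code{"2"}, \code{"0,2"}, \code{"0-3"});
#' \code{NULL} leaves a property unrestricted.  Unsaturation restrictions are
#' applied to the molecular formula before the enumeration starts; all other
#' properties are checked on each generated isomer.
#'
#' @param unsaturations admissible unsaturation counts (double bonds and
#'   cycles count one, triple bonds two)
#' @param totalBonds admissible numbers of bonds (each bonded pair counted
#'   once, irrespective of order)
#' @param singleBonds,doubleBonds,tripleBonds,quadrupleBonds admissible bond
#'   tallies by order
#' @param cycles admissible cycle counts (cyclomatic number)
#' @param maxBondOrder maximum bond order generated (1..4)
#' @param substructures list of [substructure()] definitions, each with its
#'   own admissible occurrence set
#' @return a [RestrictionSet-class]
#' @examples
#' restrictionSet(unsaturations = 0)          # saturated molecules only
#' restrictionSet(cycles = "0", doubleBonds = "1-2")
#' @export
restrictionSet <- function(unsaturations = NULL, totalBonds = NULL,
                           singleBonds = NULL, doubleBonds = NULL,
                           tripleBonds = NULL, quadrupleBonds = NULL,
                           cycles = NULL, maxBondOrder = 3L,
                           substructures = list()) {
  new("RestrictionSet",
      unsaturations = .asCountSet(unsaturations),
      totalBonds = .asCountSet(totalBonds),
      singleBonds = .asCountSet(singleBonds),
      doubleBonds = .asCountSet(doubleBonds),
      tripleBonds = .asCountSet(tripleBonds),
      quadrupleBonds = .asCountSet(quadrupleBonds),
      cycles = .asCountSet(cycles),
      maxBondOrder = as.integer(maxBondOrder),
      substructures = substructures)
}

#' Check an isomer against a restriction set
#'
#' @param isomer a [MolecularGraph-class] or [CanonicalIsomer-class]
#' @param restrictions a [RestrictionSet-class]
#' @return TRUE iff every specified restriction contains the isomer's value
#' @export
passesFilters <- function(isomer, restrictions) {
  g <- if (is(isomer, "CanonicalIsomer")) isomer@graph else isomer
  A <- g@adjacency
  tally <- .bondTally(A)
  cyc <- cycleCount(A)
  unsat <- cyc + tally[3] + 2L * tally[4] + 3L * tally[5]
  inSet <- function(set, value) length(set) == 0L || value %in% set
  ok <- inSet(restrictions@unsaturations, unsat) &&
    inSet(restrictions@totalBonds, tally[1]) &&
    inSet(restrictions@singleBonds, tally[2]) &&
    inSet(restrictions@doubleBonds, tally[3]) &&
    inSet(restrictions@tripleBonds, tally[4]) &&
    inSet(restrictions@quadrupleBonds, tally[5]) &&
    inSet(restrictions@cycles, cyc) &&
    all(A <= restrictions@maxBondOrder)
  if (!ok) return(FALSE)
  for (sub in restrictions@substructures) {
    if (is.null(sub$count) || !length(sub$count)) next
    if (!countSubstructure(g, sub) %in% sub$count) return(FALSE)
  }
  TRUE
}

# ---- substructures ---------------------------------------------------------

#' Define a substructure pattern
#'
#' A substructure is a named list of atoms plus an adjacency-matrix stack
#' (the upper triangle written row-wise).  Atoms are element symbols,
#' united-atom specs with a pinned hydrogen count (\code{"\{CH2\}"}) or the
#' wildcard \code{"*"}.  Alternatively, a SMILES string can be given: its
#' atoms are unconstrained in hydrogen count unless written as bracket atoms.
#' Bond orders must match exactly.
#'
#' @param smiles pattern as a SMILES string (overrides \code{atoms}/\code{stack})
#' @param atoms character vector of atom tokens
#' @param stack integer vector of length \code{n(n-1)/2}
#' @param name pattern name
#' @param count admissible occurrence set (integer vector or count-set string)
#' @return a substructure definition (list)
#' @examples
#' substructure(smiles = "CC")
#' substructure(atoms = c("C", "{CH2}", "O"), stack = c(1, 0, 1))
#' @export
substructure <- function(smiles = NULL, atoms = NULL, stack = NULL,
                         name = NULL, count = NULL) {
  if (!is.null(smiles)) {
    g <- parseSmiles(smiles)
    sym <- g@atoms$symbol
    nH <- attr(g, "explicitH")
    A <- g@adjacency
    if (is.null(name)) name <- smiles
  } else {
    if (is.null(atoms) || !length(atoms)) stop("empty substructure pattern")
    sym <- character(length(atoms))
    nH <- rep(NA_integer_, length(atoms))
    for (i in seq_along(atoms)) {
      tok <- atoms[i]
      if (tok == "*") {
        sym[i] <- NA_character_
      } else if (grepl("^\\{[A-Z][a-z]?H[0-9]+\\}$", tok)) {
        m <- regmatches(tok, regexec("^\\{([A-Z][a-z]?)H([0-9]+)\\}$", tok))[[1]]
        sym[i] <- m[2]
        nH[i] <- as.integer(m[3])
      } else if (tok %in% .ELEMENTS$symbol) {
        sym[i] <- tok
      } else {
        stop("malformed substructure atom token '", tok, "'")
      }
    }
    n <- length(atoms)
    if (length(stack) != n * (n - 1L) / 2L)
      stop("adjacency stack must have length n(n-1)/2")
    A <- matrix(0L, n, n)
    k <- 1L
    for (i in seq_len(n)) for (j in seq_len(n)) if (j > i) {
      A[i, j] <- as.integer(stack[k]); A[j, i] <- A[i, j]; k <- k + 1L
    }
    if (is.null(name)) name <- paste(atoms, collapse = "")
  }
  list(name = name, symbol = sym, nH = as.integer(nH), A = A,
       count = .asCountSet(count))
}

#' Count substructure occurrences (Ullmann search)
#'
#' Finds all embeddings of the pattern by Ullmann backtracking with
#' candidate refinement, collapses automorphic images of the same embedding
#' (a match is an atom set plus a bond set), and counts matches under the
#' convention that accepted matches may overlap in at most one atom (greedy
#' in canonical match order).
#'
#' @param graph a [MolecularGraph-class] (or SMILES string)
#' @param sub a [substructure()] definition (or SMILES string)
#' @return integer occurrence count
#' @examples
#' countSubstructure("CCCC", "CC")   # 3
#' countSubstructure("CCCC", "CCC")  # 1
#' @export
countSubstructure <- function(graph, sub) {
  if (is.character(graph)) graph <- parseSmiles(graph)
  if (is.character(sub)) sub <- substructure(smiles = sub)
  P <- sub$A
  np <- nrow(P)
  if (np == 0L) stop("empty substructure pattern")
  A <- graph@adjacency
  ng <- nrow(A)
  at <- graph@atoms
  if (np > ng) return(0L)
  # initial candidates
  M <- matrix(TRUE, np, ng)
  for (p in seq_len(np)) {
    if (!is.na(sub$symbol[p])) M[p, ] <- M[p, ] & at$symbol == sub$symbol[p]
    if (!is.na(sub$nH[p])) M[p, ] <- M[p, ] & at$nH == sub$nH[p]
    degP <- sum(P[p, ] > 0)
    M[p, ] <- M[p, ] & vapply(seq_len(ng), function(g)
      sum(A[g, ] > 0) >= degP, logical(1))
  }
  # Ullmann refinement: a candidate survives if every pattern neighbor can
  # be matched by some graph neighbor with the exact bond order
  repeat {
    changed <- FALSE
    for (p in seq_len(np)) for (g in which(M[p, ])) {
      for (q in which(P[p, ] > 0)) {
        hs <- which(A[g, ] == P[p, q])
        if (!any(M[q, hs])) {
          M[p, g] <- FALSE
          changed <- TRUE
          break
        }
      }
    }
    if (!changed) break
  }
  if (any(rowSums(M) == 0L)) return(0L)
  # backtracking over injective assignments
  matches <- new.env(parent = emptyenv())
  assignment <- integer(np)
  used <- logical(ng)
  rec <- function(p) {
    if (p > np) {
      atomsM <- sort(assignment)
      bondsM <- character(0)
      for (i in seq_len(np)) for (j in seq_len(np)) if (j > i && P[i, j] > 0) {
        e <- sort(c(assignment[i], assignment[j]))
        bondsM <- c(bondsM, paste(e[1], e[2], sep = "-"))
      }
      key <- paste(paste(atomsM, collapse = ","), "|",
                   paste(sort(bondsM), collapse = ","))
      base::assign(key, list(atoms = atomsM, key = key), envir = matches)
      return(invisible(NULL))
    }
    for (g in which(M[p, ] & !used)) {
      ok <- TRUE
      for (q in seq_len(p - 1L)) {
        if (P[q, p] > 0 && A[assignment[q], g] != P[q, p]) { ok <- FALSE; break }
      }
      if (!ok) next
      assignment[p] <<- g
      used[g] <<- TRUE
      rec(p + 1L)
      used[g] <<- FALSE
    }
  }
  rec(1L)
  ms <- mget(ls(matches), envir = matches)
  if (!length(ms)) return(0L)
  # canonical match order: sorted matched-index tuples
  ord <- order(vapply(ms, function(m)
    paste(formatC(m$atoms, width = 4, flag = "0"), collapse = ","), ""))
  accepted <- list()
  for (m in ms[ord]) {
    if (all(vapply(accepted, function(a)
      length(intersect(a, m$atoms)) <= 1L, logical(1)))) {
      accepted[[length(accepted) + 1L]] <- m$atoms
    }
  }
  length(accepted)
}

# ---- aromatic (six-ring) deduplication ------------------------------------

# all six-membered rings with strictly alternating single/double bonds
.alternating6Rings <- function(A) {
  n <- nrow(A)
  rings <- list()
  seen <- character(0)
  path <- integer(6)
  dfs <- function(depth) {
    u <- path[depth]
    for (v in which(A[u, ] > 0)) {
      if (depth == 6L) {
        if (v == path[1]) {
          key <- paste(sort(path), collapse = ",")
          if (!key %in% seen) {
            orders <- vapply(1:6, function(k)
              A[path[k], path[k %% 6L + 1L]], 0L)
            if (all(orders %in% c(1L, 2L)) &&
                all(abs(diff(c(orders, orders[1]))) == 1L)) {
              seen <<- c(seen, key)
              rings[[length(rings) + 1L]] <<- path
            }
          }
        }
        next
      }
      if (v %in% path[seq_len(depth)]) next
      if (v < path[1]) next  # canonical start: smallest atom first
      path[depth + 1L] <<- v
      dfs(depth + 1L)
    }
  }
  for (s in seq_len(n)) {
    path[1] <- s
    dfs(1L)
  }
  rings
}

.flipRing <- function(A, ring) {
  for (k in 1:6) {
    i <- ring[k]; j <- ring[k %% 6L + 1L]
    A[i, j] <- 3L - A[i, j]
    A[j, i] <- A[i, j]
  }
  A
}

# keep one representative per class of isomers differing only by the
# rotation of alternating single/double bonds around six-rings: a record
# survives iff its canonical SMILES is the smallest among all valid ring
# flips of its matrix
.kekuleRepresentative <- function(graph, smiles) {
  A <- graph@adjacency
  rings <- .alternating6Rings(A)
  if (!length(rings)) return(TRUE)
  eff <- graph@atoms$effValence
  best <- smiles
  nr <- length(rings)
  for (mask in 1:(2^nr - 1L)) {
    B <- A
    for (r in seq_len(nr)) {
      if (bitwAnd(bitwShiftR(mask, r - 1L), 1L)) B <- .flipRing(B, rings[[r]])
    }
    if (!all(B >= 0 & B <= 4) || !all(rowSums(B) == eff)) next
    g2 <- molecularGraph(graph@atoms, B)
    s2 <- canonicalSmiles(g2)
    if (s2 < best) return(FALSE)
  }
  TRUE
}
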