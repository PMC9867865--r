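#' @include graph.R
NULL

# ---- canonical atom ranking ------------------------------------------------

# refinement step: new class ids from (old id, sorted multiset of
# (bond order, neighbor id)); returns dense integer ids
.refineIds <- function(ids, A) {
  n <- length(ids)
  repeat {
    keys <- vapply(seq_len(n), function(i) {
      nb <- which(A[i, ] > 0)
      piece <- sort(paste0(A[i, nb], ":", formatC(ids[nb], width = 3, flag = "0")))
      paste0(formatC(ids[i], width = 3, flag = "0"), "|",
             paste(piece, collapse = ","))
    }, "")
    new <- as.integer(factor(keys, levels = sort(unique(keys))))
    if (identical(new, ids)) return(ids)
    if (length(unique(new)) == length(unique(ids)) &&
        all(tapply(new, ids, function(x) length(unique(x))) == 1L))
      return(new)
    ids <- new
  }
}

.initialIds <- function(graph) {
  at <- graph@atoms
  A <- graph@adjacency
  keys <- vapply(seq_len(nrow(at)), function(i) {
    nb <- which(A[i, ] > 0)
    paste(at$symbol[i], formatC(at$effValence[i], width = 2),
          formatC(length(nb), width = 2), formatC(at$nH[i], width = 2),
          paste(sort(A[i, nb], decreasing = TRUE), collapse = ""))
  }, "")
  as.integer(factor(keys, levels = sort(unique(keys))))
}

# orbit representative per atom under the automorphism group
.orbitReps <- function(aut, n) {
  rep <- seq_len(n)
  for (p in aut) rep <- pmin(rep, p[seq_len(n)])
  # transitive closure: iterate to a fixed point
  repeat {
    nxt <- rep
    for (p in aut) nxt <- pmin(nxt, rep[p])
    if (identical(nxt, rep)) break
    rep <- nxt
  }
  rep
}

#' Canonical atom ranking for SMILES output
#'
#' Iterative-refinement ranking from element/valence/degree/hydrogen/bond
#' invariants, refined by sorted neighbor ranks until stable.  Remaining ties
#' are broken by individualizing one atom of the first tied class and
#' re-refining; when the tied class spans several automorphism orbits, every
#' orbit is tried and the ranking giving the lexicographically smallest
#' SMILES string wins, so the result is independent of the input atom
#' labeling.
#'
#' @param graph a [MolecularGraph-class]
#' @param aut optional automorphism group (list of permutations); computed
#'   when missing
#' @return integer vector of ranks (1 = first atom visited)
#' @export
canonicalRanking <- function(graph, aut = NULL) {
  n <- nrow(graph@atoms)
  if (n == 1L) return(1L)
  if (is.null(aut)) aut <- graphAutomorphisms(graph)
  orb <- .orbitReps(aut, n)
  A <- graph@adjacency
  candidates <- list()
  resolve <- function(ids) {
    ids <- .refineIds(ids, A)
    if (length(unique(ids)) == n) {
      candidates[[length(candidates) + 1L]] <<- ids
      return(invisible(NULL))
    }
    cls <- min(ids[duplicated(ids) | duplicated(ids, fromLast = TRUE)])
    members <- which(ids == cls)
    reps <- members[!duplicated(orb[members])]
    for (r in reps) {
      keys <- ids * 2L
      keys[r] <- keys[r] - 1L
      resolve(as.integer(factor(keys, levels = sort(unique(keys)))))
    }
  }
  resolve(.initialIds(graph))
  if (length(candidates) == 1L) return(candidates[[1]])
  strs <- vapply(candidates, function(ids)
    .assembleSmiles(graph, .smilesPlan(graph, ids)), "")
  candidates[[order(strs)[1L]]]
}

# ---- traversal plan --------------------------------------------------------

# depth-first traversal in rank order; records parents, ordered children,
# ring-closure bonds with digits, and the per-atom SMILES neighbor encounter
# order used by the stereo machinery
.smilesPlan <- function(graph, ranks) {
  A <- graph@adjacency
  n <- nrow(A)
  parent <- rep(NA_integer_, n)
  children <- vector("list", n)
  closures <- vector("list", n)  # each entry: list(digit, partner, order)
  visitIdx <- rep(NA_integer_, n)
  visited <- logical(n)
  used <- matrix(FALSE, n, n)
  ctr <- 0L
  digit <- 0L
  dfs <- function(u) {
    visited[u] <<- TRUE
    ctr <<- ctr + 1L
    visitIdx[u] <<- ctr
    nbs <- which(A[u, ] > 0)
    nbs <- nbs[order(ranks[nbs])]
    for (v in nbs) {
      if (!is.na(parent[u]) && v == parent[u]) next
      if (used[u, v]) next
      used[u, v] <<- TRUE
      used[v, u] <<- TRUE
      if (visited[v]) {
        digit <<- digit + 1L
        closures[[u]] <<- c(closures[[u]], list(list(digit = digit,
          partner = v, order = A[u, v])))
        closures[[v]] <<- c(closures[[v]], list(list(digit = digit,
          partner = u, order = A[u, v])))
      } else {
        parent[v] <<- u
        children[[u]] <<- c(children[[u]], v)
        dfs(v)
      }
    }
  }
  root <- which.min(ranks)
  dfs(root)
  list(root = root, parent = parent, children = children,
       closures = closures, visitIdx = visitIdx, ranks = ranks)
}

# encounter order of the substituents of atom u in the SMILES string:
# preceding atom, implicit hydrogen, ring closures (digit order), children.
# "H" marks the implicit hydrogen slot; for the first atom of the string the
# hydrogen is the neighbor visited before the atom.
.encounterOrder <- function(graph, plan, u) {
  out <- list()
  if (!is.na(plan$parent[u])) out <- c(out, plan$parent[u])
  if (graph@atoms$nH[u] > 0L) out <- c(out, rep(list("H"), graph@atoms$nH[u]))
  for (cl in plan$closures[[u]]) out <- c(out, cl$partner)
  out <- c(out, as.list(plan$children[[u]]))
  out
}

# explicit singly-bonded neighbors of u in encounter order (implicit H last);
# used for cis/trans directionality
.ctSingles <- function(graph, plan, u) {
  A <- graph@adjacency
  out <- integer(0)
  p <- plan$parent[u]
  if (!is.na(p) && A[u, p] == 1L) out <- c(out, p)
  for (cl in plan$closures[[u]]) if (cl$order == 1L) out <- c(out, cl$partner)
  for (v in plan$children[[u]]) if (A[u, v] == 1L) out <- c(out, v)
  out
}

# ---- string assembly -------------------------------------------------------

.BOND_TOKEN <- c("", "", "=", "#", "$")  # index = order + 1

.digitToken <- function(d) if (d > 9) sprintf("%%%02d", d) else as.character(d)

# tags: character vector per atom ("@", "@@", or NA); slash: character matrix
# with slash[p, c] the symbol written for the tree bond p -> c ("" if none)
.assembleSmiles <- function(graph, plan, tags = NULL, slash = NULL) {
  at <- graph@atoms
  A <- graph@adjacency
  n <- nrow(at)
  if (is.null(tags)) tags <- rep(NA_character_, n)
  atomToken <- function(u) {
    if (is.na(tags[u])) return(at$symbol[u])
    h <- if (at$nH[u] == 0L) "" else if (at$nH[u] == 1L) "H" else
      paste0("H", at$nH[u])
    paste0("[", at$symbol[u], tags[u], h, "]")
  }
  bondToken <- function(p, c) {
    if (!is.null(slash) && nzchar(slash[p, c])) return(slash[p, c])
    .BOND_TOKEN[A[p, c] + 1L]
  }
  emit <- function(u) {
    s <- atomToken(u)
    for (cl in plan$closures[[u]]) {
      s <- paste0(s, .BOND_TOKEN[cl$order + 1L], .digitToken(cl$digit))
    }
    kids <- plan$children[[u]]
    if (length(kids)) {
      for (v in head(kids, -1L))
        s <- paste0(s, "(", bondToken(u, v), emit(v), ")")
      v <- tail(kids, 1L)
      s <- paste0(s, bondToken(u, v), emit(v))
    }
    s
  }
  emit(plan$root)
}

#' Canonical SMILES of a molecular graph
#'
#' Deterministic, label-independent SMILES string (constitution only; see
#' [stereoisomers()] for stereo-annotated strings).  Hydrogens are implicit.
#'
#' @param graph a [MolecularGraph-class]
#' @param aut optional automorphism group of the graph
#' @return a SMILES string
#' @examples
#' canonicalSmiles(parseSmiles("C(C)(C)C"))  # isobutane
#' @export
canonicalSmiles <- function(graph, aut = NULL) {
  ranks <- canonicalRanking(graph, aut)
  .assembleSmiles(graph, .smilesPlan(graph, ranks))
}

# ---- minimal SMILES parser (internal surface + fixtures) -------------------

#' Parse a SMILES string into a molecular graph
#'
#' Minimal parser for the Daylight dialect subset this package emits:
#' organic-subset atoms, bracket atoms with hydrogen counts, bond orders
#' \code{- = # $}, directional bonds (parsed, treated as single), branches
#' and ring closures (\code{\%nn} included).  Stereo annotations are dropped;
#' the result describes the constitution with hydrogens made implicit.  The
#' traversal structure of the string is attached as attribute \code{"plan"},
#' so stereo enumeration can reuse the exact atom order of the input string.
#'
#' @param text a SMILES string
#' @return a [MolecularGraph-class] (atom order = appearance order in the
#'   string)
#' @examples
#' parseSmiles("ClC(Br)CC(Br)Cl")
#' @export
parseSmiles <- function(text) {
  s <- gsub("[[:space:]]", "", text)
  n <- nchar(s)
  if (!n) stop("empty SMILES", call. = FALSE)
  symbol <- character(0)
  explicitH <- integer(0)    # NA = implicit (organic subset)
  bonds <- list()            # list(i, j, order)
  parent <- integer(0)
  children <- list()
  closures <- list()
  ring <- list()             # digit -> list(atom, order)
  prev <- NA_integer_
  stack <- integer(0)
  pend <- NA_integer_
  i <- 1L
  err <- function(msg) stop("SMILES parse error at position ", i, ": ", msg,
                            call. = FALSE)
  addAtom <- function(sym, hcount) {
    symbol[length(symbol) + 1L] <<- sym
    explicitH[length(explicitH) + 1L] <<- hcount
    id <- length(symbol)
    children[[id]] <<- integer(0)
    closures[[id]] <<- list()
    parent[id] <<- NA_integer_
    if (!is.na(prev)) {
      ord <- if (is.na(pend)) 1L else pend
      bonds[[length(bonds) + 1L]] <<- list(i = prev, j = id, order = ord)
      parent[id] <<- prev
      children[[prev]] <<- c(children[[prev]], id)
    }
    pend <<- NA_integer_
    prev <<- id
  }
  closeRing <- function(d) {
    ord <- if (is.na(pend)) NA_integer_ else pend
    pend <<- NA_integer_
    key <- as.character(d)
    if (is.null(ring[[key]])) {
      ring[[key]] <<- list(atom = prev, order = ord)
    } else {
      op <- ring[[key]]
      o <- if (!is.na(ord)) ord else if (!is.na(op$order)) op$order else 1L
      if (!is.na(ord) && !is.na(op$order) && ord != op$order)
        err("conflicting ring-bond orders")
      bonds[[length(bonds) + 1L]] <<- list(i = op$atom, j = prev, order = o)
      closures[[prev]] <<- c(closures[[prev]], list(list(partner = op$atom,
        order = o)))
      closures[[op$atom]] <<- c(closures[[op$atom]], list(list(partner = prev,
        order = o)))
      ring[[key]] <<- NULL
    }
  }
  while (i <= n) {
    ch <- substr(s, i, i)
    if (ch == "(") {
      if (is.na(prev)) err("branch before any atom")
      stack <- c(stack, prev)
      i <- i + 1L
    } else if (ch == ")") {
      if (!length(stack)) err("unbalanced ')'")
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch %in% c("-", "/", "\\")) {
      pend <- 1L; i <- i + 1L
    } else if (ch == "=") {
      pend <- 2L; i <- i + 1L
    } else if (ch == "#") {
      pend <- 3L; i <- i + 1L
    } else if (ch == "$") {
      pend <- 4L; i <- i + 1L
    } else if (grepl("^[0-9]$", ch)) {
      closeRing(as.integer(ch)); i <- i + 1L
    } else if (ch == "%") {
      d <- substr(s, i + 1L, i + 2L)
      if (!grepl("^[0-9]{2}$", d)) err("malformed %nn ring closure")
      closeRing(as.integer(d)); i <- i + 3L
    } else if (ch == "[") {
      j <- regexpr("]", substr(s, i, n), fixed = TRUE)
      if (j < 0) err("unterminated '['")
      inner <- substr(s, i + 1L, i + j - 2L)
      m <- regmatches(inner,
        regexec("^([A-Z][a-z]?)(@@|@)?(H([0-9]?))?$", inner))[[1]]
      if (!length(m) || !m[2] %in% .ELEMENTS$symbol)
        err(paste0("unsupported bracket atom '[", inner, "]'"))
      hc <- if (m[4] == "") 0L else if (m[5] == "") 1L else as.integer(m[5])
      addAtom(m[2], hc)
      i <- i + j
    } else {
      sym <- NA_character_
      for (len in c(2L, 1L)) {
        cand <- substr(s, i, i + len - 1L)
        if (cand %in% .ELEMENTS$symbol) { sym <- cand; break }
      }
      if (is.na(sym)) err(paste0("unexpected character '", ch, "'"))
      addAtom(sym, NA_integer_)
      i <- i + nchar(sym)
    }
  }
  if (length(ring)) err("unclosed ring bond")
  if (length(stack)) err("unbalanced '('")
  nAtoms <- length(symbol)
  A <- matrix(0L, nAtoms, nAtoms)
  for (b in bonds) {
    A[b$i, b$j] <- A[b$i, b$j] + b$order
    A[b$j, b$i] <- A[b$i, b$j]
  }
  val <- .elementValence(symbol)
  nH <- ifelse(is.na(explicitH), val - rowSums(A), explicitH)
  if (any(nH < 0)) stop("valence exceeded in SMILES '", text, "'")
  g <- molecularGraph(
    data.frame(symbol = symbol, nH = as.integer(nH), stringsAsFactors = FALSE), A)
  visitIdx <- seq_len(nAtoms)
  attr(g, "plan") <- list(root = 1L, parent = parent, children = children,
    closures = closures, visitIdx = visitIdx, ranks = visitIdx)
  attr(g, "explicitH") <- explicitH  # NA = hydrogen count was implicit
  g
}
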