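#' @include smiles.R
NULL

# ---------------------------------------------------------------------------
# Stereocenter detection.
#
# Tetrahedral candidates are valence-4 atoms with four singly-bonded
# substituents (implicit hydrogens included).  Cis/trans candidates are pairs
# of valence-4 atoms joined by a double bond, each with two singly-bonded
# substituents, outside any cycle.  A candidate whose equal-type substituents
# can be swapped by an automorphism that fixes the candidate is not a true
# stereocenter but may be a para stereocenter: its substituents are
# constitutionally identical yet may become stereochemically distinct once
# the other centers are configured.
# ---------------------------------------------------------------------------

.detectCenters <- function(graph, aut, plan) {
  at <- graph@atoms
  A <- graph@adjacency
  n <- nrow(at)
  key <- .typeKey(at)
  ringE <- .ringEdges(A)
  inRing <- if (n) apply(ringE, 1L, any) else logical(0)

  fixesAndMoves <- function(u, nb) {
    for (p in aut) {
      if (p[u] == u && any(p[nb] != nb)) return(TRUE)
    }
    FALSE
  }
  fixesAndSwapsPair <- function(u, s1, s2) {
    for (p in aut) {
      if (p[u] == u && p[s1] == s2) return(TRUE)
    }
    FALSE
  }

  trueTet <- list(); paraTet <- list()
  for (u in seq_len(n)) {
    if (at$valence[u] != 4L) next
    nb <- which(A[u, ] > 0)
    if (length(nb) + at$nH[u] != 4L) next
    if (any(A[u, nb] != 1L)) next
    if (at$nH[u] >= 2L) next
    k <- key[nb]
    dup <- unique(k[duplicated(k)])
    center <- list(kind = "tet", atom = u,
                   nb = .encounterOrder(graph, plan, u),
                   pos = plan$visitIdx[u])
    if (!length(dup)) {
      trueTet[[length(trueTet) + 1L]] <- center
    } else if (any(vapply(dup, function(d)
        at$valence[nb[match(d, k)]] == 1L, logical(1)))) {
      # at least two identical valence-1 substituents: never a stereocenter
      next
    } else if (fixesAndMoves(u, nb)) {
      paraTet[[length(paraTet) + 1L]] <- center
    } else {
      trueTet[[length(trueTet) + 1L]] <- center
    }
  }

  # half-center status: 0 none, 1 potential (true), 2 para candidate
  half <- integer(n)
  for (u in seq_len(n)) {
    if (at$valence[u] != 4L) next
    nb <- which(A[u, ] > 0)
    if (sum(A[u, nb] == 2L) != 1L || any(A[u, nb] > 2L)) next
    singles <- nb[A[u, nb] == 1L]
    if (length(singles) + at$nH[u] != 2L) next
    if (inRing[u]) next
    if (at$nH[u] == 2L) next
    if (length(singles) == 2L && key[singles[1]] == key[singles[2]]) {
      if (at$valence[singles[1]] == 1L) next   # two identical Cl/Br/...
      half[u] <- if (fixesAndSwapsPair(u, singles[1], singles[2])) 2L else 1L
    } else {
      half[u] <- 1L   # substituents differ (implicit H counts as one)
    }
  }
  trueCt <- list(); paraCt <- list()
  done <- logical(n)
  for (u in seq_len(n)) {
    if (!half[u] || done[u]) next
    v <- which(A[u, ] == 2L)
    if (!half[v]) next
    done[u] <- TRUE; done[v] <- TRUE
    hs <- c(u, v)[order(plan$visitIdx[c(u, v)])]
    dirs <- vapply(hs, function(h) .ctSingles(graph, plan, h)[1], 0L)
    center <- list(kind = "ct", halves = hs, dir = dirs,
                   singles = lapply(hs, function(h) .ctSingles(graph, plan, h)),
                   pos = plan$visitIdx[hs[1]])
    if (half[u] == 1L && half[v] == 1L) {
      trueCt[[length(trueCt) + 1L]] <- center
    } else if (half[u] == 2L && half[v] == 2L) {
      paraCt[[length(paraCt) + 1L]] <- center
    }
    # mixed true/para pairs are not treated as stereocenters
  }

  trueCenters <- c(trueTet, trueCt)
  trueCenters <- trueCenters[order(vapply(trueCenters, `[[`, 0L, "pos"))]

  # retain a para candidate only if it lies in a cycle or at the midpoint of
  # the shortest path between two automorphism-swapped true stereocenters
  D <- .graphDistances(A)
  centerDist <- function(x, center) {
    if (center$kind == "tet") D[x, center$atom] else min(D[x, center$halves])
  }
  swappedPairs <- list()
  if (length(trueCenters) >= 2L) {
    for (p in aut) {
      for (i in seq_along(trueCenters)) {
        for (j in seq_along(trueCenters)) {
          if (i >= j) next
          ci <- trueCenters[[i]]; cj <- trueCenters[[j]]
          hit <- if (ci$kind == "tet" && cj$kind == "tet") {
            p[ci$atom] == cj$atom
          } else if (ci$kind == "ct" && cj$kind == "ct") {
            setequal(p[ci$halves], cj$halves)
          } else FALSE
          if (hit) swappedPairs[[length(swappedPairs) + 1L]] <- c(i, j)
        }
      }
    }
    swappedPairs <- unique(swappedPairs)
  }
  midpointOf <- function(x) {
    for (pr in swappedPairs) {
      ci <- trueCenters[[pr[1]]]; cj <- trueCenters[[pr[2]]]
      ds <- centerDist(x, ci); dt <- centerDist(x, cj)
      dst <- if (ci$kind == "tet") centerDist(ci$atom, cj) else
        min(vapply(ci$halves, function(h) centerDist(h, cj), 0L))
      if (ds == dt && ds + dt == dst) return(TRUE)
    }
    FALSE
  }
  keepPara <- function(center) {
    xs <- if (center$kind == "tet") center$atom else center$halves
    any(inRing[xs]) || any(vapply(xs, midpointOf, logical(1)))
  }
  paraCenters <- c(Filter(keepPara, paraTet), Filter(keepPara, paraCt))
  paraCenters <- paraCenters[order(vapply(paraCenters, `[[`, 0L, "pos"))]

  new("StereoModel", trueCenters = trueCenters, paraCenters = paraCenters,
      plan = plan)
}

# ---------------------------------------------------------------------------
# Parity transport.  For each automorphism, precompute per stereocenter: the
# source center it maps onto this one, whether the local configuration flips
# (odd permutation of the SMILES neighbor order for tetrahedral centers;
# exactly one matched directionality neighbor for cis/trans centers), and
# whether the automorphism fixes the center while swapping two of its
# substituents (the para-deactivation test).
# ---------------------------------------------------------------------------

.permParity <- function(sigma) {
  # sign of a permutation given as an integer vector; TRUE = odd
  visited <- logical(length(sigma))
  odd <- FALSE
  for (s in seq_along(sigma)) {
    if (visited[s]) next
    len <- 0L
    j <- s
    while (!visited[j]) {
      visited[j] <- TRUE
      j <- sigma[j]
      len <- len + 1L
    }
    if (len %% 2L == 0L) odd <- !odd
  }
  odd
}

.centerMaps <- function(model, aut, graph) {
  centers <- c(model@trueCenters, model@paraCenters)
  m <- length(centers)
  tetOf <- integer(nrow(graph@atoms))
  halfOf <- integer(nrow(graph@atoms))
  for (i in seq_along(centers)) {
    cc <- centers[[i]]
    if (cc$kind == "tet") tetOf[cc$atom] <- i else halfOf[cc$halves] <- i
  }
  lapply(aut, function(p) {
    src <- integer(m); flip <- logical(m); fixswap <- logical(m)
    for (i in seq_along(centers)) {
      ci <- centers[[i]]
      if (ci$kind == "tet") {
        a <- which(p == ci$atom)   # p maps a -> atom_i
        j <- tetOf[a]
        if (j == 0L) stop("automorphism maps a stereocenter onto a non-center")
        cj <- centers[[j]]
        img <- lapply(cj$nb, function(e) if (identical(e, "H")) "H" else p[e])
        sigma <- vapply(seq_along(img), function(k) {
          hit <- which(vapply(ci$nb, identical, logical(1), img[[k]]))
          hit[1]
        }, 0L)
        src[i] <- j
        flip[i] <- .permParity(sigma)
        fixswap[i] <- p[ci$atom] == ci$atom &&
          any(vapply(ci$nb, function(e)
            !identical(e, "H") && p[e] != e, logical(1)))
      } else {
        a <- which(p == ci$halves[1] | p == ci$halves[2])
        j <- unique(halfOf[a])
        if (length(j) != 1L || any(j == 0L))
          stop("automorphism maps a stereocenter onto a non-center")
        cj <- centers[[j]]
        # matched directionality neighbors via the half correspondence
        matched <- 0L
        for (k in 1:2) {
          h <- cj$halves[k]
          hImg <- p[h]
          kImg <- match(hImg, ci$halves)
          if (p[cj$dir[k]] == ci$dir[kImg]) matched <- matched + 1L
        }
        src[i] <- j
        flip[i] <- matched == 1L
        fs <- FALSE
        if (setequal(p[ci$halves], ci$halves)) {
          for (h in ci$halves) {
            sg <- ci$singles[[match(h, ci$halves)]]
            if (p[h] == h && length(sg) == 2L && p[sg[1]] == sg[2]) fs <- TRUE
          }
        }
        fixswap[i] <- fs
      }
    }
    list(src = src, flip = flip, fixswap = fixswap)
  })
}

# transported configuration: entry i receives the (possibly negated) value of
# its source center; inactive entries (-1) stay inactive
.transportConfig <- function(vec, map, idx = seq_along(vec), offset = 0L) {
  out <- vec[map$src[idx + offset] - offset]
  fl <- map$flip[idx + offset] & out >= 0L
  out[fl] <- 1L - out[fl]
  out
}

.bitsVector <- function(v, k) {
  # first entry most significant so integer order equals lexicographic order
  if (k == 0L) return(integer(0))
  as.integer(bitwAnd(bitwShiftR(v, (k - 1L):0L), 1L))
}

.lexLess <- function(a, b) {
  d <- a - b
  nz <- which(d != 0L)
  length(nz) > 0L && d[nz[1]] < 0L
}

# ---------------------------------------------------------------------------
# Enumeration of unique stereoisomers
# ---------------------------------------------------------------------------

.enumerateTrue <- function(nTrue, maps) {
  if (nTrue == 0L) return(list(integer(0)))
  keep <- list()
  idx <- seq_len(nTrue)
  for (v in 0:(2^nTrue - 1L)) {
    cfg <- .bitsVector(v, nTrue)
    dominated <- FALSE
    for (map in maps) {
      t <- .transportConfig(cfg, map, idx)
      if (.lexLess(t, cfg)) { dominated <- TRUE; break }
    }
    if (!dominated) keep[[length(keep) + 1L]] <- cfg
  }
  keep
}

.enumeratePara <- function(trueCfg, nTrue, nPara, maps) {
  if (nPara == 0L) return(list(list(true = trueCfg, para = integer(0))))
  tIdx <- seq_len(nTrue)
  pIdx <- seq_len(nPara)
  # automorphisms preserving the configuration of the true stereocenters
  autTrue <- Filter(function(map) {
    nTrue == 0L || identical(.transportConfig(trueCfg, map, tIdx), trueCfg)
  }, maps)
  out <- list()
  # membership in Aut^para: a permutation may only swap two *distinct* para
  # stereocenters when their absolute configurations correspond; a center
  # mapped onto itself imposes no constraint (a fixed center whose
  # substituents are swapped is precisely what deactivates it)
  inAutPara <- function(map, cur) {
    for (i in pIdx) {
      j <- map$src[nTrue + i] - nTrue
      if (j == i) next
      if (cur[i] < 0L || cur[j] < 0L) {
        if (cur[i] != cur[j]) return(FALSE)
        next
      }
      t <- if (map$flip[nTrue + i]) 1L - cur[j] else cur[j]
      if (t != cur[i]) return(FALSE)
    }
    TRUE
  }
  for (v in 0:(2^nPara - 1L)) {
    p0 <- .bitsVector(v, nPara)
    cur <- p0
    repeat {
      autPara <- Filter(function(map) inAutPara(map, cur), autTrue)
      deact <- vapply(pIdx, function(m) {
        cur[m] >= 0L && any(vapply(autPara, function(map)
          map$fixswap[nTrue + m], logical(1)))
      }, logical(1))
      if (!any(deact)) break
      cur[deact] <- -1L
    }
    # report only the canonical representative: deactivated entries must
    # already have been 0, and no automorphism may give a smaller vector
    # (-1 compared as 0)
    if (!identical(pmax(cur, 0L), p0)) next
    dominated <- FALSE
    for (map in autTrue) {
      t <- .transportConfig(cur, map, pIdx, offset = nTrue)
      if (.lexLess(pmax(t, 0L), pmax(cur, 0L))) { dominated <- TRUE; break }
    }
    if (!dominated) out[[length(out) + 1L]] <- list(true = trueCfg, para = cur)
  }
  out
}

.enumerateConfigs <- function(model, maps) {
  nTrue <- length(model@trueCenters)
  nPara <- length(model@paraCenters)
  res <- list()
  for (trueCfg in .enumerateTrue(nTrue, maps)) {
    res <- c(res, .enumeratePara(trueCfg, nTrue, nPara, maps))
  }
  res
}

# enantiomer cross-references: flip every tetrahedral entry (0 <-> 1, -1
# fixed), then locate the equivalent reported stereoisomer; a self-match is a
# meso form and gets no reference
.enantiomerRefs <- function(configs, model, maps) {
  centers <- c(model@trueCenters, model@paraCenters)
  kinds <- vapply(centers, `[[`, "", "kind")
  nTrue <- length(model@trueCenters)
  full <- lapply(configs, function(cf) c(cf$true, cf$para))
  vapply(seq_along(configs), function(i) {
    v <- full[[i]]
    tet <- kinds == "tet" & v >= 0L
    if (!any(tet)) return(NA_integer_)
    fl <- v
    fl[tet] <- 1L - fl[tet]
    for (map in maps) {
      t <- .transportConfig(fl, map)
      for (j in seq_along(full)) {
        if (identical(t, full[[j]])) {
          return(if (j == i) NA_integer_ else j)
        }
      }
    }
    NA_integer_
  }, 0L)
}

# ---------------------------------------------------------------------------
# Stereo SMILES writing
# ---------------------------------------------------------------------------

# '/' and '\' encode on which side of the double-bond axis the marked
# substituent lies; the side depends on the writing direction of the bond
.slashSide <- function(sym, neighborFirst) {
  # TRUE = "down" side
  if (neighborFirst) sym == "/" else sym == "\\"
}
.sideSlash <- function(down, neighborFirst) {
  if (neighborFirst) (if (down) "/" else "\\") else (if (down) "\\" else "/")
}

.stereoSmiles <- function(graph, plan, model, cfg) {
  n <- nrow(graph@atoms)
  tags <- rep(NA_character_, n)
  slash <- matrix("", n, n)
  centers <- c(model@trueCenters, model@paraCenters)
  values <- c(cfg$true, cfg$para)
  ord <- order(vapply(centers, `[[`, 0L, "pos"))
  for (i in ord) {
    cc <- centers[[i]]
    v <- values[i]
    if (v < 0L) next
    if (cc$kind == "tet") {
      tags[cc$atom] <- if (v == 0L) "@@" else "@"
      next
    }
    h1 <- cc$halves[1]; h2 <- cc$halves[2]
    d1 <- cc$dir[1]; d2 <- cc$dir[2]
    readSide <- function(h, d) {
      nbFirst <- isTRUE(plan$parent[h] == d)
      pFrom <- if (nbFirst) d else h
      pTo <- if (nbFirst) h else d
      if (!nzchar(slash[pFrom, pTo])) {
        slash[pFrom, pTo] <<- "/"
      }
      .slashSide(slash[pFrom, pTo], nbFirst)
    }
    setSide <- function(h, d, down) {
      nbFirst <- isTRUE(plan$parent[h] == d)
      pFrom <- if (nbFirst) d else h
      pTo <- if (nbFirst) h else d
      if (!nzchar(slash[pFrom, pTo])) {
        slash[pFrom, pTo] <<- .sideSlash(down, nbFirst)
        return(TRUE)
      }
      .slashSide(slash[pFrom, pTo], nbFirst) == down
    }
    s1 <- readSide(h1, d1)
    want <- if (v == 1L) s1 else !s1      # 1 = cis: same side
    if (!setSide(h2, d2, want)) {
      others <- setdiff(cc$singles[[2]], d2)
      ok <- length(others) == 1L && setSide(h2, others[1], !want)
      if (!ok) stop("cannot encode cis/trans configuration consistently")
    }
  }
  .assembleSmiles(graph, plan, tags, slash)
}

# ---------------------------------------------------------------------------
# User-facing stereo enumeration
# ---------------------------------------------------------------------------

#' Enumerate the unique stereoisomers of one molecule
#'
#' Detects true and para stereocenters (tetrahedral and cis/trans) from the
#' automorphism group, enumerates all unique configuration vectors by binary
#' counting with automorphism deduplication, and reports each stereoisomer as
#' a stereo-annotated SMILES string.  Double bonds inside cycles, cumulated
#' double bonds and centers of valence above four carry no stereochemistry,
#' and para stereocenters that lie only in rings are not considered.
#'
#' @param x a SMILES string, a [MolecularGraph-class] or a
#'   [CanonicalIsomer-class]
#' @param inputOrder if \code{x} is a SMILES string (or a parsed graph with a
#'   traversal plan attached), freeze the neighbor orders from the input
#'   string instead of the package-canonical atom ranking.  Configuration
#'   vectors are only comparable across conventions through the strings.
#' @return data.frame with one row per unique stereoisomer: \code{smiles},
#'   \code{config} (configuration vector, \code{-1} = inactive para center),
#'   \code{nTet}, \code{nCt} (active stereocenter counts) and
#'   \code{enantiomer} (row index of the enantiomer, NA for meso forms or
#'   molecules without tetrahedral centers)
#' @examples
#' stereoisomers("ClC(Br)CC(Br)Cl", inputOrder = TRUE)
#' @export
stereoisomers <- function(x, inputOrder = FALSE) {
  aut <- NULL
  if (is.character(x)) x <- parseSmiles(x)
  if (is(x, "CanonicalIsomer")) {
    aut <- x@automorphisms
    x <- x@graph
  }
  stopifnot(is(x, "MolecularGraph"))
  if (is.null(aut)) aut <- graphAutomorphisms(x)
  plan <- if (inputOrder) {
    pl <- attr(x, "plan")
    if (is.null(pl)) stop("inputOrder = TRUE requires a parsed SMILES string")
    pl
  } else {
    .smilesPlan(x, canonicalRanking(x, aut))
  }
  model <- .detectCenters(x, aut, plan)
  maps <- .centerMaps(model, aut, x)
  configs <- .enumerateConfigs(model, maps)
  enant <- .enantiomerRefs(configs, model, maps)
  kinds <- vapply(c(model@trueCenters, model@paraCenters), `[[`, "", "kind")
  data.frame(
    smiles = vapply(configs, function(cf) .stereoSmiles(x, plan, model, cf), ""),
    config = vapply(configs, function(cf)
      paste0("[", paste(c(cf$true, cf$para), collapse = ","), "]"), ""),
    nTet = vapply(configs, function(cf)
      sum(kinds == "tet" & c(cf$true, cf$para) >= 0L), 0L),
    nCt = vapply(configs, function(cf)
      sum(kinds == "ct" & c(cf$true, cf$para) >= 0L), 0L),
    enantiomer = enant,
    stringsAsFactors = FALSE)
}

#' Detect the stereocenters of a molecule
#'
#' @param x a SMILES string, [MolecularGraph-class] or
#'   [CanonicalIsomer-class]
#' @param inputOrder see [stereoisomers()]
#' @return a [StereoModel-class]
#' @export
stereoModel <- function(x, inputOrder = FALSE) {
  aut <- NULL
  if (is.character(x)) x <- parseSmiles(x)
  if (is(x, "CanonicalIsomer")) {
    aut <- x@automorphisms
    x <- x@graph
  }
  if (is.null(aut)) aut <- graphAutomorphisms(x)
  plan <- if (inputOrder) attr(x, "plan") else
    .smilesPlan(x, canonicalRanking(x, aut))
  .detectCenters(x, aut, plan)
}

setMethod("show", "StereoModel", function(object) {
  kt <- vapply(object@trueCenters, `[[`, "", "kind")
  kp <- vapply(object@paraCenters, `[[`, "", "kind")
  cat("StereoModel:", sum(kt == "tet"), "true tetrahedral,",
      sum(kt == "ct"), "true cis/trans,",
      sum(kp == "tet"), "+", sum(kp == "ct"), "retained para centers\n")
})
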