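#' @include molenum-package.R
NULL

#' Molecular multigraph of united atoms
#'
#' A connected labeled multigraph describing one molecule: an ordered table of
#' united atoms (heavy atom plus its attached hydrogens) and a symmetric
#' adjacency matrix of non-negative integer bond orders with a zero diagonal.
#' Row sums of the adjacency matrix equal the effective valences (element
#' valence minus attached hydrogens), i.e. the graph is always a completed
#' molecule.
#'
#' @slot atoms data.frame with columns \code{symbol}, \code{nH},
#'   \code{valence}, \code{effValence} (one row per united atom)
#' @slot adjacency integer matrix of bond orders
#' @exportClass MolecularGraph
setClass("MolecularGraph",
  representation(atoms = "data.frame", adjacency = "matrix"))

setValidity("MolecularGraph", function(object) {
  A <- object@adjacency
  at <- object@atoms
  n <- nrow(at)
  msg <- character(0)
  if (!all(c("symbol", "nH", "valence", "effValence") %in% names(at)))
    msg <- c(msg, "atoms table must have symbol, nH, valence, effValence")
  if (nrow(A) != n || ncol(A) != n)
    msg <- c(msg, "adjacency dimension does not match atom count")
  else {
    if (!isTRUE(all(A == t(A)))) msg <- c(msg, "adjacency must be symmetric")
    if (any(diag(A) != 0)) msg <- c(msg, "adjacency diagonal must be zero")
    if (any(A < 0) || any(A > 4)) msg <- c(msg, "bond orders must be in 0..4")
    if (n > 0 && !isTRUE(all(rowSums(A) == at$effValence)))
      msg <- c(msg, "row sums must equal effective valences")
  }
  if (length(msg)) msg else TRUE
})

#' Canonical constitutional isomer
#'
#' A molecular graph whose adjacency matrix is the lexicographically largest
#' among all type-preserving relabelings, together with the automorphism group
#' of that matrix (the by-product of the canonicity test).
#'
#' @slot graph a [MolecularGraph-class]
#' @slot automorphisms list of integer permutation vectors, identity included
#' @exportClass CanonicalIsomer
setClass("CanonicalIsomer",
  representation(graph = "MolecularGraph", automorphisms = "list"))

setValidity("CanonicalIsomer", function(object) {
  n <- nrow(object@graph@atoms)
  for (p in object@automorphisms) {
    if (length(p) != n || !setequal(p, seq_len(n)))
      return("automorphisms must be permutations of the atom indices")
  }
  TRUE
})

#' Molecular formula with count-sets and implicit-hydrogen constraints
#'
#' @slot free named list: element symbol -> admissible counts (integer vector)
#' @slot fixed data.frame with columns \code{symbol}, \code{nH} and a list
#'   column \code{counts} of admissible counts, one row per united-atom spec
#'   such as \code{\{CH1\}}
#' @slot text the original formula string
#' @exportClass MolecularFormula
setClass("MolecularFormula",
  representation(free = "list", fixed = "data.frame", text = "character"))

#' Property restrictions for an enumeration run
#'
#' Each slot holds the set of admissible values (an integer vector; empty
#' means unrestricted).  \code{maxBondOrder} caps bond orders during matrix
#' filling.  \code{substructures} is a list of substructure definitions, each
#' carrying its own admissible occurrence set.
#'
#' @exportClass RestrictionSet
setClass("RestrictionSet",
  representation(unsaturations = "integer", totalBonds = "integer",
    singleBonds = "integer", doubleBonds = "integer", tripleBonds = "integer",
    quadrupleBonds = "integer", cycles = "integer", maxBondOrder = "integer",
    substructures = "list"),
  prototype(unsaturations = integer(0), totalBonds = integer(0),
    singleBonds = integer(0), doubleBonds = integer(0),
    tripleBonds = integer(0), quadrupleBonds = integer(0),
    cycles = integer(0), maxBondOrder = 3L, substructures = list()))

setValidity("RestrictionSet", function(object) {
  if (length(object@maxBondOrder) != 1L || object@maxBondOrder < 1L ||
      object@maxBondOrder > 4L)
    return("maxBondOrder must be a single integer in 1..4")
  sets <- list(object@unsaturations, object@totalBonds, object@singleBonds,
    object@doubleBonds, object@tripleBonds, object@quadrupleBonds,
    object@cycles)
  if (any(vapply(sets, function(s) any(s < 0), logical(1))))
    return("restriction values must be non-negative")
  TRUE
})

#' Detected stereocenters of a constitutional isomer
#'
#' Holds the true and retained potential-para stereocenters of a molecule,
#' with the SMILES neighbor orders frozen before configuration enumeration,
#' plus the traversal plan of the SMILES writer they refer to.
#'
#' @exportClass StereoModel
setClass("StereoModel",
  representation(trueCenters = "list", paraCenters = "list", plan = "list"))

#' Result of an enumeration run
#'
#' One record per reported constitutional isomer; each record carries the
#' canonical isomer, its constitutional SMILES, and the list of its unique
#' stereoisomers (SMILES, stereocenter counts, enantiomer cross-reference).
#'
#' @exportClass IsomerEnumeration
setClass("IsomerEnumeration",
  representation(formula = "character", records = "list",
    nConstitutional = "integer", nSpatial = "integer"))

setMethod("show", "MolecularGraph", function(object) {
  at <- object@atoms
  lab <- ifelse(at$nH > 0, paste0(at$symbol, "H", at$nH), at$symbol)
  cat("MolecularGraph with", nrow(at), "united atoms:",
      paste(lab, collapse = " "), "\n")
  cat("bonds:", sum(object@adjacency[upper.tri(object@adjacency)] > 0), "\n")
})

setMethod("show", "CanonicalIsomer", function(object) {
  show(object@graph)
  cat("automorphism group size:", length(object@automorphisms), "\n")
})

setMethod("show", "MolecularFormula", function(object) {
  cat("MolecularFormula:", object@text, "\n")
  n <- length(expandFormula(object))
  cat("expands to", n, "concrete formula(s)\n")
})

setMethod("show", "IsomerEnumeration", function(object) {
  cat("IsomerEnumeration for", object@formula, "\n")
  cat("  constitutional isomers:", object@nConstitutional, "\n")
  cat("  spatial isomers:       ", object@nSpatial, "\n")
})

setMethod("show", "RestrictionSet", function(object) {
  cat("RestrictionSet (maxBondOrder =", object@maxBondOrder, ")\n")
  for (nm in c("unsaturations", "totalBonds", "singleBonds", "doubleBonds",
               "tripleBonds", "quadrupleBonds", "cycles")) {
    v <- slot(object, nm)
    if (length(v)) cat("  ", nm, ": {", paste(v, collapse = ","), "}\n")
  }
  if (length(object@substructures))
    cat("  substructures:", length(object@substructures), "\n")
})

# ---- accessors -------------------------------------------------------------

#' Accessors for molecular graphs and isomers
#'
#' \code{adjacency} returns the bond-order matrix, \code{atomTable} the united
#' atom table, \code{automorphisms} the automorphism group of a canonical
#' isomer, and \code{records} the per-isomer records of an enumeration.
#'
#' @param x a [MolecularGraph-class], [CanonicalIsomer-class] or
#'   [IsomerEnumeration-class]
#' @return matrix, data.frame or list, respectively
#' @rdname accessors
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))

#' @rdname accessors
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))

#' @rdname accessors
#' @export
setGeneric("automorphisms", function(x) standardGeneric("automorphisms"))

#' @rdname accessors
#' @export
setGeneric("records", function(x) standardGeneric("records"))

#' @rdname accessors
setMethod("adjacency", "MolecularGraph", function(x) x@adjacency)
#' @rdname accessors
setMethod("adjacency", "CanonicalIsomer", function(x) x@graph@adjacency)
#' @rdname accessors
setMethod("atomTable", "MolecularGraph", function(x) x@atoms)
#' @rdname accessors
setMethod("atomTable", "CanonicalIsomer", function(x) x@graph@atoms)
#' @rdname accessors
setMethod("automorphisms", "CanonicalIsomer", function(x) x@automorphisms)
#' @rdname accessors
setMethod("records", "IsomerEnumeration", function(x) x@records)

#' @rdname accessors
#' @export
setMethod("length", "IsomerEnumeration", function(x) length(x@records))

#' Tabulate an enumeration result
#'
#' @param x an [IsomerEnumeration-class]
#' @param row.names,optional,... ignored (S3 compatibility)
#' @return data.frame with one row per stereoisomer: formula, constitutional
#'   SMILES, stereo SMILES, stereocenter counts and enantiomer reference
#' @export
as.data.frame.IsomerEnumeration <- function(x, row.names = NULL,
                                            optional = FALSE, ...) {
  rows <- list()
  for (rec in x@records) {
    for (k in seq_along(rec$stereo)) {
      st <- rec$stereo[[k]]
      rows[[length(rows) + 1L]] <- data.frame(
        formula = rec$formula, constitution = rec$smiles,
        smiles = st$smiles, nTet = st$ntet, nCt = st$nct,
        enantiomer = if (is.na(st$enantiomer)) NA_character_ else
          rec$stereo[[st$enantiomer]]$smiles,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
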