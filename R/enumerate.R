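#' @include formula.R graph.R smiles.R stereo.R filters.R
NULL

# enumerate all canonical isomers for one united-atom partition; returns a
# list of CanonicalIsomer (unfiltered)
.enumeratePartition <- function(partition, maxBondOrder = 3L) {
  atoms <- .partitionAtoms(partition)
  res <- cpp_enumerate(as.integer(atoms$effValence), as.integer(atoms$type),
                       as.integer(maxBondOrder))
  lapply(res, function(r) {
    g <- molecularGraph(atoms[, c("symbol", "nH", "valence", "effValence")],
                        r$A)
    new("CanonicalIsomer", graph = g, automorphisms = r$aut)
  })
}

#' Enumerate the canonical constitutional isomers of one hydrogen partition
#'
#' Streams every connected, canonical adjacency matrix for the united-atom
#' partition, in strictly lexicographically decreasing order, each with its
#' full automorphism group.  Isomers failing the property or substructure
#' restrictions are suppressed.
#'
#' @param partition a partition from [distributeHydrogens()]
#' @param restrictions optional [RestrictionSet-class]
#' @param maxBondOrder maximum generated bond order (overridden by
#'   \code{restrictions@maxBondOrder} when restrictions are given)
#' @return list of [CanonicalIsomer-class]
#' @export
enumerateCanonicalMatrices <- function(partition, restrictions = NULL,
                                       maxBondOrder = 3L) {
  if (!is.null(restrictions)) maxBondOrder <- restrictions@maxBondOrder
  isomers <- .enumeratePartition(partition, maxBondOrder)
  if (is.null(restrictions)) return(isomers)
  Filter(function(iso) passesFilters(iso, restrictions), isomers)
}

#' Enumerate all isomers of a molecular formula
#'
#' The full pipeline: the formula is expanded into concrete formulas,
#' hydrogens are distributed onto the heavy atoms (united atoms), the
#' canonical adjacency matrices of every partition are generated by orderly
#' enumeration, property and substructure restrictions are applied, Kekule
#' duplicates of alternating six-rings are removed, and (optionally) every
#' surviving constitutional isomer is expanded into its unique stereoisomers.
#'
#' @param formula formula string or [MolecularFormula-class]
#' @param restrictions optional [RestrictionSet-class]
#' @param stereo expand stereoisomers? (default TRUE)
#' @param maxBondOrder maximum bond order when no restriction set is given
#' @param aromaticDedup recognize six-rings with alternating single/double
#'   bonds and report only one Kekule form per such ring system (basic
#'   aromaticity handling; off by default, which keeps the output exhaustive
#'   over distinct adjacency matrices)
#' @param progressEvery print a progress line to standard error after every
#'   N detected (stereo)isomers; 0 disables progress output
#' @return an [IsomerEnumeration-class]
#' @examples
#' enumerateIsomers("C4H10")
#' countIsomers("C3H8O3")
#' @export
enumerateIsomers <- function(formula, restrictions = NULL, stereo = TRUE,
                             maxBondOrder = 3L, aromaticDedup = FALSE,
                             progressEvery = 0L) {
  if (is.character(formula)) formula <- parseFormula(formula)
  rs <- if (is.null(restrictions)) restrictionSet(maxBondOrder = maxBondOrder)
        else restrictions
  concrete <- expandFormula(formula)
  records <- list()
  nSpatial <- 0L
  nSeen <- 0L
  lastReport <- 0L
  for (cf in concrete) {
    u <- unsaturations(cf$counts)
    if (u < 0) next
    if (length(rs@unsaturations) && !(u %in% rs@unsaturations)) next
    recs <- list()
    for (part in distributeHydrogens(cf)) {
      for (iso in enumerateCanonicalMatrices(part, rs)) {
        g <- iso@graph
        ranks <- canonicalRanking(g, iso@automorphisms)
        plan <- .smilesPlan(g, ranks)
        smi <- .assembleSmiles(g, plan)
        recs[[length(recs) + 1L]] <- list(formula = cf$label, isomer = iso,
          smiles = smi, plan = plan)
      }
    }
    if (aromaticDedup) {
      recs <- Filter(function(r)
        .kekuleRepresentative(r$isomer@graph, r$smiles), recs)
    }
    for (r in recs) {
      if (stereo) {
        g <- r$isomer@graph
        model <- .detectCenters(g, r$isomer@automorphisms, r$plan)
        maps <- .centerMaps(model, r$isomer@automorphisms, g)
        configs <- .enumerateConfigs(model, maps)
        enant <- .enantiomerRefs(configs, model, maps)
        kinds <- vapply(c(model@trueCenters, model@paraCenters), `[[`, "",
                        "kind")
        r$stereo <- lapply(seq_along(configs), function(i) {
          cf2 <- configs[[i]]
          v <- c(cf2$true, cf2$para)
          list(smiles = .stereoSmiles(g, r$plan, model, cf2),
               config = v,
               ntet = sum(kinds == "tet" & v >= 0L),
               nct = sum(kinds == "ct" & v >= 0L),
               enantiomer = enant[i])
        })
        nSpatial <- nSpatial + length(r$stereo)
        nSeen <- nSeen + length(r$stereo)
      } else {
        r$stereo <- list()
        nSeen <- nSeen + 1L
      }
      r$plan <- NULL
      records[[length(records) + 1L]] <- r
      if (progressEvery > 0L && nSeen - lastReport >= progressEvery) {
        lastReport <- nSeen
        message(sprintf("%s: %d isomer(s) so far", cf$label, nSeen))
      }
    }
  }
  new("IsomerEnumeration", formula = formula@text, records = records,
      nConstitutional = length(records),
      nSpatial = if (stereo) nSpatial else NA_integer_)
}

#' Count isomers without keeping the structures
#'
#' @inheritParams enumerateIsomers
#' @return list with elements \code{constitutional} and \code{spatial}
#'   (\code{spatial} is NA when \code{stereo = FALSE})
#' @export
countIsomers <- function(formula, restrictions = NULL, stereo = TRUE,
                         maxBondOrder = 3L, aromaticDedup = FALSE,
                         progressEvery = 0L) {
  e <- enumerateIsomers(formula, restrictions, stereo, maxBondOrder,
                        aromaticDedup, progressEvery)
  list(constitutional = e@nConstitutional, spatial = e@nSpatial)
}
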