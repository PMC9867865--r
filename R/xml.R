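#' @include enumerate.R
NULL

#' Write an enumeration result to XML
#'
#' One \code{formula_isomers} element per concrete formula, one
#' \code{constitutional_isomer} element per reported isomer, and one nested
#' \code{stereoisomer} element per unique stereoisomer carrying its
#' stereocenter counts and enantiomer cross-reference.  The document type
#' definition is shipped at
#' \code{system.file("extdata", "isomer_enumeration.dtd", package = "molenum")}.
#'
#' @param x an [IsomerEnumeration-class]
#' @param file output path or \code{""} for standard output
#' @return invisibly, the path written to
#' @export
writeIsomerXML <- function(x, file) {
  stopifnot(is(x, "IsomerEnumeration"))
  doc <- xml2::xml_new_root("isomer_enumeration",
                            formula = x@formula)
  labels <- vapply(x@records, `[[`, "", "formula")
  ci <- 0L
  for (lab in unique(labels)) {
    recs <- x@records[labels == lab]
    nSpat <- sum(vapply(recs, function(r)
      max(1L, length(r$stereo)), 0L))
    fnode <- xml2::xml_add_child(doc, "formula_isomers", formula = lab,
      n_constitutional = as.character(length(recs)),
      n_spatial = as.character(nSpat))
    for (r in recs) {
      ci <- ci + 1L
      cid <- paste0("c", ci)
      cnode <- xml2::xml_add_child(fnode, "constitutional_isomer",
        id = cid, smiles = r$smiles)
      for (k in seq_along(r$stereo)) {
        st <- r$stereo[[k]]
        attrs <- list(id = paste0(cid, ".s", k), smiles = st$smiles,
                      n_tet = as.character(st$ntet),
                      n_ct = as.character(st$nct))
        if (!is.na(st$enantiomer))
          attrs$enantiomer <- paste0(cid, ".s", st$enantiomer)
        do.call(xml2::xml_add_child,
                c(list(cnode, "stereoisomer"), attrs))
      }
    }
  }
  txt <- as.character(doc)
  # insert the document type declaration after the XML declaration
  txt <- sub("\\?>\n",
             "?>\n<!DOCTYPE isomer_enumeration SYSTEM \"isomer_enumeration.dtd\">\n",
             txt)
  if (identical(file, "")) {
    cat(txt)
  } else {
    writeLines(txt, file, sep = "")
  }
  invisible(file)
}

#' Read an enumeration XML document back
#'
#' @param file path to a document written by [writeIsomerXML()]
#' @return data.frame with one row per stereoisomer (or per constitutional
#'   isomer when no stereoisomers were written)
#' @export
readIsomerXML <- function(file) {
  doc <- xml2::read_xml(file)
  rows <- list()
  for (fn in xml2::xml_find_all(doc, "formula_isomers")) {
    lab <- xml2::xml_attr(fn, "formula")
    for (cn in xml2::xml_find_all(fn, "constitutional_isomer")) {
      smi <- xml2::xml_attr(cn, "smiles")
      sts <- xml2::xml_find_all(cn, "stereoisomer")
      if (!length(sts)) {
        rows[[length(rows) + 1L]] <- data.frame(formula = lab,
          constitution = smi, smiles = NA_character_, nTet = NA_integer_,
          nCt = NA_integer_, enantiomer = NA_character_,
          stringsAsFactors = FALSE)
      }
      for (sn in sts) {
        rows[[length(rows) + 1L]] <- data.frame(formula = lab,
          constitution = smi, smiles = xml2::xml_attr(sn, "smiles"),
          nTet = as.integer(xml2::xml_attr(sn, "n_tet")),
          nCt = as.integer(xml2::xml_attr(sn, "n_ct")),
          enantiomer = xml2::xml_attr(sn, "enantiomer"),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
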