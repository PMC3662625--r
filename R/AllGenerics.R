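#' @include AllClasses.R
NULL

#' Accessors for ligfam containers
#'
#' Small accessor generics for the S4 containers: \code{atoms()} returns
#' the atom table of a structure or ligand, \code{structureId()} its
#' source identifier, \code{ligandCode()} the HET code of a ligand,
#' \code{isComplete()} the ribose-ring completeness flag,
#' \code{orderString()} the strand-order permutation of a sheet,
#' \code{typeLabels()} the conformation Type assignments,
#' \code{rulePositions()} the anchored positions of a site rule and
#' \code{representativeId()} the representative of a family alignment.
#'
#' @param x An object of the appropriate class.
#' @return The slot value (see description).
#' @name ligfam-accessors
#' @aliases atoms structureId ligandCode isComplete orderString typeLabels
#'   rulePositions representativeId
NULL

#' @rdname ligfam-accessors
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname ligfam-accessors
#' @export
setGeneric("structureId", function(x) standardGeneric("structureId"))

#' @rdname ligfam-accessors
#' @export
setGeneric("ligandCode", function(x) standardGeneric("ligandCode"))

#' @rdname ligfam-accessors
#' @export
setGeneric("isComplete", function(x) standardGeneric("isComplete"))

#' @rdname ligfam-accessors
#' @export
setGeneric("orderString", function(x) standardGeneric("orderString"))

#' @rdname ligfam-accessors
#' @export
setGeneric("typeLabels", function(x) standardGeneric("typeLabels"))

#' @rdname ligfam-accessors
#' @export
setGeneric("rulePositions", function(x) standardGeneric("rulePositions"))

#' @rdname ligfam-accessors
#' @export
setGeneric("representativeId", function(x) standardGeneric("representativeId"))

#' @rdname ligfam-accessors
#' @export
setMethod("atoms", "PdbStructure", function(x) x@atoms)

#' @rdname ligfam-accessors
#' @export
setMethod("atoms", "LigandInstance", function(x) x@atoms)

#' @rdname ligfam-accessors
#' @export
setMethod("structureId", "PdbStructure", function(x) x@structureId)

#' @rdname ligfam-accessors
#' @export
setMethod("structureId", "LigandInstance", function(x) x@structureId)

#' @rdname ligfam-accessors
#' @export
setMethod("ligandCode", "LigandInstance", function(x) x@ligandCode)

#' @rdname ligfam-accessors
#' @export
setMethod("isComplete", "LigandInstance", function(x) x@complete)

#' @rdname ligfam-accessors
#' @export
setMethod("orderString", "SheetTopology", function(x) x@orderString)

#' @rdname ligfam-accessors
#' @export
setMethod("typeLabels", "ConformationTyping", function(x) x@labels)

#' @rdname ligfam-accessors
#' @export
setMethod("rulePositions", "SiteRule", function(x) x@positions)

#' @rdname ligfam-accessors
#' @export
setMethod("representativeId", "FamilyAlignment", function(x) x@representativeId)

setMethod("show", "PdbStructure", function(object) {
  a <- object@atoms
  cat("PdbStructure", object@structureId, "\n",
      " ", nrow(a), "atoms (", sum(a$type == "ATOM"), "ATOM /",
      sum(a$type == "HETATM"), "HETATM ),",
      length(unique(a$chain)), "chain(s),", object@nModels, "model(s)\n")
})

setMethod("show", "LigandInstance", function(object) {
  cat("LigandInstance", object@ligandCode, "\n",
      "  source:", object@structureId, "chain", object@chain,
      "residue", object@resno, "\n",
      "  atoms:", nrow(object@atoms),
      if (object@complete) "(ribose ring complete)" else
        "(ribose ring INCOMPLETE)", "\n")
})

setMethod("show", "PuckerResult", function(object) {
  if (!object@defined) {
    cat("PuckerResult: pucker undefined (near-planar ring)\n")
    return(invisible(NULL))
  }
  cat(sprintf("PuckerResult: P = %.1f deg (signed %.1f), Vmax = %.1f deg, %s\n",
              object@P, object@PSigned, object@Vmax, object@conformer))
  cat("  nu0..nu4:", paste(sprintf("%.1f", object@nu), collapse = ", "), "\n")
})

setMethod("show", "SheetTopology", function(object) {
  cat("SheetTopology:", object@nCore, "core strands, order",
      object@orderString,
      if (object@ambiguous) "(reading ambiguous)" else "", "\n")
  if (length(object@antiparallel))
    cat("  antiparallel strand(s):",
        paste(object@antiparallel, collapse = ", "), "\n")
})

setMethod("show", "FamilyAlignment", function(object) {
  cat("FamilyAlignment", object@familyId, "\n",
      " ", length(object@sequences), "sequences, width",
      Biostrings::width(object@sequences)[1],
      "| representative:", object@representativeId, "\n")
})

setMethod("show", "SiteRule", function(object) {
  cat("SiteRule", object@familyId, sprintf("(%s mode)", object@mode), "\n",
      " ", nrow(object@positions), "anchored position(s)\n")
  if (nrow(object@positions)) {
    p <- object@positions
    cat("  ", paste(sprintf("%s%d", p$residue, p$resno), collapse = ", "), "\n")
  }
  if (length(object@unmapped))
    cat("  unmapped contact residue(s):",
        paste(object@unmapped, collapse = ", "), "\n")
})

setMethod("show", "ConformationTyping", function(object) {
  k <- length(unique(object@labels))
  cat("ConformationTyping:", nrow(object@matrix), "ligands,", k,
      "Type(s) at threshold", object@threshold, "A\n")
  print(table(Type = object@labels))
})
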