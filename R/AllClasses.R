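## Central S4 containers.
##
## Atom tables are plain data.frames with a fixed column schema shared by
## PdbStructure and LigandInstance:
##   eleno, name, resname, chain, resno, insert, x, y, z, occ, b, altloc,
##   type ("ATOM"/"HETATM"), element

.ATOM_COLS <- c("eleno", "name", "resname", "chain", "resno", "insert",
                "x", "y", "z", "occ", "b", "altloc", "type", "element")

.RIBOSE_RING <- c("C1'", "C2'", "C3'", "C4'", "O4'")

.check_atom_table <- function(atoms) {
  if (!is.data.frame(atoms)) return("'atoms' must be a data.frame")
  miss <- setdiff(.ATOM_COLS, names(atoms))
  if (length(miss))
    return(paste("atom table lacks columns:", paste(miss, collapse = ", ")))
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (nrow(atoms) && !all(is.finite(xyz)))
    return("atom coordinates must be finite")
  if (nrow(atoms) && any(!is.na(atoms$b) & atoms$b < 0))
    return("B-factors must be >= 0")
  NULL
}

#' PdbStructure: a parsed PDB-format structure
#'
#' Holds all ATOM/HETATM records of the first model of a PDB file as a
#' flat atom table, together with the structure identifier.
#'
#' @slot structureId Identifier (typically the PDB id or file stem).
#' @slot atoms data.frame with columns \code{eleno, name, resname, chain,
#'   resno, insert, x, y, z, occ, b, altloc, type, element}.
#' @slot nModels Number of models present in the source file (only the
#'   first is retained).
#'
#' @seealso [readPDB()], [extractLigands()]
#' @export
setClass("PdbStructure",
  representation(structureId = "character",
                 atoms = "data.frame",
                 nModels = "integer"),
  prototype(structureId = NA_character_, nModels = 1L))

setValidity("PdbStructure", function(object) {
  msg <- .check_atom_table(object@atoms)
  if (!is.null(msg)) return(msg)
  if (nrow(object@atoms) == 0) return("structure has no atoms")
  TRUE
})

#' LigandInstance: one bound SAM/SAH residue
#'
#' One extracted ligand residue (all its heavy atoms) together with its
#' provenance and a completeness flag for the ribose ring atoms
#' (\code{C1', C2', C3', C4', O4'}) required by the pucker analysis.
#'
#' @slot ligandCode Three-letter HET code, "SAM" or "SAH".
#' @slot structureId Source structure identifier.
#' @slot chain Chain identifier of the ligand residue.
#' @slot resno Residue number of the ligand residue.
#' @slot atoms Atom table (same schema as [PdbStructure-class]).
#' @slot complete TRUE when all five ribose ring atoms are present.
#'
#' @export
setClass("LigandInstance",
  representation(ligandCode = "character",
                 structureId = "character",
                 chain = "character",
                 resno = "integer",
                 atoms = "data.frame",
                 complete = "logical"))

setValidity("LigandInstance", function(object) {
  msg <- .check_atom_table(object@atoms)
  if (!is.null(msg)) return(msg)
  if (nrow(object@atoms) == 0) return("ligand has no atoms")
  if (!all(object@atoms$resname == object@ligandCode))
    return("all ligand atoms must share the ligand residue name")
  expected <- all(.RIBOSE_RING %in% object@atoms$name)
  if (!identical(unname(object@complete), expected))
    return("completeness flag inconsistent with ribose ring atoms")
  TRUE
})

#' PuckerResult: pseudorotation analysis of a five-membered ring
#'
#' Endocyclic torsions and the derived pseudorotation phase angle and
#' puckering amplitude of a ribose ring, with the envelope conformer name
#' read off the pseudorotation wheel.
#'
#' @slot nu Named numeric(5): endocyclic torsions nu0..nu4, degrees.
#' @slot P Pseudorotation phase angle in [0, 360), degrees.
#' @slot PSigned The same phase in the signed convention (-180, 180].
#' @slot Vmax Puckering amplitude, degrees (>= 0).
#' @slot conformer Envelope conformer name (e.g. "C1'-exo"), or "planar".
#' @slot sector Full 20-sector wheel label (envelope or twist).
#' @slot defined FALSE for near-planar rings (max |nu| < 1 degree), in
#'   which case P, PSigned and conformer are NA/"planar".
#'
#' @seealso [pseudorotation()], [conformerName()]
#' @export
setClass("PuckerResult",
  representation(nu = "numeric", P = "numeric", PSigned = "numeric",
                 Vmax = "numeric", conformer = "character",
                 sector = "character", defined = "logical"))

setValidity("PuckerResult", function(object) {
  if (length(object@nu) != 5) return("nu must hold five torsions")
  if (object@Vmax < 0) return("Vmax must be >= 0")
  if (object@defined) {
    if (abs(object@nu[[3]] - object@Vmax * cos(object@P * pi / 180)) > 0.01)
      return("nu2 must equal Vmax*cos(P) within 0.01 degrees")
  }
  TRUE
})

#' SheetTopology: strand order of a beta-sheet
#'
#' The linearised strand graph of one beta-sheet: strands numbered by
#' N-to-C sequence position and read left-to-right across the sheet.
#'
#' @slot nCore Number of core strands.
#' @slot orderString Spatial permutation of 1..nCore, e.g. "3214567".
#' @slot strands data.frame describing the core strands (id, chain,
#'   start, end).
#' @slot antiparallel Integer ids of strands running antiparallel to the
#'   majority orientation.
#' @slot readings Both possible reading directions of the sheet.
#' @slot ambiguous TRUE when the canonical-orientation rule could not
#'   discriminate the two readings via the catalog.
#'
#' @seealso [buildSheet()], [assignLigFold()]
#' @export
setClass("SheetTopology",
  representation(nCore = "integer", orderString = "character",
                 strands = "data.frame", antiparallel = "integer",
                 readings = "character", ambiguous = "logical"))

setValidity("SheetTopology", function(object) {
  if (object@nCore < 1) return("nCore must be >= 1")
  digits <- strsplit(object@orderString, "")[[1]]
  if (!setequal(digits, as.character(seq_len(object@nCore))) ||
      length(digits) != object@nCore)
    return("orderString must be a permutation of 1..nCore")
  TRUE
})

#' FamilyAlignment: an aligned protein family with a representative
#'
#' A gapped multiple sequence alignment of a family, one member of which
#' is the designated representative structure; alignment columns are
#' anchored to representative residue numbers.
#'
#' @slot familyId Family identifier.
#' @slot sequences AAStringSet of equal-width aligned sequences.
#' @slot representativeId Name of the representative row.
#' @slot columnMap Integer vector (one per alignment column) giving the
#'   representative residue number of the column, NA at representative
#'   gap columns.
#'
#' @seealso [readFamilyAlignment()], [buildSiteRule()]
#' @export
setClass("FamilyAlignment",
  representation(familyId = "character",
                 sequences = "AAStringSet",
                 representativeId = "character",
                 columnMap = "integer"))

setValidity("FamilyAlignment", function(object) {
  w <- Biostrings::width(object@sequences)
  if (length(w) < 1) return("alignment must contain at least one sequence")
  if (length(unique(w)) != 1) return("aligned sequences must share one width")
  if (!object@representativeId %in% names(object@sequences))
    return("representativeId not found among sequence names")
  if (length(object@columnMap) != w[1])
    return("columnMap length must equal the alignment width")
  mapped <- object@columnMap[!is.na(object@columnMap)]
  if (anyDuplicated(mapped))
    return("a representative residue number maps to two columns")
  TRUE
})

#' SiteRule: conserved ligand-binding positions of a family
#'
#' A family site rule: the ligand-contacting residues of the
#' representative structure that are conserved across all aligned family
#' members, anchored to representative residue numbers.
#'
#' @slot familyId Family identifier.
#' @slot mode Conservation mode used, "strict" or "conservative".
#' @slot positions data.frame with columns \code{resno} (representative
#'   residue number), \code{residue} (one-letter code), \code{allowed}
#'   (permitted residues, e.g. "D" or "DE"), \code{feature}.
#' @slot unmapped Contact residue numbers that could not be mapped to an
#'   alignment column.
#'
#' @seealso [buildSiteRule()], [propagateRule()]
#' @export
setClass("SiteRule",
  representation(familyId = "character", mode = "character",
                 positions = "data.frame", unmapped = "integer"))

setValidity("SiteRule", function(object) {
  if (!object@mode %in% c("strict", "conservative"))
    return("mode must be 'strict' or 'conservative'")
  need <- c("resno", "residue", "allowed", "feature")
  if (!all(need %in% names(object@positions)))
    return(paste("positions must have columns:", paste(need, collapse = ", ")))
  TRUE
})

#' ConformationTyping: RMSD-based ligand conformation Types
#'
#' An all-vs-all ligand RMSD matrix together with the complete-linkage
#' cluster labels ("Type 1", "Type 2", ...) obtained by cutting the
#' dendrogram at a distance threshold.  Types are numbered by decreasing
#' cluster size (ties broken by the lexicographically smallest member id).
#'
#' @slot matrix Symmetric RMSD matrix (Angstrom) with ligand ids as
#'   dimnames.
#' @slot threshold Cut height, Angstrom.
#' @slot labels Named character vector, ligand id -> "Type N".
#'
#' @seealso [rmsdMatrix()], [assignTypes()]
#' @export
setClass("ConformationTyping",
  representation(matrix = "matrix", threshold = "numeric",
                 labels = "character"))

setValidity("ConformationTyping", function(object) {
  m <- object@matrix
  if (nrow(m) != ncol(m)) return("RMSD matrix must be square")
  if (any(abs(diag(m)) > 1e-9)) return("RMSD matrix diagonal must be zero")
  if (any(m < -1e-12)) return("RMSD values must be non-negative")
  if (max(abs(m - t(m))) > 1e-9) return("RMSD matrix must be symmetric")
  if (!identical(sort(names(object@labels)), sort(rownames(m))))
    return("every ligand in the matrix must carry a Type label")
  TRUE
})
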