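#' @include AllClasses.R AllGenerics.R
NULL

#' Normalize a PDB atom name
#'
#' Converts PDB-v2 asterisk names to primed names (\code{O2*} ->
#' \code{O2'}) and strips padding whitespace.  All downstream analysis
#' uses primed names only.
#'
#' @param name Character vector of raw atom names.
#' @return Character vector of normalized names.
#' @examples
#' normalizeAtomName(c(" O2* ", "C1*", "SD"))
#' @export
normalizeAtomName <- function(name) {
  gsub("\\*", "'", trimws(name))
}

## Altloc policy: among duplicate (chain, resno, insert, name) records keep
## the highest occupancy; ties broken by altloc identifier order.
.resolve_altlocs <- function(atoms) {
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$name, sep = "\r")
  if (!anyDuplicated(key)) return(atoms)
  ord <- order(key, -atoms$occ, atoms$altloc)
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(key[ord]), , drop = FALSE]
  atoms[order(atoms$eleno), , drop = FALSE]
}

#' Read a PDB-format structure
#'
#' Parses all ATOM/HETATM records of the first model of a fixed-column
#' PDB file (via \pkg{bio3d}), normalizes atom names
#' (see [normalizeAtomName()]) and applies the single-conformer
#' alternate-location policy (highest occupancy, ties broken by altloc
#' identifier).
#'
#' @param path Path to a PDB file.
#' @param structureId Identifier to record; defaults to the file stem.
#' @return A [PdbStructure-class] object.
#' @examples
#' lig <- makeConformer(ligandCode = "SAM")
#' f <- tempfile(fileext = ".pdb")
#' writePDB(ligandToStructure(lig), f)
#' readPDB(f)
#' @export
readPDB <- function(path, structureId = NULL) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  if (is.null(structureId))
    structureId <- sub("\\.(pdb|ent)$", "", basename(path),
                       ignore.case = TRUE)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("PDB parse error in '", path, "': ",
                             conditionMessage(e)))
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0)
    stop("empty structure: no ATOM/HETATM records in ", path)
  n_models <- max(1L, sum(grepl("^MODEL ", readLines(path, warn = FALSE))))
  atoms <- data.frame(
    eleno = as.integer(a$eleno),
    name = normalizeAtomName(a$elety),
    resname = trimws(a$resid),
    chain = ifelse(is.na(a$chain), "", a$chain),
    resno = as.integer(a$resno),
    insert = ifelse(is.na(a$insert), "", a$insert),
    x = a$x, y = a$y, z = a$z,
    occ = ifelse(is.na(a$o), 1, a$o),
    b = ifelse(is.na(a$b), 0, a$b),
    altloc = ifelse(is.na(a$alt), "", a$alt),
    type = a$type,
    element = trimws(ifelse(is.na(a$elesy), "", a$elesy)),
    stringsAsFactors = FALSE)
  no_elem <- !nzchar(atoms$element)
  atoms$element[no_elem] <- sub("^[0-9]*", "",
                                substr(atoms$name[no_elem], 1, 1))
  atoms <- .resolve_altlocs(atoms)
  rownames(atoms) <- NULL
  new("PdbStructure", structureId = structureId, atoms = atoms,
      nModels = as.integer(n_models))
}

#' Write a structure to a PDB file
#'
#' Emits standard-conformant fixed-column ATOM/HETATM records
#' (coordinates to 3 decimals, occupancy in columns 55-60, B-factor in
#' columns 61-66).
#'
#' @param s A [PdbStructure-class].
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
writePDB <- function(s, path) {
  stopifnot(is(s, "PdbStructure"))
  a <- s@atoms
  bio3d::write.pdb(file = path,
                   type = a$type,
                   eleno = a$eleno,
                   elety = a$name,
                   resid = a$resname,
                   chain = a$chain,
                   resno = a$resno,
                   insert = ifelse(nzchar(a$insert), a$insert, NA),
                   xyz = as.vector(t(as.matrix(a[, c("x", "y", "z")]))),
                   o = a$occ,
                   b = a$b,
                   elesy = a$element)
  invisible(path)
}

#' Extract bound ligand instances from a structure
#'
#' Collects, for each (chain, residue number) whose residue name matches
#' one of \code{codes}, a [LigandInstance-class] holding all its atoms.
#' Instances lacking any of the five ribose ring atoms are flagged
#' incomplete (they are excluded from pucker analysis downstream).
#'
#' @param s A [PdbStructure-class].
#' @param codes Character vector of 3-letter HET codes to extract.
#' @return A list of [LigandInstance-class] objects (possibly empty).
#' @examples
#' lig <- makeConformer(ligandCode = "SAM")
#' s <- ligandToStructure(lig)
#' extractLigands(s)
#' @export
extractLigands <- function(s, codes = c("SAM", "SAH")) {
  stopifnot(is(s, "PdbStructure"), length(codes) >= 1)
  a <- s@atoms
  hit <- a$resname %in% codes
  if (!any(hit)) return(list())
  sub <- a[hit, , drop = FALSE]
  key <- paste(sub$chain, sub$resno, sub$insert, sub$resname, sep = "\r")
  lapply(split(seq_len(nrow(sub)), factor(key, levels = unique(key))),
         function(ix) {
           at <- sub[ix, , drop = FALSE]
           rownames(at) <- NULL
           new("LigandInstance",
               ligandCode = at$resname[1],
               structureId = s@structureId,
               chain = at$chain[1],
               resno = at$resno[1],
               atoms = at,
               complete = all(.RIBOSE_RING %in% at$name))
         }) |> unname()
}

#' Protein (ATOM-record) subset of a structure
#'
#' @param s A [PdbStructure-class].
#' @return Atom table restricted to ATOM records.
#' @export
proteinAtoms <- function(s) {
  stopifnot(is(s, "PdbStructure"))
  s@atoms[s@atoms$type == "ATOM", , drop = FALSE]
}

#' Wrap a ligand instance as a standalone structure
#'
#' Convenience for writing generator output to PDB files.
#'
#' @param lig A [LigandInstance-class].
#' @return A [PdbStructure-class] holding only the ligand atoms.
#' @export
ligandToStructure <- function(lig) {
  stopifnot(is(lig, "LigandInstance"))
  new("PdbStructure", structureId = lig@structureId, atoms = lig@atoms,
      nModels = 1L)
}

## Named coordinate matrix of a ligand/atom table (heavy atoms only).
.coords <- function(x, names = NULL) {
  at <- if (is.data.frame(x)) x else x@atoms
  at <- at[!at$element %in% c("H", "D"), , drop = FALSE]
  if (!is.null(names)) {
    ix <- match(names, at$name)
    if (anyNA(ix))
      stop("missing atom(s): ", paste(names[is.na(ix)], collapse = ", "))
    at <- at[ix, , drop = FALSE]
  }
  m <- as.matrix(at[, c("x", "y", "z")])
  rownames(m) <- at$name
  m
}
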