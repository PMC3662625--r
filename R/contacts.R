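#' @include AllClasses.R AllGenerics.R structio.R
NULL

## Donor/acceptor roles of the polar SAM/SAH ligand atoms.  SD is
## deliberately absent (thioether/sulfonium sulfur; it rarely hydrogen
## bonds).  "both" marks hydroxyls that can donate and accept.
.LIGAND_HB_ROLE <- c(
  "N"   = "donor",      # methionine alpha-amine
  "N1"  = "acceptor",   # adenine ring N
  "N3"  = "acceptor",
  "N6"  = "donor",      # exocyclic amine
  "N7"  = "acceptor",
  "O2'" = "both",       # ribose hydroxyls
  "O3'" = "both",
  "O4'" = "acceptor",   # ring ether
  "O"   = "acceptor",   # carboxylate
  "OXT" = "acceptor")

## Donor/acceptor roles of protein N/O/S heavy atoms.  Backbone N/O/OXT
## apply to every residue type; side-chain entries are residue-specific.
.PROTEIN_HB_BACKBONE <- c("N" = "donor", "O" = "acceptor",
                          "OXT" = "acceptor")
.PROTEIN_HB_SIDECHAIN <- list(
  SER = c("OG"  = "both"),
  THR = c("OG1" = "both"),
  TYR = c("OH"  = "both"),
  ASN = c("OD1" = "acceptor", "ND2" = "donor"),
  GLN = c("OE1" = "acceptor", "NE2" = "donor"),
  ASP = c("OD1" = "acceptor", "OD2" = "acceptor"),
  GLU = c("OE1" = "acceptor", "OE2" = "acceptor"),
  LYS = c("NZ"  = "donor"),
  ARG = c("NE"  = "donor", "NH1" = "donor", "NH2" = "donor"),
  HIS = c("ND1" = "both", "NE2" = "both"),
  TRP = c("NE1" = "donor"),
  CYS = c("SG"  = "both"),
  MET = c("SD"  = "acceptor"))

## Residue chemical classes used by the interaction profile.
.RESIDUE_CLASS <- c(
  ASP = "charged", GLU = "charged", LYS = "charged", ARG = "charged",
  HIS = "charged",
  ALA = "hydrophobic", VAL = "hydrophobic", LEU = "hydrophobic",
  ILE = "hydrophobic", MET = "hydrophobic", PHE = "hydrophobic",
  TRP = "hydrophobic", CYS = "hydrophobic",
  SER = "polar", THR = "polar", ASN = "polar", GLN = "polar",
  TYR = "polar", GLY = "polar", PRO = "polar")

.hb_compatible <- function(lig_role, prot_role) {
  (lig_role %in% c("donor", "both") & prot_role %in% c("acceptor", "both")) |
  (lig_role %in% c("acceptor", "both") & prot_role %in% c("donor", "both"))
}

#' Ligand-protein hydrogen bonds
#'
#' Geometric heavy-atom hydrogen-bond detection: every (polar ligand
#' atom, polar protein atom) pair within the distance cutoff where one
#' partner can donate and the other accept, per fixed donor/acceptor
#' tables (no angle term; hydrogens are ignored throughout).  Carbon
#' atoms never participate; the ligand SD sulfur is excluded.
#'
#' @param lig A [LigandInstance-class].
#' @param s The [PdbStructure-class] providing the protein atoms.
#' @param cutoff Donor-acceptor distance cutoff, Angstrom (default 3.35).
#' @return data.frame with columns \code{structure_id, ligand_atom,
#'   protein_atom, chain, resno, resname, distance}, sorted by ligand
#'   atom then distance.  Zero rows when no contacts.
#' @examples
#' pocket <- makePocket(makeConformer(),
#'   data.frame(ligand_atom = "N6", restype = "ASP",
#'              protein_atom = "OD1", distance = 2.9))
#' hydrogenBonds(extractLigands(pocket)[[1]], pocket)
#' @export
hydrogenBonds <- function(lig, s, cutoff = 3.35) {
  stopifnot(is(lig, "LigandInstance"), is(s, "PdbStructure"))
  la <- lig@atoms[lig@atoms$name %in% names(.LIGAND_HB_ROLE), , drop = FALSE]
  pa <- proteinAtoms(s)
  pa <- pa[pa$element %in% c("N", "O", "S"), , drop = FALSE]
  empty <- data.frame(structure_id = character(0), ligand_atom = character(0),
                      protein_atom = character(0), chain = character(0),
                      resno = integer(0), resname = character(0),
                      distance = numeric(0), stringsAsFactors = FALSE)
  if (!nrow(la) || !nrow(pa)) return(empty)
  prot_role <- .PROTEIN_HB_BACKBONE[pa$name]
  side <- mapply(function(rn, an) {
    tbl <- .PROTEIN_HB_SIDECHAIN[[rn]]
    if (is.null(tbl)) NA_character_ else unname(tbl[an])
  }, pa$resname, pa$name)
  prot_role[is.na(prot_role)] <- side[is.na(prot_role)]
  keep <- !is.na(prot_role)
  pa <- pa[keep, , drop = FALSE]; prot_role <- prot_role[keep]
  if (!nrow(pa)) return(empty)
  d <- .cdist(as.matrix(la[, c("x", "y", "z")]),
              as.matrix(pa[, c("x", "y", "z")]))
  lig_role <- .LIGAND_HB_ROLE[la$name]
  hit <- which(d <= cutoff &
                 outer(lig_role, prot_role, .hb_compatible),
               arr.ind = TRUE)
  if (!nrow(hit)) return(empty)
  out <- data.frame(structure_id = lig@structureId,
                    ligand_atom = la$name[hit[, 1]],
                    protein_atom = pa$name[hit[, 2]],
                    chain = pa$chain[hit[, 2]],
                    resno = pa$resno[hit[, 2]],
                    resname = pa$resname[hit[, 2]],
                    distance = d[hit],
                    stringsAsFactors = FALSE)
  out <- out[order(out$ligand_atom, out$distance), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Aggregate per-ligand-atom interaction profile
#'
#' Tallies, over a set of contact tables (one per family representative),
#' which residue types contact each ligand atom, and the fraction of
#' charged / hydrophobic / polar contacts per atom.
#'
#' @param contacts A contact data.frame from [hydrogenBonds()], or a list
#'   of them.
#' @return List with \code{counts} (ligand_atom, resname, class, count)
#'   and \code{class_fractions} (ligand_atom, charged, hydrophobic,
#'   polar, n).  Both empty when no contacts.
#' @examples
#' ctc <- data.frame(ligand_atom = c("N6", "N6", "N6"),
#'                   resname = c("ASP", "ASP", "GLN"))
#' interactionProfile(ctc)$class_fractions
#' @export
interactionProfile <- function(contacts) {
  if (is.data.frame(contacts)) contacts <- list(contacts)
  all <- do.call(rbind, lapply(contacts, function(x)
    x[, c("ligand_atom", "resname"), drop = FALSE]))
  if (is.null(all) || !nrow(all)) {
    return(list(counts = data.frame(ligand_atom = character(0),
                                    resname = character(0),
                                    class = character(0),
                                    count = integer(0)),
                class_fractions = data.frame(ligand_atom = character(0),
                                             charged = numeric(0),
                                             hydrophobic = numeric(0),
                                             polar = numeric(0),
                                             n = integer(0))))
  }
  tab <- as.data.frame(table(ligand_atom = all$ligand_atom,
                             resname = all$resname),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0, , drop = FALSE]
  counts <- data.frame(ligand_atom = tab$ligand_atom,
                       resname = tab$resname,
                       class = unname(.RESIDUE_CLASS[tab$resname]),
                       count = tab$Freq, stringsAsFactors = FALSE)
  counts <- counts[order(counts$ligand_atom, -counts$count,
                         counts$resname), , drop = FALSE]
  rownames(counts) <- NULL
  cls <- .RESIDUE_CLASS[all$resname]
  frac <- do.call(rbind, lapply(split(cls, all$ligand_atom), function(v) {
    n <- length(v)
    data.frame(charged = mean(v == "charged", na.rm = TRUE),
               hydrophobic = mean(v == "hydrophobic", na.rm = TRUE),
               polar = mean(v == "polar", na.rm = TRUE), n = n)
  }))
  frac <- data.frame(ligand_atom = rownames(frac), frac,
                     row.names = NULL, stringsAsFactors = FALSE)
  list(counts = counts, class_fractions = frac)
}

#' Write contacts as TSV
#'
#' @param contacts data.frame from [hydrogenBonds()].
#' @param path Output TSV path.
#' @return Invisibly, \code{path}.
#' @export
writeContacts <- function(contacts, path) {
  utils::write.table(contacts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
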