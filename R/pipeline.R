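#' @include AllClasses.R AllGenerics.R structio.R geometry.R superpose.R
#' @include contacts.R topology.R siterules.R
NULL

#' Analysis configuration
#'
#' All thresholds of the pipeline in one place: the mean-B reliability
#' cutoff (Angstrom^2), the hydrogen-bond distance cutoff (Angstrom),
#' the conformation-typing threshold (Angstrom), the conservation mode,
#' and the superposition atom sets (fit on \code{atom_set}, measure the
#' typing RMSD on \code{measure_set}).
#'
#' @param b_factor_cutoff Mean-B reliability cutoff, Angstrom^2.
#' @param hbond_cutoff Hydrogen-bond distance cutoff, Angstrom.
#' @param typing_threshold Conformation-typing cut height, Angstrom.
#' @param conservation_mode "strict" or "conservative".
#' @param atom_set Superposition fitting set ("ribose" or "all").
#' @param measure_set Atom set on which the typing RMSD is measured.
#' @return Named list of parameters.
#' @export
ligfamConfig <- function(b_factor_cutoff = 80, hbond_cutoff = 3.35,
                         typing_threshold = 1.0,
                         conservation_mode = c("strict", "conservative"),
                         atom_set = "ribose", measure_set = "all") {
  list(b_factor_cutoff = b_factor_cutoff, hbond_cutoff = hbond_cutoff,
       typing_threshold = typing_threshold,
       conservation_mode = match.arg(conservation_mode),
       atom_set = atom_set, measure_set = measure_set)
}

#' End-to-end ligand-centric analysis
#'
#' Orchestrates the full pipeline over a set of structures: parse each
#' PDB file, extract SAM/SAH ligand instances, compute pucker and
#' dihedral geometry with B-factor reliability flags, profile
#' ligand-protein hydrogen bonds, classify the beta-sheet topology when
#' a secondary-structure annotation is supplied, and (with at least two
#' unflagged ligands) assign conformation Types across structures.
#' Per-structure failures are logged and skipped; the run fails only
#' when no structure parses.
#'
#' @param paths Character vector of PDB file paths.
#' @param ssa Optional secondary-structure annotations: a list (one
#'   element per structure, NULL allowed) of annotation lists as
#'   returned by [readStrandAnnotation()].
#' @param config Parameter list from [ligfamConfig()].
#' @param codes Ligand HET codes to extract.
#' @return An analysis report: list with \code{ligands} (per-ligand
#'   geometry data.frame), \code{contacts} (named list of contact
#'   tables), \code{topology} (named list of LigFold assignments, absent
#'   when no annotation given), \code{typing}
#'   ([ConformationTyping-class] or NULL), \code{skipped} (data.frame of
#'   skipped entities with reasons) and \code{metadata}.
#' @examples
#' f <- tempfile(fileext = ".pdb")
#' writePDB(ligandToStructure(makeConformer()), f)
#' rep <- analyzeStructures(f)
#' rep$ligands$conformer
#' @export
analyzeStructures <- function(paths, ssa = NULL, config = ligfamConfig(),
                              codes = c("SAM", "SAH")) {
  stopifnot(length(paths) >= 1)
  if (!is.null(ssa) && length(ssa) != length(paths))
    stop("ssa must have one element (possibly NULL) per structure")
  skipped <- list()
  note_skip <- function(what, why) {
    skipped[[length(skipped) + 1L]] <<- data.frame(
      entity = what, reason = why, stringsAsFactors = FALSE)
    message("skipped ", what, ": ", why)
  }
  geo <- list(); contacts <- list(); topo <- list(); ligs <- list()
  for (k in seq_along(paths)) {
    s <- tryCatch(readPDB(paths[k]), error = function(e) {
      note_skip(paths[k], conditionMessage(e)); NULL
    })
    if (is.null(s)) next
    instances <- extractLigands(s, codes)
    if (!length(instances))
      note_skip(structureId(s), "no SAM/SAH ligand present")
    for (lig in instances) {
      id <- paste(lig@structureId, lig@chain, lig@resno, sep = "_")
      geo[[id]] <- ligandGeometry(lig, config$b_factor_cutoff)
      contacts[[id]] <- hydrogenBonds(lig, s, config$hbond_cutoff)
      ligs[[id]] <- lig
    }
    if (!is.null(ssa) && !is.null(ssa[[k]])) {
      topo[[structureId(s)]] <- tryCatch({
        sheet <- buildSheet(ssa[[k]])
        assignLigFold(sheet)
      }, error = function(e) {
        note_skip(paste0(structureId(s), " (topology)"),
                  conditionMessage(e))
        NULL
      })
    }
  }
  if (!length(ligs) && !length(geo))
    stop("no structure could be analysed")
  ligand_table <- do.call(rbind, geo)
  rownames(ligand_table) <- NULL
  typing <- NULL
  unflagged <- Filter(function(l)
    !ligandReliability(l, config$b_factor_cutoff)$flagged &&
      l@complete, ligs)
  if (length(unflagged) >= 2) {
    typing <- tryCatch({
      m <- rmsdMatrix(unname(unflagged), atomSet = config$atom_set,
                      measureSet = config$measure_set,
                      excludeFlagged = FALSE)
      assignTypes(m, config$typing_threshold)
    }, error = function(e) {
      note_skip("conformation typing", conditionMessage(e)); NULL
    })
  } else if (length(ligs) >= 2) {
    note_skip("conformation typing",
              "fewer than 2 unflagged complete ligands")
  }
  out <- list(ligands = ligand_table, contacts = contacts,
              typing = typing,
              skipped = if (length(skipped)) do.call(rbind, skipped) else
                data.frame(entity = character(0), reason = character(0)),
              metadata = list(
                version = as.character(utils::packageVersion("ligfam")),
                parameters = config, n_structures = length(paths)))
  if (length(topo)) out$topology <- topo
  out
}

#' Write an analysis report as JSON (+ optional TSV tables)
#'
#' JSON serialisation is bit-stable for identical input: keys are
#' emitted in a fixed order and no timestamps are recorded.
#'
#' @param report Report from [analyzeStructures()].
#' @param path Output JSON path.
#' @param tsvDir Optional directory for per-table TSV exports
#'   (ligands.tsv, contacts.tsv).
#' @return Invisibly, \code{path}.
#' @export
writeAnalysisReport <- function(report, path, tsvDir = NULL) {
  obj <- list(schema = "ligfam-report/1",
              metadata = report$metadata,
              ligands = report$ligands,
              contacts = report$contacts,
              skipped = report$skipped)
  if (!is.null(report$typing))
    obj$typing <- list(threshold = report$typing@threshold,
                       labels = as.list(typeLabels(report$typing)))
  if (!is.null(report$topology)) obj$topology <- report$topology
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = 6,
                       pretty = TRUE, na = "null")
  if (!is.null(tsvDir)) {
    dir.create(tsvDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(report$ligands, file.path(tsvDir, "ligands.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    ctc <- do.call(rbind, report$contacts)
    if (!is.null(ctc) && nrow(ctc))
      utils::write.table(ctc, file.path(tsvDir, "contacts.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Batch site-rule generation over families
#'
#' Builds one site rule per family from its alignment and representative
#' contact table, writes each rule as JSON plus a summary TSV of rule
#' sizes.  Families without contacts are skipped with a warning.
#'
#' @param families Named list; each element a list with
#'   \code{alignment} (a [FamilyAlignment-class] or aligned-FASTA path)
#'   and \code{contacts} (data.frame with \code{resno}, or a TSV path).
#' @param mode Conservation mode.
#' @param outDir Output directory for rule JSON files and
#'   \code{rules_summary.tsv}; NULL to skip writing.
#' @return Named list of [SiteRule-class] objects (invisible components
#'   skipped families omitted); the summary data.frame is attached as
#'   attribute \code{"summary"}.
#' @export
batchRules <- function(families, mode = c("strict", "conservative"),
                       outDir = NULL) {
  mode <- match.arg(mode)
  rules <- list()
  summary <- list()
  for (nm in names(families)) {
    fam <- families[[nm]]
    aln <- fam$alignment
    if (is.character(aln)) aln <- readFamilyAlignment(aln, familyId = nm)
    ctc <- fam$contacts
    if (is.character(ctc)) ctc <- utils::read.delim(ctc)
    if (is.null(ctc) || !nrow(ctc)) {
      warning("family ", nm, " has no representative contacts: skipped")
      next
    }
    rule <- buildSiteRule(aln, ctc, mode)
    rules[[nm]] <- rule
    summary[[nm]] <- data.frame(family_id = aln@familyId, mode = mode,
                                n_positions = nrow(rule@positions),
                                n_unmapped = length(rule@unmapped),
                                stringsAsFactors = FALSE)
    if (!is.null(outDir)) {
      dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
      writeSiteRule(rule, file.path(outDir, paste0(nm, ".rule.json")))
    }
  }
  summary <- if (length(summary)) do.call(rbind, c(summary,
                                                   make.row.names = FALSE))
    else data.frame(family_id = character(0), mode = character(0),
                    n_positions = integer(0), n_unmapped = integer(0))
  if (!is.null(outDir))
    utils::write.table(summary, file.path(outDir, "rules_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  attr(rules, "summary") <- summary
  rules
}
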