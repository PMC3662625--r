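#' @include AllClasses.R AllGenerics.R
NULL

#' Conservative-substitution groups
#'
#' The Dayhoff-style residue groups used by the "conservative"
#' conservation mode: \{D,E\}, \{K,R\}, \{S,T\}, \{N,Q\}, \{I,L,V,M\},
#' \{F,Y,W\}, \{A,G\}.  Residues outside every group (C, H, P) only
#' match themselves.
#'
#' @return Named list of character vectors.
#' @export
conservationGroups <- function() {
  list(acidic = c("D", "E"), basic = c("K", "R"), hydroxyl = c("S", "T"),
       amide = c("N", "Q"), aliphatic = c("I", "L", "V", "M"),
       aromatic = c("F", "Y", "W"), small = c("A", "G"))
}

.group_of <- function(res, groups = conservationGroups()) {
  for (g in groups) if (res %in% g) return(g)
  res
}

#' Construct a family alignment object
#'
#' @param sequences Named AAStringSet (or named character vector) of
#'   equal-width aligned sequences, gap character "-".
#' @param representativeId Name of the representative (structure-bearing)
#'   row.
#' @param familyId Family identifier.
#' @param firstResno Residue number of the representative's first
#'   residue (default 1).
#' @return A [FamilyAlignment-class].
#' @export
FamilyAlignment <- function(sequences, representativeId,
                            familyId = "FAM1", firstResno = 1L) {
  if (!is(sequences, "AAStringSet"))
    sequences <- Biostrings::AAStringSet(sequences)
  if (is.null(names(sequences)))
    stop("aligned sequences must be named")
  rep_chars <- strsplit(as.character(sequences[[representativeId]]),
                        "")[[1]]
  is_res <- rep_chars != "-"
  columnMap <- rep(NA_integer_, length(rep_chars))
  columnMap[is_res] <- seq_len(sum(is_res)) + as.integer(firstResno) - 1L
  new("FamilyAlignment", familyId = familyId, sequences = sequences,
      representativeId = representativeId, columnMap = columnMap)
}

#' Read an aligned-FASTA family alignment
#'
#' @param path Aligned FASTA file (gap character "-").
#' @param representativeId Name of the representative row; defaults to
#'   the first sequence.
#' @param familyId Family identifier; defaults to the file stem.
#' @param firstResno Residue number of the representative's first residue.
#' @return A [FamilyAlignment-class].
#' @export
readFamilyAlignment <- function(path, representativeId = NULL,
                                familyId = NULL, firstResno = 1L) {
  seqs <- Biostrings::readAAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (is.null(representativeId)) representativeId <- names(seqs)[1]
  if (is.null(familyId))
    familyId <- sub("\\.(fa|fasta|afa|aln)$", "", basename(path),
                    ignore.case = TRUE)
  FamilyAlignment(seqs, representativeId, familyId, firstResno)
}

.aln_matrix <- function(aln) {
  do.call(rbind, strsplit(as.character(aln@sequences), ""))
}

#' Column conservation audit of a family alignment
#'
#' Labels each alignment column \code{strict} (all rows share one
#' residue, no gaps), \code{conservative} (all residues fall within one
#' substitution group; only meaningful in conservative mode) or
#' \code{not_conserved}.  Gaps disqualify a column in either mode.
#'
#' @param aln A [FamilyAlignment-class] (>= 2 sequences).
#' @param mode "strict" or "conservative".
#' @param groups Substitution groups, see [conservationGroups()].
#' @return data.frame with columns \code{column}, \code{resno}
#'   (representative residue number, NA at representative gaps),
#'   \code{residue} (representative residue), \code{status}.
#' @export
conservedColumns <- function(aln, mode = c("strict", "conservative"),
                             groups = conservationGroups()) {
  stopifnot(is(aln, "FamilyAlignment"))
  mode <- match.arg(mode)
  M <- .aln_matrix(aln)
  if (nrow(M) < 2) stop("conservation needs at least 2 sequences")
  rep_row <- M[match(aln@representativeId, names(aln@sequences)), ]
  status <- apply(M, 2, function(col) {
    if (any(col == "-")) return("not_conserved")
    if (length(unique(col)) == 1) return("strict")
    if (mode == "conservative") {
      g <- .group_of(col[1], groups)
      if (all(col %in% g)) return("conservative")
    }
    "not_conserved"
  })
  data.frame(column = seq_len(ncol(M)), resno = aln@columnMap,
             residue = rep_row, status = status,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Build a family site rule from contacts and conservation
#'
#' Intersects the ligand-contacting representative residues with the
#' conserved alignment columns: a position enters the rule only if the
#' representative residue hydrogen-bonds the ligand AND the column is
#' conserved across all family members under the chosen mode.  Contacts
#' whose residue numbers cannot be mapped to an alignment column are
#' reported as unmapped and excluded; an empty rule is allowed (with a
#' warning).
#'
#' @param aln A [FamilyAlignment-class].
#' @param contacts data.frame with a \code{resno} column of
#'   representative residue numbers (e.g. from [hydrogenBonds()] on the
#'   representative structure).
#' @param mode Conservation mode, "strict" or "conservative".
#' @param feature Feature label recorded for each position.
#' @param groups Substitution groups.
#' @return A [SiteRule-class].
#' @export
buildSiteRule <- function(aln, contacts, mode = c("strict", "conservative"),
                          feature = "SAM binding",
                          groups = conservationGroups()) {
  stopifnot(is(aln, "FamilyAlignment"))
  mode <- match.arg(mode)
  resnos <- sort(unique(as.integer(contacts$resno)))
  cons <- conservedColumns(aln, mode, groups)
  unmapped <- resnos[!resnos %in% cons$resno]
  mapped <- cons[match(setdiff(resnos, unmapped), cons$resno), ,
                 drop = FALSE]
  ok_status <- if (mode == "strict") "strict" else
    c("strict", "conservative")
  keep <- mapped[mapped$status %in% ok_status, , drop = FALSE]
  allowed <- vapply(seq_len(nrow(keep)), function(i) {
    if (keep$status[i] == "strict") keep$residue[i]
    else paste(sort(.group_of(keep$residue[i], groups)), collapse = "")
  }, character(1))
  positions <- data.frame(resno = keep$resno, residue = keep$residue,
                          allowed = allowed,
                          feature = rep(feature, length.out = nrow(keep)),
                          stringsAsFactors = FALSE, row.names = NULL)
  if (!nrow(positions))
    warning("empty site rule: no conserved contacting positions for ",
            aln@familyId)
  new("SiteRule", familyId = aln@familyId, mode = mode,
      positions = positions, unmapped = as.integer(unmapped))
}

## Global pairwise alignment of the family representative against a query
## sequence, returning a residue-number map rep_resno -> query position.
.map_to_query <- function(rep_seq, query, firstResno = 1L) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(rep_seq), Biostrings::AAString(query),
    substitutionMatrix = .blosum62(), gapOpening = 10, gapExtension = 1,
    type = "global")
  p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  ip <- cumsum(p != "-")
  is <- cumsum(s != "-")
  keep <- p != "-" & s != "-"
  map <- rep(NA_integer_, nchar(rep_seq))
  map[ip[keep]] <- is[keep]
  names(map) <- seq_along(map) + firstResno - 1L
  map
}

.blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Propagate a site rule to a structure-less sequence
#'
#' Globally aligns the query to the family representative (BLOSUM62,
#' affine gaps: open 10, extend 1), maps every rule position through the
#' alignment and checks the query residue against the allowed set.  The
#' match is positive only when every rule position is present and
#' matches; per-position diagnostics are always returned.
#'
#' @param rule A [SiteRule-class].
#' @param aln The [FamilyAlignment-class] the rule was built from.
#' @param query Unaligned amino-acid sequence (character or AAString).
#' @return List with \code{positive} (logical), \code{annotations}
#'   (data.frame query_pos, residue, feature; empty when negative) and
#'   \code{diagnostics} (per rule position: resno, expected, allowed,
#'   query_pos, found, ok).
#' @export
propagateRule <- function(rule, aln, query) {
  stopifnot(is(rule, "SiteRule"), is(aln, "FamilyAlignment"))
  query <- toupper(as.character(query))
  if (!grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", query))
    stop("query contains non-amino-acid characters")
  rep_seq <- gsub("-", "",
                  as.character(aln@sequences[[aln@representativeId]]))
  firstResno <- min(aln@columnMap, na.rm = TRUE)
  map <- .map_to_query(rep_seq, query, firstResno)
  qchars <- strsplit(query, "")[[1]]
  pos <- rule@positions
  if (!nrow(pos)) {
    return(list(positive = TRUE,
                annotations = data.frame(query_pos = integer(0),
                                         residue = character(0),
                                         feature = character(0)),
                diagnostics = data.frame()))
  }
  qpos <- unname(map[as.character(pos$resno)])
  found <- ifelse(is.na(qpos), NA_character_, qchars[qpos])
  ok <- !is.na(found) &
    mapply(function(f, allowed) f %in% strsplit(allowed, "")[[1]],
           found, pos$allowed)
  diagnostics <- data.frame(resno = pos$resno, expected = pos$residue,
                            allowed = pos$allowed, query_pos = qpos,
                            found = found, ok = ok,
                            stringsAsFactors = FALSE, row.names = NULL)
  positive <- all(ok)
  annotations <- if (positive) {
    data.frame(query_pos = qpos, residue = found,
               feature = pos$feature, stringsAsFactors = FALSE)
  } else {
    data.frame(query_pos = integer(0), residue = character(0),
               feature = character(0))
  }
  list(positive = positive, annotations = annotations,
       diagnostics = diagnostics)
}

#' Write / read a site rule as JSON
#'
#' Versioned JSON schema: \code{schema}, \code{family_id}, \code{mode},
#' \code{positions[]} (resno, residue, allowed, feature),
#' \code{unmapped[]}.
#'
#' @param rule A [SiteRule-class].
#' @param path Output path.
#' @return \code{writeSiteRule}: invisibly, \code{path};
#'   \code{readSiteRule}: a [SiteRule-class].
#' @export
writeSiteRule <- function(rule, path) {
  obj <- list(schema = "ligfam-site-rule/1",
              family_id = rule@familyId, mode = rule@mode,
              positions = rule@positions,
              unmapped = rule@unmapped)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeSiteRule
#' @export
readSiteRule <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pos <- obj$positions
  if (length(pos) == 0)
    pos <- data.frame(resno = integer(0), residue = character(0),
                      allowed = character(0), feature = character(0))
  new("SiteRule", familyId = obj$family_id, mode = obj$mode,
      positions = as.data.frame(pos),
      unmapped = as.integer(obj$unmapped))
}

## ---- Conserved motifs of Rossmann-fold MTases -------------------------

.HYDROPHOBIC_I <- c("L", "V", "I", "Y", "A", "F")    # motif I flank
.HYDROPHOBIC_II <- c("I", "V", "F", "W", "Y")        # motif II flank
.HYDROPHOBIC <- c("A", "V", "L", "I", "M", "F", "W", "C", "Y")
.ACIDIC <- c("D", "E")
.HYDROPHILIC_III <- c("D", "S", "T", "N")

#' Detect Rossmann-fold MTase sequence motifs
#'
#' Scans a sequence for the conserved motifs of fold-type-I
#' (Rossmann-fold) methyltransferases:
#' \itemize{
#'   \item Motif I: glycine-rich core \code{[GA]x[GA]x[GA]} with an
#'     acidic residue (D/E) at -2 from the first G/A and hydrophobic
#'     residues at -3 and -4.
#'   \item Motif II: an acidic residue in the middle of strand II,
#'     preceded by hydrophobic residues at -3 and -4.
#'   \item Motif III: a hydrophilic residue (D/S/T/N) at the strand-III
#'     N-terminus; a C-terminal glycine is recorded when present.
#'   \item Motif IV: an acidic residue near the strand-IV N-terminus
#'     with V/I at +2.
#'   \item Motif V: the helix after strand IV; no residue pattern — it
#'     is reported as a region only.
#'   \item Motif VI: a glycine at the strand-V start with hydrophobic
#'     residues at +2 and +3.
#' }
#' Motifs II-VI require strand annotations; without them they are
#' skipped and listed in the \code{"skipped"} attribute of the result.
#'
#' @param seq Amino-acid sequence (character or AAString), length >= 9.
#' @param strands Optional data.frame of strand elements in N-to-C order
#'   with columns \code{start}, \code{end} (1-based sequence positions);
#'   row k is strand k.
#' @return data.frame with columns \code{motif}, \code{start},
#'   \code{end}, \code{residues}; attribute \code{"skipped"} lists
#'   motifs not evaluated.
#' @examples
#' detectMotifs("WVLEAGAGTGLL")   # motif I hit
#' @export
detectMotifs <- function(seq, strands = NULL) {
  seq <- toupper(as.character(seq))
  if (nchar(seq) < 9) stop("sequence too short for motif detection")
  x <- strsplit(seq, "")[[1]]
  n <- length(x)
  hits <- list()
  add <- function(motif, start, end) {
    hits[[length(hits) + 1L]] <<- data.frame(
      motif = motif, start = start, end = end,
      residues = paste(x[start:end], collapse = ""),
      stringsAsFactors = FALSE)
  }
  ## Motif I: hydrophobic at -4,-3, acidic at -2, [GA]x[GA]x[GA] core
  for (i in seq_len(n - 4)) {
    if (i < 5) next
    core <- x[i:(i + 4)]
    if (core[1] %in% c("G", "A") && core[3] %in% c("G", "A") &&
        core[5] %in% c("G", "A") &&
        x[i - 2] %in% .ACIDIC &&
        x[i - 3] %in% .HYDROPHOBIC_I && x[i - 4] %in% .HYDROPHOBIC_I) {
      add("I", i - 4, i + 4)
    }
  }
  skipped <- character(0)
  if (is.null(strands) || nrow(strands) < 2) {
    skipped <- c("II", "III", "IV", "V", "VI")
    message("strand annotations absent: motifs II-VI skipped")
  } else {
    strand <- function(k) if (k <= nrow(strands))
      strands$start[k]:strands$end[k] else NULL
    ## Motif II: acidic mid-strand-II with hydrophobic at -3, -4
    s2 <- strand(2)
    if (!is.null(s2)) {
      mid <- s2[abs(s2 - stats::median(s2)) <= 1]
      for (i in mid) {
        if (i >= 5 && x[i] %in% .ACIDIC &&
            x[i - 3] %in% .HYDROPHOBIC_II &&
            x[i - 4] %in% .HYDROPHOBIC_II) add("II", i - 4, i)
      }
    } else skipped <- c(skipped, "II")
    ## Motif III: hydrophilic at strand-III N-terminus (+ optional G)
    s3 <- strand(3)
    if (!is.null(s3)) {
      nt <- s3[seq_len(min(2, length(s3)))]
      i <- nt[x[nt] %in% .HYDROPHILIC_III][1]
      if (!is.na(i)) {
        end <- if (x[s3[length(s3)]] == "G") s3[length(s3)] else i
        add("III", i, end)
      }
    } else skipped <- c(skipped, "III")
    ## Motif IV: acidic near strand-IV N-terminus with V/I at +2
    s4 <- strand(4)
    if (!is.null(s4)) {
      nt <- s4[seq_len(min(3, length(s4)))]
      for (i in nt) {
        if (i + 2 <= n && x[i] %in% .ACIDIC && x[i + 2] %in% c("V", "I")) {
          add("IV", i, i + 2)
          break
        }
      }
    } else skipped <- c(skipped, "IV")
    ## Motif V: region between strand IV and strand V, never a match
    s5 <- strand(5)
    if (!is.null(s4) && !is.null(s5) &&
        s5[1] - 1 >= s4[length(s4)] + 1) {
      add("V", s4[length(s4)] + 1, s5[1] - 1)
    } else if (is.null(s5)) skipped <- c(skipped, "V")
    ## Motif VI: G at strand-V start with hydrophobic at +2, +3
    if (!is.null(s5)) {
      i <- s5[1]
      if (i + 3 <= n && x[i] == "G" &&
          x[i + 2] %in% .HYDROPHOBIC && x[i + 3] %in% .HYDROPHOBIC)
        add("VI", i, i + 3)
    } else skipped <- c(skipped, "VI")
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(motif = character(0), start = integer(0), end = integer(0),
               residues = character(0))
  attr(out, "skipped") <- unique(skipped)
  out
}
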