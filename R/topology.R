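#' @include AllClasses.R AllGenerics.R
NULL

#' The packaged LigFold catalog
#'
#' The 14 strand-order arrangements observed within the Rossmann
#' (fold-type I) SAM-dependent methyltransferase fold, each with its
#' LigFold identifier, topology sub-class and the number of PDB
#' structures in which it was observed.  The entry \code{SAM_DM_Il} is
#' the dual-domain combination of the Ia and Ib arrangements (one sheet
#' of each in a single protein).
#'
#' @return data.frame with columns \code{order_string}, \code{ligfold},
#'   \code{subclass}, \code{n_structures}.
#' @examples
#' ligFoldCatalog()
#' @export
ligFoldCatalog <- function() {
  data.frame(
    order_string = c("3214567", "6754123", "32145", "54123", "564312",
                     "654321", "1762354", "7645321", "7654123",
                     "17865234", "5671432", "6754123/3214567",
                     "3421567", "34215687"),
    ligfold = paste0("SAM_DM_I", letters[1:14]),
    subclass = paste0("Class I", letters[1:14]),
    n_structures = c(351L, 321L, 2L, 19L, 29L, 2L, 10L, 1L, 12L, 1L, 2L,
                     1L, 1L, 4L),
    stringsAsFactors = FALSE)
}

#' The fold-type registry (I-XVIII)
#'
#' The 18 fold types to which bound SAM/SAH has been observed: 9
#' methyltransferase folds and 9 non-MTase SAM-binding folds.  Fold
#' types I-V carry the classical MTase class names (Rossmann fold,
#' protein MTases, tetrapyrrole methylases, RNA methylases, SET-domain
#' histone methylases); the remaining MTase classes extend that
#' five-class scheme, and the non-MTase entries (including the
#' author-assigned Helical bundle) carry descriptive reconstructed
#' names.
#'
#' @return data.frame with columns \code{numeral}, \code{name},
#'   \code{is_mtase} (9 TRUE, 9 FALSE).
#' @examples
#' table(foldRegistry()$is_mtase)
#' @export
foldRegistry <- function() {
  data.frame(
    numeral = c("I", "II", "III", "IV", "V", "VI", "VII", "VIII", "IX",
                "X", "XI", "XII", "XIII", "XIV", "XV", "XVI", "XVII",
                "XVIII"),
    name = c("Rossmann fold (SAM-dependent MTase)",
             "Protein MTase fold (class II)",
             "Tetrapyrrole methylase fold (class III)",
             "RNA methylase fold (class IV)",
             "SET-domain histone MTase fold (class V)",
             "MTase fold, extended class VI",
             "MTase fold, extended class VII",
             "MTase fold, extended class VIII",
             "MTase fold, extended class IX",
             "Helical bundle",
             "Non-MTase SAM-binding fold XI",
             "Non-MTase SAM-binding fold XII",
             "Non-MTase SAM-binding fold XIII",
             "Non-MTase SAM-binding fold XIV",
             "Non-MTase SAM-binding fold XV",
             "Non-MTase SAM-binding fold XVI",
             "Non-MTase SAM-binding fold XVII",
             "Non-MTase SAM-binding fold XVIII"),
    is_mtase = c(rep(TRUE, 9), rep(FALSE, 9)),
    stringsAsFactors = FALSE)
}

#' Read a strand/ladder secondary-structure annotation
#'
#' Secondary structure is an input, not computed internally.  Two
#' formats are supported: a sidecar TSV pair (a strand table with
#' columns \code{chain, start, end, type, sheet_id} plus a ladder table
#' with columns \code{strand_i, strand_j, orientation}), or a classic
#' DSSP file, from which strands (consecutive 'E' summary states),
#' sheets and ladder partners (BP1/BP2; lowercase ladder letter =
#' parallel, uppercase = antiparallel) are extracted.
#'
#' @param path Strand TSV or DSSP file.
#' @param ladderPath Ladder TSV (required for TSV input).
#' @param format "tsv" or "dssp" (guessed from the file when missing).
#' @return List with data.frames \code{strands} (chain, start, end,
#'   type, sheet_id; rows ordered N-to-C) and \code{ladders} (strand_i,
#'   strand_j, orientation), where strand indices refer to the N-to-C
#'   order of the strand table.
#' @export
readStrandAnnotation <- function(path, ladderPath = NULL,
                                 format = c("auto", "tsv", "dssp")) {
  format <- match.arg(format)
  if (format == "auto") {
    head1 <- readLines(path, n = 5, warn = FALSE)
    format <- if (any(grepl("DSSP", head1, fixed = TRUE))) "dssp" else "tsv"
  }
  if (format == "tsv") {
    strands <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("chain", "start", "end", "type")
    if (!all(need %in% names(strands)))
      stop("strand TSV must have columns: ", paste(need, collapse = ", "))
    if (is.null(strands$sheet_id)) strands$sheet_id <- "A"
    if (is.null(ladderPath))
      stop("TSV strand annotation requires a ladder table (ladderPath)")
    ladders <- utils::read.delim(ladderPath, stringsAsFactors = FALSE)
    if (!all(c("strand_i", "strand_j", "orientation") %in% names(ladders)))
      stop("ladder TSV must have columns strand_i, strand_j, orientation")
  } else {
    parsed <- .read_dssp(path)
    strands <- parsed$strands
    ladders <- parsed$ladders
  }
  strands <- strands[order(strands$chain, strands$start), , drop = FALSE]
  rownames(strands) <- NULL
  if (any(strands$type == "strand")) {
    st <- strands[strands$type == "strand", , drop = FALSE]
    overl <- any(vapply(unique(st$chain), function(ch) {
      s <- st[st$chain == ch, , drop = FALSE]
      s <- s[order(s$start), , drop = FALSE]
      nrow(s) > 1 && any(s$start[-1] <= s$end[-nrow(s)])
    }, logical(1)))
    if (overl) stop("strand residue ranges overlap within a chain")
  }
  list(strands = strands, ladders = ladders)
}

## Minimal classic-DSSP reader: residue table columns, summary SS at
## column 17, ladder letters at 24-25, BP1/BP2 at 26-29/30-33, sheet
## label at 34.
.read_dssp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^  #  RESIDUE", lines)
  if (!length(hdr)) stop("not a DSSP file (no residue table header): ", path)
  body <- lines[(hdr[1] + 1):length(lines)]
  body <- body[nchar(body) >= 34]
  aa <- substr(body, 14, 14)
  body <- body[aa != "!"]                      # chain breaks
  seqno <- as.integer(substr(body, 1, 5))      # DSSP running number
  resno <- as.integer(substr(body, 6, 10))
  chain <- trimws(substr(body, 12, 12))
  ss <- substr(body, 17, 17)
  lad1 <- substr(body, 24, 24)
  lad2 <- substr(body, 25, 25)
  bp1 <- as.integer(substr(body, 26, 29))
  bp2 <- as.integer(substr(body, 30, 33))
  sheet <- trimws(substr(body, 34, 34))
  is_e <- ss == "E"
  if (!any(is_e))
    return(list(strands = data.frame(chain = character(0), start = integer(0),
                                     end = integer(0), type = character(0),
                                     sheet_id = character(0)),
                ladders = data.frame(strand_i = integer(0),
                                     strand_j = integer(0),
                                     orientation = character(0))))
  ## group consecutive E residues (same chain, consecutive seqno)
  grp <- cumsum(!is_e | c(TRUE, diff(seqno) != 1 |
                            chain[-1] != chain[-length(chain)]))
  strand_of <- rep(NA_integer_, length(body))
  strands <- list()
  k <- 0L
  for (g in unique(grp[is_e])) {
    ix <- which(grp == g & is_e)
    if (!length(ix)) next
    k <- k + 1L
    strand_of[ix] <- k
    strands[[k]] <- data.frame(chain = chain[ix[1]],
                               start = min(resno[ix]), end = max(resno[ix]),
                               type = "strand",
                               sheet_id = sheet[ix[1]],
                               stringsAsFactors = FALSE)
  }
  strands <- do.call(rbind, strands)
  ## map DSSP running numbers to strand index for bridge partners
  seq2strand <- strand_of[match(seq_along(body), seq_along(body))]
  names(seq2strand) <- seqno
  pairs <- list()
  add_pair <- function(i, bp, lad) {
    if (is.na(bp) || bp == 0) return()
    si <- strand_of[i]
    sj <- seq2strand[as.character(bp)]
    if (is.na(si) || is.na(sj) || si == sj) return()
    ori <- if (lad %in% letters) "parallel" else "antiparallel"
    pairs[[length(pairs) + 1L]] <<- data.frame(
      strand_i = min(si, sj), strand_j = max(si, sj), orientation = ori,
      stringsAsFactors = FALSE)
  }
  for (i in which(is_e)) {
    add_pair(i, bp1[i], lad1[i])
    add_pair(i, bp2[i], lad2[i])
  }
  ladders <- unique(do.call(rbind, pairs))
  if (is.null(ladders))
    ladders <- data.frame(strand_i = integer(0), strand_j = integer(0),
                          orientation = character(0))
  rownames(ladders) <- NULL
  list(strands = strands, ladders = ladders)
}

#' Build the beta-sheet strand-order topology
#'
#' Numbers the strands 1..n by N-to-C sequence position, assembles the
#' ladder (strand adjacency) graph, linearises it into a path and emits
#' the left-to-right strand-order string.  A linearised sheet can be
#' read in two directions; the canonical reading is chosen by catalog
#' lookup (if exactly one reading matches the packaged LigFold catalog
#' it is used), falling back to the reading whose first strand has the
#' lower N-to-C number, with the ambiguity recorded.
#'
#' Cyclic ladder graphs (beta-barrels) and branched sheets are rejected;
#' a disconnected ladder graph is reduced to its largest component with
#' a warning.
#'
#' @param ssa Annotation list from [readStrandAnnotation()] (elements
#'   \code{strands}, \code{ladders}).
#' @param catalog Catalog used for canonical-orientation lookup.
#' @return A [SheetTopology-class].
#' @examples
#' ssa <- list(
#'   strands = data.frame(chain = "A", start = seq(10, 70, 10),
#'                        end = seq(14, 74, 10), type = "strand",
#'                        sheet_id = "A"),
#'   ladders = data.frame(strand_i = c(3, 2, 1, 4, 5, 6),
#'                        strand_j = c(2, 1, 4, 5, 6, 7),
#'                        orientation = c(rep("parallel", 5),
#'                                        "antiparallel")))
#' orderString(buildSheet(ssa))  # "3214567"
#' @export
buildSheet <- function(ssa, catalog = ligFoldCatalog()) {
  strands <- ssa$strands[ssa$strands$type == "strand", , drop = FALSE]
  n <- nrow(strands)
  if (n < 1) stop("annotation contains no strands")
  strands <- strands[order(strands$chain, strands$start), , drop = FALSE]
  strands$id <- seq_len(n)
  ladders <- ssa$ladders
  if (nrow(ladders)) {
    bad <- !(ladders$strand_i %in% strands$id &
               ladders$strand_j %in% strands$id)
    if (any(bad)) stop("ladder pairs reference undeclared strands")
  }
  ## adjacency over declared strands
  adj <- vector("list", n)
  ori <- list()
  for (r in seq_len(nrow(ladders))) {
    i <- ladders$strand_i[r]; j <- ladders$strand_j[r]
    adj[[i]] <- union(adj[[i]], j)
    adj[[j]] <- union(adj[[j]], i)
    ori[[paste(min(i, j), max(i, j))]] <- ladders$orientation[r]
  }
  ## connected components
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (v in seq_len(n)) {
    if (!is.na(comp[v])) next
    cid <- cid + 1L
    queue <- v
    while (length(queue)) {
      u <- queue[[1]]; queue <- queue[-1]
      if (!is.na(comp[u])) next
      comp[u] <- cid
      queue <- c(queue, setdiff(adj[[u]], which(!is.na(comp))))
    }
  }
  sizes <- tabulate(comp)
  use <- which.max(sizes)
  if (cid > 1L)
    warning("disconnected ladder graph: using the largest sheet (",
            sizes[use], " of ", n, " strands)")
  core <- which(comp == use)
  m <- length(core)
  deg <- vapply(core, function(v) length(intersect(adj[[v]], core)),
                integer(1))
  n_edges <- sum(deg) / 2
  if (any(deg > 2))
    stop("branched sheet (a strand has more than two ladder partners): ",
         "not supported")
  if (m > 1 && n_edges >= m)
    stop("cyclic ladder graph: beta-barrels are not supported")
  ## linearise from an endpoint
  if (m == 1) {
    path <- core
  } else {
    start <- core[which(deg == 1)][1]
    path <- start
    prev <- -1L
    repeat {
      nxt <- setdiff(intersect(adj[[path[length(path)]]], core), prev)
      if (!length(nxt)) break
      prev <- path[length(path)]
      path <- c(path, nxt[1])
    }
  }
  ## renumber strands 1..m within the core by N-to-C order
  renum <- match(path, sort(core))
  fwd <- paste(renum, collapse = "")
  rev_ <- paste(rev(renum), collapse = "")
  in_cat <- c(fwd, rev_) %in% catalog$order_string
  ambiguous <- FALSE
  if (xor(in_cat[1], in_cat[2])) {
    chosen <- if (in_cat[1]) fwd else rev_
  } else {
    ambiguous <- all(in_cat)    # both match (or neither: fall through)
    chosen <- if (renum[1] <= renum[length(renum)]) fwd else rev_
  }
  ## orientation bookkeeping: two-colour the path by ladder orientation
  rel <- logical(m)             # TRUE = flipped w.r.t. path[1]
  for (k in seq_len(m - 1)) {
    key <- paste(min(path[k], path[k + 1]), max(path[k], path[k + 1]))
    o <- ori[[key]]
    rel[k + 1] <- if (identical(o, "antiparallel")) !rel[k] else rel[k]
  }
  minority <- if (sum(rel) * 2 > m) !rel else rel
  anti <- sort(renum[minority])
  new("SheetTopology", nCore = as.integer(m), orderString = chosen,
      strands = strands[core, c("id", "chain", "start", "end"),
                        drop = FALSE],
      antiparallel = as.integer(anti),
      readings = c(fwd, rev_), ambiguous = ambiguous)
}

#' Assign a LigFold label to a sheet topology
#'
#' Exact-match lookup of the strand-order string in the LigFold catalog.
#' Unmatched topologies are flagged NOVEL, with the nearest catalog
#' entries by string edit distance reported.
#'
#' @param topo A [SheetTopology-class] (or an order string).
#' @param catalog Catalog data.frame, defaults to [ligFoldCatalog()].
#' @return List with \code{order_string}, \code{novel}, and either
#'   \code{ligfold}/\code{subclass} or \code{nearest} (character vector
#'   of closest catalog entries).
#' @examples
#' assignLigFold("3214567")$ligfold   # SAM_DM_Ia
#' assignLigFold("2134567")$novel     # TRUE
#' @export
assignLigFold <- function(topo, catalog = ligFoldCatalog()) {
  os <- if (is(topo, "SheetTopology")) topo@orderString else
    as.character(topo)
  hit <- match(os, catalog$order_string)
  if (!is.na(hit)) {
    return(list(order_string = os, novel = FALSE,
                ligfold = catalog$ligfold[hit],
                subclass = catalog$subclass[hit]))
  }
  d <- utils::adist(os, catalog$order_string)[1, ]
  nearest <- catalog$order_string[d == min(d)]
  list(order_string = os, novel = TRUE, nearest = nearest,
       min_edit_distance = min(d))
}

#' Per-domain LigFold assignment for multi-sheet structures
#'
#' Assigns each sheet independently and, for multi-domain structures,
#' looks the joined order strings up in the catalog (in both orders) so
#' that the dual Ia+Ib arrangement resolves to its combined catalog
#' entry (SAM_DM_Il).
#'
#' @param sheets List of [SheetTopology-class] (or order strings).
#' @param catalog Catalog data.frame.
#' @return List with \code{domains} (per-sheet [assignLigFold()]
#'   results) and \code{summary} (structure-level label, or "NOVEL").
#' @examples
#' dualDomainScan(list("3214567", "6754123"))$summary  # SAM_DM_Il
#' @export
dualDomainScan <- function(sheets, catalog = ligFoldCatalog()) {
  stopifnot(length(sheets) >= 1)
  domains <- lapply(sheets, assignLigFold, catalog = catalog)
  os <- vapply(domains, `[[`, "", "order_string")
  summary <- NULL
  if (length(os) > 1) {
    for (perm in list(os, rev(os))) {
      key <- paste(perm, collapse = "/")
      hit <- match(key, catalog$order_string)
      if (!is.na(hit)) { summary <- catalog$ligfold[hit]; break }
    }
  }
  if (is.null(summary)) {
    if (all(!vapply(domains, `[[`, TRUE, "novel"))) {
      summary <- paste(vapply(domains, `[[`, "", "ligfold"),
                       collapse = " + ")
    } else {
      summary <- "NOVEL"
    }
  }
  list(domains = domains, summary = summary)
}
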