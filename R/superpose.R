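#' @include AllClasses.R AllGenerics.R structio.R geometry.R
NULL

#' Kabsch least-squares rigid-body superposition
#'
#' Finds the proper rotation (det = +1, reflections forbidden) and
#' translation minimising the RMSD between paired coordinate sets, via
#' the SVD of the cross-covariance matrix.  The fitted mobile set is
#' \code{sweep(mobile, 2, cm) \%*\% R + rep(ct, each = n)} where cm/ct are
#' the centroids.
#'
#' @param mobile,target Numeric n x 3 matrices of paired coordinates
#'   (row i of mobile corresponds to row i of target).
#' @return List with \code{rotation} (3 x 3, det +1), \code{translation}
#'   (target centroid minus rotated mobile centroid), \code{rmsd}
#'   (Angstrom), \code{n_atoms}, and \code{fitted} (transformed mobile
#'   coordinates).
#' @examples
#' m <- makeRibose(18, 40)
#' kabsch(m, m)$rmsd  # 0
#' @export
kabsch <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (!all(dim(mobile) == dim(target)) || ncol(mobile) != 3)
    stop("mobile and target must be matching n x 3 matrices")
  n <- nrow(mobile)
  if (n < 3) stop("degenerate fit: need at least 3 atom pairs")
  cm <- colMeans(mobile); ct <- colMeans(target)
  A <- sweep(mobile, 2, cm); B <- sweep(target, 2, ct)
  if (qr(A)$rank < 2 || qr(B)$rank < 2)
    stop("degenerate fit: collinear coordinates")
  H <- crossprod(A, B)                     # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  R <- t(R)                                # row-vector convention: A %*% R
  fitted <- A %*% R
  rmsd <- sqrt(mean(rowSums((fitted - B)^2)))
  list(rotation = R, translation = ct - as.vector(cm %*% R), rmsd = rmsd,
       n_atoms = n, fitted = sweep(fitted, 2, ct, "+"))
}

#' Pair matching atoms of two ligands
#'
#' Builds the ordered coordinate pairs used for superposition.
#' \code{atomSet = "ribose"} uses the five ring atoms C1', C2', C3', C4',
#' O4'; \code{"all"} uses the intersection of shared heavy-atom names (so
#' a SAM vs SAH pair drops the S-methyl CE); a character vector selects
#' named atoms explicitly.
#'
#' @param a,b [LigandInstance-class] objects.
#' @param atomSet "ribose", "all", or explicit atom names.
#' @return List with matrices \code{a}, \code{b} (rownames = atom names)
#'   and \code{dropped} (atom names present in only one ligand).
#' @export
pairAtoms <- function(a, b, atomSet = c("ribose", "all")) {
  stopifnot(is(a, "LigandInstance"), is(b, "LigandInstance"))
  if (is.character(atomSet) && length(atomSet) == 1 &&
      atomSet %in% c("ribose", "all")) {
    atomSet <- match.arg(atomSet)
  }
  ca <- .coords(a); cb <- .coords(b)
  if (identical(atomSet, "ribose")) {
    want <- .RIBOSE_RING
    miss <- c(setdiff(want, rownames(ca)), setdiff(want, rownames(cb)))
    if (length(miss))
      stop("pairing error: incomplete ribose ring (missing ",
           paste(unique(miss), collapse = ", "), ")")
    shared <- want
  } else if (identical(atomSet, "all")) {
    shared <- intersect(rownames(ca), rownames(cb))
  } else {
    shared <- intersect(atomSet, intersect(rownames(ca), rownames(cb)))
  }
  if (length(shared) < 3)
    stop("pairing error: fewer than 3 shared atoms")
  dropped <- setdiff(union(rownames(ca), rownames(cb)), shared)
  list(a = ca[shared, , drop = FALSE], b = cb[shared, , drop = FALSE],
       dropped = dropped)
}

#' Superpose one ligand onto another
#'
#' Convenience wrapper: pairs atoms with [pairAtoms()] and fits with
#' [kabsch()].
#'
#' @inheritParams pairAtoms
#' @param measureSet Optional second atom set on which the RMSD is
#'   evaluated after fitting on \code{atomSet} (e.g. fit the ribose,
#'   measure over all shared atoms).
#' @return The [kabsch()] result, augmented with \code{atom_set} and,
#'   when \code{measureSet} is given, \code{rmsd_measured} and
#'   \code{n_measured}.
#' @export
superposeLigands <- function(a, b, atomSet = "ribose", measureSet = NULL) {
  pr <- pairAtoms(a, b, atomSet)
  fit <- kabsch(pr$a, pr$b)
  fit$atom_set <- if (is.character(atomSet) && length(atomSet) == 1)
    atomSet else "custom"
  if (!is.null(measureSet)) {
    pm <- pairAtoms(a, b, measureSet)
    moved <- sweep(pm$a %*% fit$rotation, 2, fit$translation, "+")
    fit$rmsd_measured <- sqrt(mean(rowSums((moved - pm$b)^2)))
    fit$n_measured <- nrow(pm$a)
  }
  fit
}

.ligand_ids <- function(ligands) {
  ids <- vapply(ligands, function(l)
    paste(l@structureId, l@chain, l@resno, sep = "_"), character(1))
  if (anyDuplicated(ids)) ids <- make.unique(ids, sep = "#")
  ids
}

#' All-vs-all ligand RMSD matrix
#'
#' Pairwise superposition of every ligand pair on \code{atomSet}, with
#' the RMSD evaluated on \code{measureSet} (by default the fitting set
#' itself).  Ligands flagged by the mean-B policy are excluded when
#' \code{excludeFlagged} (the flagged ids are recorded in the
#' \code{"excluded"} attribute); pairs that cannot be paired are masked
#' as NA with a warning.
#'
#' @param ligands List of [LigandInstance-class] objects (>= 2 after
#'   exclusion).
#' @param atomSet Atom set for the fit ("ribose", "all", or names).
#' @param measureSet Atom set on which the RMSD is evaluated; defaults to
#'   \code{atomSet}.
#' @param excludeFlagged Drop ligands with mean B above \code{bCutoff}.
#' @param bCutoff Mean-B cutoff, Angstrom^2.
#' @return Symmetric numeric matrix (Angstrom) with ligand ids as
#'   dimnames.
#' @examples
#' ligs <- lapply(c(10, 15, 160), function(p) makeConformer(P = p))
#' rmsdMatrix(ligs, atomSet = "all")
#' @export
rmsdMatrix <- function(ligands, atomSet = "ribose", measureSet = atomSet,
                       excludeFlagged = TRUE, bCutoff = 80) {
  stopifnot(is.list(ligands))
  excluded <- character(0)
  if (excludeFlagged) {
    flag <- vapply(ligands, function(l) ligandReliability(l, bCutoff)$flagged,
                   logical(1))
    excluded <- .ligand_ids(ligands)[flag]
    ligands <- ligands[!flag]
  }
  n <- length(ligands)
  if (n < 2) stop("need at least 2 (unflagged) ligands")
  ids <- .ligand_ids(ligands)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  masked <- FALSE
  same_set <- identical(atomSet, measureSet)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    v <- tryCatch({
      fit <- superposeLigands(ligands[[i]], ligands[[j]], atomSet,
                              measureSet = if (same_set) NULL else measureSet)
      if (same_set) fit$rmsd else fit$rmsd_measured
    }, error = function(e) { masked <<- TRUE; NA_real_ })
    m[i, j] <- m[j, i] <- v
  }
  if (masked)
    warning("some ligand pairs could not be superposed; cells masked as NA")
  attr(m, "atom_set") <- atomSet
  attr(m, "measure_set") <- measureSet
  attr(m, "excluded") <- excluded
  m
}

#' RMSD of each ligand to a fixed target
#'
#' Target-based variant of [rmsdMatrix()]: every ligand is superposed
#' onto one reference ligand.
#'
#' @inheritParams rmsdMatrix
#' @param target A [LigandInstance-class] reference.
#' @return Named numeric vector of RMSDs, Angstrom.
#' @export
rmsdToTarget <- function(ligands, target, atomSet = "ribose",
                         measureSet = atomSet) {
  stopifnot(is.list(ligands), is(target, "LigandInstance"))
  same_set <- identical(atomSet, measureSet)
  out <- vapply(ligands, function(l) {
    fit <- superposeLigands(l, target, atomSet,
                            measureSet = if (same_set) NULL else measureSet)
    if (same_set) fit$rmsd else fit$rmsd_measured
  }, numeric(1))
  names(out) <- .ligand_ids(ligands)
  out
}

#' Cluster an RMSD matrix into conformation Types
#'
#' Complete-linkage agglomerative clustering of the ligand RMSD matrix,
#' cut at a distance threshold.  Clusters become "Type 1", "Type 2", ...
#' ordered by decreasing size, ties broken by the lexicographically
#' smallest member id — so labels are deterministic for identical input.
#'
#' @param m Symmetric RMSD matrix (no NA cells) as from [rmsdMatrix()].
#' @param threshold Cut height, Angstrom (default 1.0).
#' @return A [ConformationTyping-class].
#' @examples
#' ligs <- lapply(c(10, 12, 160), function(p) makeConformer(P = p))
#' m <- rmsdMatrix(ligs, atomSet = "ribose", measureSet = "all")
#' assignTypes(m, threshold = 1.0)
#' @export
assignTypes <- function(m, threshold = 1.0) {
  m <- as.matrix(m)
  if (anyNA(m))
    stop("RMSD matrix contains masked (NA) cells; ",
         "exclude the offending ligands before typing")
  hc <- stats::hclust(stats::as.dist(m), method = "complete")
  cl <- stats::cutree(hc, h = threshold)
  ids <- rownames(m)
  size <- table(cl)
  first_id <- vapply(split(ids, cl), function(v) min(v), character(1))
  ord <- order(-as.integer(size), first_id)
  rank <- integer(length(size))
  rank[as.integer(names(size))[ord]] <- seq_along(ord)
  labels <- paste("Type", rank[cl])
  names(labels) <- ids
  new("ConformationTyping", matrix = m, threshold = threshold,
      labels = labels)
}

#' Write an RMSD matrix as TSV
#'
#' @param m Matrix from [rmsdMatrix()].
#' @param path Output TSV path (ids as header row and first column).
#' @return Invisibly, \code{path}.
#' @export
writeRMSDMatrix <- function(m, path) {
  df <- data.frame(id = rownames(m), as.data.frame(m, check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
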