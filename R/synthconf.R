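#' @include AllClasses.R AllGenerics.R structio.R geometry.R contacts.R siterules.R
NULL

## ---- idealized internal coordinates ----------------------------------
## Bond lengths/angles follow the idealized small-molecule geometry of
## the SAM component (standard C-C/C-O/C-N/C-S values).

.RING_BONDS <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(5, 1))
.RING_BOND_LEN <- c(1.526, 1.525, 1.523, 1.451, 1.452)

## planar adenine template (x, y in the ring plane): origin N9, +x toward
## C4, C1' side at +y
.ADENINE_XY <- matrix(c(
  1.7251, -1.3359,   # C5
  0.6034, -2.1429,   # N7
 -0.4127, -1.3053,   # C8
  2.1724,  1.0692,   # N3
  3.4655,  0.6829,   # C2
  3.9687, -0.5724,   # N1
  3.1024, -1.6121,   # C6
  3.6215, -2.9005),  # N6
  ncol = 2, byrow = TRUE,
  dimnames = list(c("C5", "N7", "C8", "N3", "C2", "N1", "C6", "N6"),
                  c("x", "y")))

## bond graph of the full SAM heavy-atom topology (SAH = SAM minus CE)
.SAM_BONDS <- rbind(
  c("C1'", "C2'"), c("C2'", "C3'"), c("C3'", "C4'"), c("C4'", "O4'"),
  c("O4'", "C1'"), c("C2'", "O2'"), c("C3'", "O3'"), c("C1'", "N9"),
  c("C4'", "C5'"), c("C5'", "SD"), c("SD", "CG"), c("SD", "CE"),
  c("CG", "CB"), c("CB", "CA"), c("CA", "N"), c("CA", "C"),
  c("C", "O"), c("C", "OXT"),
  c("N9", "C8"), c("N9", "C4"), c("C8", "N7"), c("N7", "C5"),
  c("C5", "C4"), c("C5", "C6"), c("C6", "N6"), c("C6", "N1"),
  c("N1", "C2"), c("C2", "N3"), c("N3", "C4"))

.SAM_ATOM_ORDER <- c("N", "CA", "C", "O", "OXT", "CB", "CG", "SD", "CE",
                     "C5'", "C4'", "O4'", "C3'", "O3'", "C2'", "O2'",
                     "C1'", "N9", "C8", "N7", "C5", "C6", "N6", "N1",
                     "C2", "N3", "C4")

.element_of <- function(name) {
  ifelse(name == "SD", "S", substr(sub("^[0-9]*", "", name), 1, 1))
}

## ---- ribose ring at prescribed pucker --------------------------------

.ring_nu <- function(xyz) {
  rownames(xyz) <- .RIBOSE_RING
  endocyclicTorsions(xyz)
}

.target_nu <- function(P, Vmax) Vmax * cos((P + 144 * ((0:4) - 2)) * .DEG)

## seed geometry: planar regular pentagon with the out-of-plane
## displacement model z_k = A cos(P + 144 k + 54); the 54-degree offset
## aligns the displacement wave with the endocyclic torsion convention.
.seed_ring <- function(P, Vmax) {
  r <- 1.49 / (2 * sin(36 * .DEG))
  th <- (90 + 72 * (0:4)) * .DEG
  z <- 0.0115 * Vmax * cos((P + 144 * (0:4) + 54) * .DEG)
  cbind(r * cos(th), r * sin(th), z)
}

## canonical frame (removes the 6 rigid-body degrees of freedom)
.ring_to_frame <- function(xyz) {
  xyz <- sweep(xyz, 2, xyz[1, ])
  e1 <- .unit(xyz[2, ])
  v <- xyz[3, ] - sum(xyz[3, ] * e1) * e1
  e2 <- .unit(v)
  xyz %*% cbind(e1, e2, .cross(e1, e2))
}
.ring_par <- function(xyz) c(xyz[2, 1], xyz[3, 1:2], t(xyz[4:5, ]))
.ring_from_par <- function(p)
  rbind(c(0, 0, 0), c(p[1], 0, 0), c(p[2], p[3], 0), p[4:6], p[7:9])

#' Generate a ribose ring at a prescribed pucker
#'
#' Builds a closed five-membered ring (atoms C1', C2', C3', C4', O4')
#' whose endocyclic torsions follow the pseudorotation cosine law
#' \eqn{\nu_j = V_{max} \cos(P + 144^\circ (j - 2))} for the requested
#' phase angle and amplitude.  A planar-pentagon seed displaced
#' out-of-plane is refined by constrained least squares against the
#' target torsions and idealized bond lengths.  \code{Vmax = 0} yields a
#' planar ring (pucker undefined downstream).
#'
#' @param P Pseudorotation phase angle, degrees.
#' @param Vmax Puckering amplitude, degrees (0 to 60; >= 1 for a
#'   defined-pucker ring).
#' @param tol Maximum permitted torsion residual, degrees.
#' @return 5 x 3 coordinate matrix with rownames C1', C2', C3', C4',
#'   O4'.
#' @examples
#' pseudorotation(endocyclicTorsions(makeRibose(18, 40)))
#' @export
makeRibose <- function(P, Vmax, tol = 0.5) {
  stopifnot(is.finite(P), is.finite(Vmax), Vmax >= 0, Vmax <= 60)
  if (Vmax < 1e-8) {
    xyz <- .seed_ring(P, 0)
  } else {
    nu_t <- .target_nu(P, Vmax)
    objective <- function(p) {
      xyz <- .ring_from_par(p)
      nu <- .ring_nu(xyz)
      bl <- sqrt(rowSums((xyz[.RING_BONDS[, 1], ] -
                            xyz[.RING_BONDS[, 2], ])^2))
      sum(.angdiff(nu, nu_t)^2) + 200 * sum((bl - .RING_BOND_LEN)^2)
    }
    x0 <- .ring_to_frame(.seed_ring(P, Vmax))
    opt <- stats::nlminb(.ring_par(x0), objective,
                         control = list(iter.max = 2000,
                                        abs.tol = 1e-13, rel.tol = 1e-13))
    xyz <- .ring_from_par(opt$par)
    resid <- max(abs(.angdiff(.ring_nu(xyz), nu_t)))
    if (resid > tol)
      stop(sprintf(
        "ring generation failed for (P = %g, Vmax = %g): torsion residual %.2f deg",
        P, Vmax, resid))
  }
  dimnames(xyz) <- list(.RIBOSE_RING, c("x", "y", "z"))
  xyz
}

## ---- full SAM/SAH conformer -------------------------------------------

## direction of an exocyclic substituent on ring atom `ctr` with ring
## neighbours r1, r2, on the face where the sign of the dot product with
## `up` matches `side`
.exo_dir <- function(ctr, r1, r2, up, side) {
  u1 <- .unit(r1 - ctr); u2 <- .unit(r2 - ctr)
  bis <- .unit(u1 + u2)
  nrm <- .unit(.cross(u1, u2))
  a <- cos(109.5 * .DEG) / sum(bis * u1)
  cc <- sqrt(max(0, 1 - a^2))
  for (s in c(1, -1)) {
    d <- a * bis + s * cc * nrm
    if (sign(sum(d * up)) == side) return(.unit(d))
  }
  .unit(a * bis + cc * nrm)
}

.rotate_about <- function(p, origin, axis, theta) {
  k <- .unit(axis); v <- p - origin
  th <- theta * .DEG
  vrot <- v * cos(th) + .cross(k, v) * sin(th) + k * sum(k * v) * (1 - cos(th))
  origin + vrot
}

.bond_graph_dist <- function(bonds, atoms) {
  n <- length(atoms)
  idx <- stats::setNames(seq_len(n), atoms)
  adj <- vector("list", n)
  for (r in seq_len(nrow(bonds))) {
    i <- unname(idx[bonds[r, 1]]); j <- unname(idx[bonds[r, 2]])
    if (is.na(i) || is.na(j)) next
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  D <- matrix(Inf, n, n, dimnames = list(atoms, atoms))
  for (s in seq_len(n)) {
    D[s, s] <- 0
    frontier <- s; depth <- 0
    while (length(frontier)) {
      depth <- depth + 1
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[D[s, nxt] == Inf]
      D[s, nxt] <- depth
      frontier <- nxt
    }
  }
  D
}

#' Generate a full synthetic SAM/SAH conformer
#'
#' Builds all heavy atoms of a SAM (27 atoms) or SAH (26 atoms, no CE)
#' ligand from internal coordinates: the ribose ring from
#' [makeRibose()], the adenine moiety attached rigidly through the
#' glycosidic torsion chi (C4-N9-C1'-O4'), and the
#' methionine/homocysteine arm through gamma (O3'-C4'-C5'-SD) and delta
#' (C4'-C5'-SD-CG).  The construction is deterministic for a fixed
#' specification; \code{seed} is accepted for interface symmetry with
#' the other generators but no coordinate depends on it.
#'
#' @param P,Vmax Ribose pucker specification (degrees).
#' @param chi,gamma,delta Ligand dihedrals, degrees.
#' @param ligandCode "SAM" or "SAH".
#' @param bFactor B-factor assigned to every atom (scalar or per-atom
#'   vector in output atom order), Angstrom^2.
#' @param structureId,chain,resno Provenance fields of the instance.
#' @param seed Unused for coordinates (determinism contract).
#' @return A [LigandInstance-class].
#' @examples
#' ligandDihedrals(makeConformer(chi = -60, gamma = 75, delta = 180))
#' @export
makeConformer <- function(P = 18, Vmax = 40, chi = -60, gamma = -60,
                          delta = 180, ligandCode = c("SAM", "SAH"),
                          bFactor = 30, structureId = "SYNTH",
                          chain = "A", resno = 401L, seed = 1L) {
  ligandCode <- match.arg(ligandCode)
  pos <- list()
  ring <- makeRibose(P, Vmax)
  for (nm in rownames(ring)) pos[[nm]] <- ring[nm, ]
  up <- .unit(.cross(pos[["C2'"]] - pos[["C1'"]],
                     pos[["O4'"]] - pos[["C1'"]]))
  ## exocyclic substituents: base and C5' on one face, hydroxyls on the
  ## other (beta-furanose arrangement)
  pos[["O2'"]] <- pos[["C2'"]] +
    1.413 * .exo_dir(pos[["C2'"]], pos[["C1'"]], pos[["C3'"]], up, -1)
  pos[["O3'"]] <- pos[["C3'"]] +
    1.423 * .exo_dir(pos[["C3'"]], pos[["C2'"]], pos[["C4'"]], up, -1)
  pos[["N9"]] <- pos[["C1'"]] +
    1.468 * .exo_dir(pos[["C1'"]], pos[["O4'"]], pos[["C2'"]], up, 1)
  pos[["C5'"]] <- pos[["C4'"]] +
    1.508 * .exo_dir(pos[["C4'"]], pos[["C3'"]], pos[["O4'"]], up, 1)
  ## adenine plane through C1'-N9-C4, oriented by chi
  pos[["C4"]] <- .place_atom(pos[["O4'"]], pos[["C1'"]], pos[["N9"]],
                             1.374, 126.6, chi)
  e1 <- .unit(pos[["C4"]] - pos[["N9"]])
  v <- (pos[["C1'"]] - pos[["N9"]])
  e2 <- .unit(v - sum(v * e1) * e1)
  for (nm in rownames(.ADENINE_XY))
    pos[[nm]] <- pos[["N9"]] + .ADENINE_XY[nm, 1] * e1 +
      .ADENINE_XY[nm, 2] * e2
  ## methionine / homocysteine arm
  pos[["SD"]] <- .place_atom(pos[["C3'"]], pos[["C4'"]], pos[["C5'"]],
                             1.810, 109.0, 180)
  g_now <- .dihedral(pos[["O3'"]], pos[["C4'"]], pos[["C5'"]], pos[["SD"]])
  for (sgn in c(1, -1)) {
    cand <- .rotate_about(pos[["SD"]], pos[["C5'"]],
                          pos[["C5'"]] - pos[["C4'"]],
                          sgn * .angdiff(gamma, g_now))
    if (abs(.angdiff(.dihedral(pos[["O3'"]], pos[["C4'"]], pos[["C5'"]],
                               cand), gamma)) < 1e-6) {
      pos[["SD"]] <- cand
      break
    }
  }
  pos[["CG"]] <- .place_atom(pos[["C4'"]], pos[["C5'"]], pos[["SD"]],
                             1.810, 100.5, delta)
  if (ligandCode == "SAM")
    pos[["CE"]] <- .place_atom(pos[["C4'"]], pos[["C5'"]], pos[["SD"]],
                               1.791, 100.5, .wrap180(delta + 120))
  pos[["CB"]] <- .place_atom(pos[["C5'"]], pos[["SD"]], pos[["CG"]],
                             1.520, 112.0, 180)
  pos[["CA"]] <- .place_atom(pos[["SD"]], pos[["CG"]], pos[["CB"]],
                             1.530, 112.5, 180)
  pos[["N"]] <- .place_atom(pos[["CG"]], pos[["CB"]], pos[["CA"]],
                            1.489, 110.5, -60)
  pos[["C"]] <- .place_atom(pos[["CG"]], pos[["CB"]], pos[["CA"]],
                            1.522, 110.5, 60)
  pos[["O"]] <- .place_atom(pos[["CB"]], pos[["CA"]], pos[["C"]],
                            1.232, 120.5, -20)
  pos[["OXT"]] <- .place_atom(pos[["CB"]], pos[["CA"]], pos[["C"]],
                              1.250, 118.0, 160)
  atom_names <- if (ligandCode == "SAM") .SAM_ATOM_ORDER else
    setdiff(.SAM_ATOM_ORDER, "CE")
  xyz <- do.call(rbind, pos[atom_names])
  ## clash guard: non-bonded pairs (graph distance >= 3) must stay apart
  D <- .bond_graph_dist(.SAM_BONDS, atom_names)
  E <- .cdist(xyz, xyz)
  bad <- which(D >= 3 & E < 1.8, arr.ind = TRUE)
  bad <- bad[bad[, 1] < bad[, 2], , drop = FALSE]
  if (nrow(bad)) {
    pairs <- apply(bad, 1, function(ix)
      sprintf("%s-%s (%.2f A)", atom_names[ix[1]], atom_names[ix[2]],
              E[ix[1], ix[2]]))
    stop("steric clash in generated conformer: ",
         paste(pairs, collapse = ", "))
  }
  b <- rep(bFactor, length.out = length(atom_names))
  at <- data.frame(eleno = seq_along(atom_names), name = atom_names,
                   resname = ligandCode, chain = chain,
                   resno = as.integer(resno), insert = "",
                   x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                   occ = 1, b = b, altloc = "", type = "HETATM",
                   element = .element_of(atom_names),
                   stringsAsFactors = FALSE)
  new("LigandInstance", ligandCode = ligandCode,
      structureId = structureId, chain = chain, resno = as.integer(resno),
      atoms = at, complete = TRUE)
}

## ---- toy binding pocket ----------------------------------------------

#' Generate a toy binding pocket around a ligand
#'
#' Places, for each specification row, a one-atom protein residue so
#' that the named protein atom sits at exactly the requested distance
#' from the named ligand atom, along an outward direction chosen so no
#' other polar ligand atom falls within hydrogen-bonding range of it.
#' Optional decoy carbon atoms (which can never hydrogen-bond) are
#' placed at least 5 Angstrom from every ligand atom.
#'
#' @param lig A [LigandInstance-class].
#' @param spec data.frame with columns \code{ligand_atom},
#'   \code{restype} (3-letter residue type), \code{protein_atom},
#'   \code{distance} (Angstrom, > 1.5).  May have zero rows.
#' @param decoys Number of decoy carbon atoms.
#' @param seed RNG seed (affects decoy placement only).
#' @param guard Minimum clearance required between a placed protein atom
#'   and every other polar ligand atom, Angstrom.
#' @return A [PdbStructure-class] containing the protein fragment atoms
#'   (ATOM) and the ligand (HETATM).
#' @examples
#' pocket <- makePocket(makeConformer(),
#'   data.frame(ligand_atom = "N6", restype = "ASP",
#'              protein_atom = "OD1", distance = 2.9))
#' @export
makePocket <- function(lig, spec = NULL, decoys = 0L, seed = 1L,
                       guard = 3.45) {
  stopifnot(is(lig, "LigandInstance"))
  if (is.null(spec))
    spec <- data.frame(ligand_atom = character(0), restype = character(0),
                       protein_atom = character(0), distance = numeric(0))
  if (nrow(spec) && any(spec$distance <= 1.5))
    stop("pocket distances must exceed 1.5 Angstrom")
  lxyz <- .coords(lig)
  miss <- setdiff(spec$ligand_atom, rownames(lxyz))
  if (length(miss))
    stop("ligand atoms not present: ", paste(miss, collapse = ", "))
  centroid <- colMeans(lxyz)
  polar <- lxyz[rownames(lxyz) %in% names(.LIGAND_HB_ROLE), , drop = FALSE]
  ## deterministic direction candidates: outward plus tilted variants
  tilt <- function(d, ax, th) .unit(.rotate_about(d, c(0, 0, 0), ax, th))
  rows <- list()
  for (r in seq_len(nrow(spec))) {
    target <- lxyz[spec$ligand_atom[r], ]
    out <- target - centroid
    if (.norm(out) < 1e-6) out <- c(1, 0, 0)
    out <- .unit(out)
    perp1 <- .unit(.cross(out, if (abs(out[1]) < 0.9) c(1, 0, 0)
                          else c(0, 1, 0)))
    perp2 <- .cross(out, perp1)
    cands <- c(list(out),
               lapply(c(25, -25, 50, -50), function(t) tilt(out, perp1, t)),
               lapply(c(25, -25, 50, -50), function(t) tilt(out, perp2, t)))
    placed <- NULL
    for (d in cands) {
      p <- target + spec$distance[r] * d
      others <- polar[rownames(polar) != spec$ligand_atom[r], ,
                      drop = FALSE]
      if (!nrow(others) ||
          min(.cdist(matrix(p, 1), others)) > guard) {
        placed <- p
        break
      }
    }
    if (is.null(placed))
      stop("geometric infeasibility: cannot place ", spec$protein_atom[r],
           " near ", spec$ligand_atom[r],
           " without contacting other ligand atoms")
    rows[[r]] <- data.frame(name = spec$protein_atom[r],
                            resname = spec$restype[r],
                            resno = 100L + r,
                            x = placed[1], y = placed[2], z = placed[3],
                            stringsAsFactors = FALSE)
  }
  decoy_rows <- list()
  if (decoys > 0) {
    decoy_rows <- .with_seed(seed, {
      out <- list()
      tries <- 0
      while (length(out) < decoys && tries < 10000) {
        tries <- tries + 1
        d <- .unit(stats::rnorm(3))
        p <- centroid + d * stats::runif(1, 7, 12)
        if (min(.cdist(matrix(p, 1), lxyz)) >= 5) {
          out[[length(out) + 1L]] <- data.frame(
            name = "CB", resname = "ALA",
            resno = 200L + length(out),
            x = p[1], y = p[2], z = p[3], stringsAsFactors = FALSE)
        }
      }
      if (length(out) < decoys)
        stop("geometric infeasibility: could not place decoys")
      out
    })
  }
  prot <- do.call(rbind, c(rows, decoy_rows))
  lat <- lig@atoms
  n_prot <- if (is.null(prot)) 0L else nrow(prot)
  if (n_prot) {
    pat <- data.frame(eleno = seq_len(n_prot), name = prot$name,
                      resname = prot$resname, chain = "P",
                      resno = prot$resno, insert = "",
                      x = prot$x, y = prot$y, z = prot$z,
                      occ = 1, b = 20, altloc = "", type = "ATOM",
                      element = .element_of(prot$name),
                      stringsAsFactors = FALSE)
  } else {
    pat <- NULL
  }
  lat$eleno <- n_prot + seq_len(nrow(lat))
  all_at <- rbind(pat, lat)
  rownames(all_at) <- NULL
  new("PdbStructure", structureId = lig@structureId, atoms = all_at,
      nModels = 1L)
}

## ---- toy family alignment --------------------------------------------

.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
           "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Generate a toy family alignment with controlled conservation
#'
#' Builds a gapless alignment of \code{n} members around a random
#' representative sequence, forcing specified columns to be strictly
#' conserved, conservatively substituted (all members within one
#' substitution group, not identical) or explicitly not conserved
#' (members drawn from different groups).  Background columns vary
#' freely.  Reproducible for a fixed seed.
#'
#' @param n Number of members (>= 2).
#' @param repLength Representative sequence length.
#' @param conservedSpec data.frame with columns \code{pos},
#'   \code{residue}, \code{status} in \{"strict", "conservative",
#'   "non_conserved"\}.
#' @param contactPositions Representative residue numbers designated as
#'   ligand contacts (returned as a toy contact table).
#' @param seed RNG seed.
#' @param familyId,representativeId Identifiers.
#' @return List with \code{alignment} (a [FamilyAlignment-class]) and
#'   \code{contacts} (data.frame resno, resname).
#' @examples
#' fam <- makeFamily(4, 50,
#'   data.frame(pos = c(10, 25, 40), residue = c("D", "G", "K"),
#'              status = c("strict", "strict", "non_conserved")),
#'   contactPositions = c(10, 25, 40))
#' @export
makeFamily <- function(n, repLength,
                       conservedSpec = NULL,
                       contactPositions = integer(0), seed = 1L,
                       familyId = "FAM1", representativeId = "REP1") {
  stopifnot(n >= 2, repLength >= 1)
  if (is.null(conservedSpec))
    conservedSpec <- data.frame(pos = integer(0), residue = character(0),
                                status = character(0))
  if (nrow(conservedSpec) &&
      (any(conservedSpec$pos < 1) || any(conservedSpec$pos > repLength)))
    stop("conservedSpec positions out of range 1..", repLength)
  if (any(!conservedSpec$status %in%
            c("strict", "conservative", "non_conserved")))
    stop("conservedSpec status must be strict/conservative/non_conserved")
  if (any(contactPositions < 1 | contactPositions > repLength))
    stop("contactPositions out of range 1..", repLength)
  groups <- conservationGroups()
  alt_pool <- c("D", "K", "F", "P", "H", "S", "L")
  seqs <- .with_seed(seed, {
    rep_seq <- sample(.AA20, repLength, replace = TRUE)
    for (r in seq_len(nrow(conservedSpec))) {
      rs <- conservedSpec$residue[r]
      if (conservedSpec$status[r] == "conservative" &&
          length(.group_of(rs, groups)) < 2)
        stop("residue ", rs, " has no multi-member substitution group")
      rep_seq[conservedSpec$pos[r]] <- rs
    }
    rows <- list(rep_seq)
    for (i in 2:n) {
      s <- rep_seq
      mutate <- stats::runif(repLength) < 0.4
      s[mutate] <- sample(.AA20, sum(mutate), replace = TRUE)
      for (r in seq_len(nrow(conservedSpec))) {
        p <- conservedSpec$pos[r]; rs <- conservedSpec$residue[r]
        s[p] <- switch(conservedSpec$status[r],
          strict = rs,
          conservative = {
            g <- .group_of(rs, groups)
            g[((match(rs, g) + i - 2) %% length(g)) + 1]
          },
          non_conserved = {
            pool <- setdiff(alt_pool, .group_of(rs, groups))
            pool[((i - 2) %% length(pool)) + 1]
          })
      }
      rows[[i]] <- s
    }
    vapply(rows, paste, "", collapse = "")
  })
  names(seqs) <- c(representativeId, paste0("MEM", seq_len(n - 1)))
  aln <- FamilyAlignment(seqs, representativeId, familyId)
  rep_chars <- strsplit(seqs[[1]], "")[[1]]
  contacts <- data.frame(resno = as.integer(contactPositions),
                         resname = rep_chars[contactPositions],
                         stringsAsFactors = FALSE)
  list(alignment = aln, contacts = contacts)
}
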