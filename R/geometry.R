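#' @include AllClasses.R AllGenerics.R structio.R
NULL

## Pseudorotation wheel: envelope conformer names at the odd multiples of
## 18 degrees (sector midpoints).  Nearest-midpoint assignment reproduces
## the conformer vocabulary of the furanose literature (C3'-endo at 18,
## C1'-exo at 126, C2'-endo at 162, ...).
.ENVELOPE_MID <- seq(18, 342, by = 36)
.ENVELOPE_NAME <- c("C3'-endo", "C4'-exo", "O4'-endo", "C1'-exo",
                    "C2'-endo", "C3'-exo", "C4'-endo", "O4'-exo",
                    "C1'-endo", "C2'-exo")

## Endocyclic torsion definitions over the ring C1'-C2'-C3'-C4'-O4'.
.NU_ATOMS <- list(
  nu0 = c("C4'", "O4'", "C1'", "C2'"),
  nu1 = c("O4'", "C1'", "C2'", "C3'"),
  nu2 = c("C1'", "C2'", "C3'", "C4'"),
  nu3 = c("C2'", "C3'", "C4'", "O4'"),
  nu4 = c("C3'", "C4'", "O4'", "C1'"))

#' Signed torsion (dihedral) angle
#'
#' The IUPAC-signed torsion angle defined by four points, in degrees,
#' in (-180, 180].
#'
#' @param a,b,c,d Numeric 3-vectors (Cartesian coordinates, Angstrom).
#' @return Torsion angle in degrees.
#' @examples
#' dihedralAngle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 0, 1)) # -90
#' @export
dihedralAngle <- function(a, b, c, d) {
  .dihedral(as.numeric(a), as.numeric(b), as.numeric(c), as.numeric(d))
}

#' Endocyclic torsions of a ribose ring
#'
#' Computes the five endocyclic torsions nu0..nu4 over the ring
#' C1'-C2'-C3'-C4'-O4':
#' nu0 = C4'-O4'-C1'-C2', nu1 = O4'-C1'-C2'-C3',
#' nu2 = C1'-C2'-C3'-C4', nu3 = C2'-C3'-C4'-O4',
#' nu4 = C3'-C4'-O4'-C1'.
#'
#' @param x A [LigandInstance-class], or a coordinate matrix whose
#'   rownames include the five ring atom names.
#' @return Named numeric(5) of torsions, degrees.
#' @examples
#' ring <- makeRibose(P = 18, Vmax = 40)
#' endocyclicTorsions(ring)
#' @export
endocyclicTorsions <- function(x) {
  m <- if (is.matrix(x)) x else .coords(x)
  miss <- setdiff(.RIBOSE_RING, rownames(m))
  if (length(miss))
    stop("incomplete ribose ring, missing atom(s): ",
         paste(miss, collapse = ", "))
  vapply(.NU_ATOMS, function(nm)
    .dihedral(m[nm[1], ], m[nm[2], ], m[nm[3], ], m[nm[4], ]),
    numeric(1))
}

#' Pseudorotation phase and amplitude
#'
#' Derives the pseudorotation phase angle P and puckering amplitude Vmax
#' from the five endocyclic torsions, using nu2 as the reference torsion:
#' \deqn{\tan P = \frac{(\nu_4 + \nu_1) - (\nu_3 + \nu_0)}
#'   {2 \nu_2 (\sin 36^\circ + \sin 72^\circ)}, \qquad
#'   V_{max} = \nu_2 / \cos P.}
#' The quadrant of P is resolved with \code{atan2} so that Vmax is always
#' non-negative.  Near-planar rings (max |nu| < 1 degree) yield an
#' undefined pucker rather than an error.
#'
#' @param nu Numeric(5) of endocyclic torsions (degrees), in nu0..nu4
#'   order, or an object accepted by [endocyclicTorsions()].
#' @return A [PuckerResult-class].
#' @examples
#' pseudorotation(endocyclicTorsions(makeRibose(18, 40)))
#' @export
pseudorotation <- function(nu) {
  if (!(is.numeric(nu) && length(nu) == 5)) nu <- endocyclicTorsions(nu)
  nu <- as.numeric(nu)
  if (any(!is.finite(nu))) stop("endocyclic torsions must be finite")
  names(nu) <- names(.NU_ATOMS)
  if (max(abs(nu)) < 1) {
    return(new("PuckerResult", nu = nu, P = NA_real_, PSigned = NA_real_,
               Vmax = 0, conformer = "planar", sector = "planar",
               defined = FALSE))
  }
  s <- unname(((nu[5] + nu[2]) - (nu[4] + nu[1])) /
                (2 * (sin(36 * .DEG) + sin(72 * .DEG))))
  P <- atan2(s, nu[3]) / .DEG
  Vmax <- sqrt(s^2 + nu[3]^2)            # == nu2 / cos(P), sign-safe
  P0 <- P %% 360
  new("PuckerResult", nu = nu, P = unname(P0), PSigned = unname(.wrap180(P)),
      Vmax = unname(Vmax), conformer = conformerName(P0),
      sector = wheelSector(P0), defined = TRUE)
}

#' Envelope conformer name from the pseudorotation wheel
#'
#' Assigns the envelope conformer name whose wheel midpoint (odd
#' multiples of 18 degrees) is nearest to P: 18 = C3'-endo,
#' 54 = C4'-exo, 90 = O4'-endo, 126 = C1'-exo, 162 = C2'-endo,
#' 198 = C3'-exo, 234 = C4'-endo, 270 = O4'-exo, 306 = C1'-endo,
#' 342 = C2'-exo.
#'
#' @param P Pseudorotation phase angle(s), degrees (any convention).
#' @return Character vector of conformer names.
#' @examples
#' conformerName(c(18, 126, 162))
#' @export
conformerName <- function(P) {
  vapply(P, function(p) {
    if (is.na(p)) return(NA_character_)
    .ENVELOPE_NAME[which.min(abs(.angdiff(p, .ENVELOPE_MID)))]
  }, character(1))
}

#' Full 20-sector pseudorotation wheel label
#'
#' The 18-degree-sector wheel label: envelope names centred on the odd
#' multiples of 18 degrees, twist labels (between the two flanking
#' envelope forms) centred on the even multiples.
#'
#' @param P Pseudorotation phase angle(s), degrees.
#' @return Character vector of sector labels.
#' @export
wheelSector <- function(P) {
  vapply(P, function(p) {
    if (is.na(p)) return(NA_character_)
    sector <- (round((p %% 360) / 18) %% 20) * 18
    if (sector %% 36 == 18) {
      .ENVELOPE_NAME[match(sector, .ENVELOPE_MID)]
    } else {
      lo <- (sector - 18) %% 360
      hi <- (sector + 18) %% 360
      paste0(.ENVELOPE_NAME[match(lo, .ENVELOPE_MID)], "/",
             .ENVELOPE_NAME[match(hi, .ENVELOPE_MID)], " twist")
    }
  }, character(1))
}

#' Ligand conformation dihedrals chi, gamma, delta
#'
#' The three dihedral angles describing the extended or folded character
#' of a bound SAM/SAH: chi = C4-N9-C1'-O4' (glycosidic orientation),
#' gamma = O3'-C4'-C5'-SD, delta = C4'-C5'-SD-CG (for SAH, CG of the
#' homocysteine arm).  Angles whose atoms are missing are returned as NA
#' rather than raising an error.
#'
#' @param lig A [LigandInstance-class].
#' @return Named list with numeric elements \code{chi}, \code{gamma},
#'   \code{delta} (degrees, NA when undefined).
#' @examples
#' ligandDihedrals(makeConformer(chi = -60, gamma = 75, delta = 180))
#' @export
ligandDihedrals <- function(lig) {
  stopifnot(is(lig, "LigandInstance"))
  m <- .coords(lig)
  ang <- function(nm) {
    if (!all(nm %in% rownames(m))) return(NA_real_)
    .dihedral(m[nm[1], ], m[nm[2], ], m[nm[3], ], m[nm[4], ])
  }
  list(chi = ang(c("C4", "N9", "C1'", "O4'")),
       gamma = ang(c("O3'", "C4'", "C5'", "SD")),
       delta = ang(c("C4'", "C5'", "SD", "CG")))
}

#' Ligand B-factor reliability flag
#'
#' Mean crystallographic temperature factor over the ligand atoms;
#' ligands with mean B strictly greater than the cutoff (default 80
#' Angstrom^2) are flagged as unreliable for conformational analysis.
#'
#' @param lig A [LigandInstance-class].
#' @param cutoff Mean-B threshold, Angstrom^2 (strict inequality).
#' @return List with \code{mean_b} and logical \code{flagged}.
#' @examples
#' ligandReliability(makeConformer(bFactor = 50))$flagged  # FALSE
#' @export
ligandReliability <- function(lig, cutoff = 80) {
  stopifnot(is(lig, "LigandInstance"))
  b <- lig@atoms$b
  if (!length(b)) stop("ligand has no atoms with B-factors")
  mb <- mean(b)
  list(mean_b = mb, flagged = mb > cutoff)
}

#' Per-ligand geometry report row
#'
#' One flat row combining provenance, endocyclic torsions, pseudorotation
#' parameters (both P conventions), conformer name, chi/gamma/delta and
#' the B-factor reliability flag — the unit record of the per-ligand
#' TSV/JSON report.
#'
#' @param lig A [LigandInstance-class].
#' @param bCutoff Mean-B reliability cutoff, Angstrom^2.
#' @return A one-row data.frame.
#' @export
ligandGeometry <- function(lig, bCutoff = 80) {
  stopifnot(is(lig, "LigandInstance"))
  rel <- ligandReliability(lig, bCutoff)
  dih <- ligandDihedrals(lig)
  if (lig@complete) {
    pk <- pseudorotation(endocyclicTorsions(lig))
    nu <- pk@nu
    P <- pk@P; Ps <- pk@PSigned; Vmax <- pk@Vmax; conf <- pk@conformer
  } else {
    nu <- rep(NA_real_, 5)
    P <- Ps <- Vmax <- NA_real_; conf <- NA_character_
  }
  data.frame(structure_id = lig@structureId, chain = lig@chain,
             resno = lig@resno, ligand_code = lig@ligandCode,
             complete = lig@complete,
             nu0 = nu[[1]], nu1 = nu[[2]], nu2 = nu[[3]], nu3 = nu[[4]],
             nu4 = nu[[5]], P = P, P_signed = Ps, Vmax = Vmax,
             conformer = conf, chi = dih$chi, gamma = dih$gamma,
             delta = dih$delta, mean_b = rel$mean_b,
             flagged = rel$flagged, stringsAsFactors = FALSE)
}
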