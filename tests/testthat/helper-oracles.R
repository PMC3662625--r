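## Independent oracles used to cross-check the package implementations.
## These deliberately avoid the code paths they verify.

## Quaternion-eigenvalue (Horn) superposition RMSD: independent of the
## SVD-based Kabsch implementation.
quaternion_rmsd <- function(mobile, target) {
  X <- scale(mobile, scale = FALSE)
  Y <- scale(target, scale = FALSE)
  S <- crossprod(X, Y)
  Sxx <- S[1, 1]; Sxy <- S[1, 2]; Sxz <- S[1, 3]
  Syx <- S[2, 1]; Syy <- S[2, 2]; Syz <- S[2, 3]
  Szx <- S[3, 1]; Szy <- S[3, 2]; Szz <- S[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,       -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  lambda <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(X^2) + sum(Y^2) - 2 * lambda) / nrow(X)
  sqrt(max(0, msd))
}

## Torsion oracle in plain atan2 vector algebra (no shared helpers).
torsion_oracle <- function(a, b, c, d) {
  u1 <- b - a; u2 <- c - b; u3 <- d - c
  cross <- function(p, q) c(p[2] * q[3] - p[3] * q[2],
                            p[3] * q[1] - p[1] * q[3],
                            p[1] * q[2] - p[2] * q[1])
  n1 <- cross(u1, u2); n2 <- cross(u2, u3)
  ## IUPAC sign: positive = clockwise viewed b -> c
  y <- -sum(cross(n1, n2) * u2) / sqrt(sum(u2^2))
  x <- sum(n1 * n2)
  atan2(y, x) * 180 / pi
}

## Convert a strand-order permutation into the ladder-pair table whose
## linearisation must recover it (consecutive elements are neighbours).
perm_to_ladders <- function(perm, orientation = "parallel") {
  data.frame(strand_i = perm[-length(perm)],
             strand_j = perm[-1],
             orientation = orientation,
             stringsAsFactors = FALSE)
}

perm_to_ssa <- function(perm) {
  n <- length(perm)
  list(strands = data.frame(chain = "A",
                            start = seq(10, by = 10, length.out = n),
                            end = seq(14, by = 10, length.out = n),
                            type = "strand", sheet_id = "A",
                            stringsAsFactors = FALSE),
       ladders = perm_to_ladders(perm))
}

## Brute-force conservation audit of an alignment matrix (gaps
## disqualify; conservative = one substitution group holds all rows).
audit_conserved <- function(seqs, positions, mode) {
  M <- do.call(rbind, strsplit(seqs, ""))
  groups <- list(c("D", "E"), c("K", "R"), c("S", "T"), c("N", "Q"),
                 c("I", "L", "V", "M"), c("F", "Y", "W"), c("A", "G"))
  ok <- logical(length(positions))
  for (k in seq_along(positions)) {
    col <- M[, positions[k]]
    if (any(col == "-")) next
    if (length(unique(col)) == 1) { ok[k] <- TRUE; next }
    if (mode == "conservative") {
      for (g in groups) if (all(col %in% g)) { ok[k] <- TRUE; break }
    }
  }
  positions[ok]
}

## Small angular helper for test assertions.
ang_delta <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, abs(d - 360), abs(d))
}

## Hand-rolled fixed-column PDB record writer for parser fixtures.
pdb_line <- function(record, serial, name, altloc, resname, chain, resno,
                     x, y, z, occ = 1, b = 20, element = "") {
  name_fmt <- if (nchar(name) >= 4) substr(name, 1, 4)
    else sprintf(" %-3s", name)
  sprintf("%-6s%5d %4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name_fmt, altloc, resname, chain, resno,
          x, y, z, occ, b, element)
}
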