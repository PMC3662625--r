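test_that("dihedral angles follow the IUPAC sign convention", {
  a <- c(0, 1, 0); b <- c(0, 0, 0); c3 <- c(1, 0, 0)
  expect_equal(dihedralAngle(a, b, c3, c(1, -1, 0)), 180)
  expect_equal(dihedralAngle(a, b, c3, c(1, 1, 0)), 0)
  expect_equal(dihedralAngle(a, b, c3, c(1, 0, 1)), -90)
  ## against an independent atan2 oracle on random quadruples
  set.seed(11)
  for (i in 1:25) {
    p <- matrix(rnorm(12), 4, 3)
    expect_equal(dihedralAngle(p[1, ], p[2, ], p[3, ], p[4, ]),
                 torsion_oracle(p[1, ], p[2, ], p[3, ], p[4, ]),
                 tolerance = 1e-9)
  }
  expect_error(dihedralAngle(a, b, c3, c(2, 0, 0)), "collinear")
})

test_that("endocyclic torsions match the cosine law on generated rings", {
  ## planar pentagon
  nu <- endocyclicTorsions(makeRibose(0, 0))
  expect_true(all(abs(nu) < 1e-6))
  ## the (P = 18, Vmax = 40) reference ring
  nu <- endocyclicTorsions(makeRibose(18, 40))
  expect_equal(unname(nu), c(0.0, -23.5, 38.0, -38.0, 23.5),
               tolerance = 0.5 / 23)  # 0.5 degree absolute
  ## mirror image negates every torsion
  ring <- makeRibose(126, 38)
  mirrored <- ring %*% diag(c(1, 1, -1))
  rownames(mirrored) <- rownames(ring)
  expect_equal(unname(endocyclicTorsions(mirrored)),
               unname(-endocyclicTorsions(ring)), tolerance = 1e-9)
})

test_that("pseudorotation inverts the generating identity", {
  pk <- pseudorotation(c(0.0, -23.5, 38.0, -38.0, 23.5))
  expect_true(pk@defined)
  expect_lt(ang_delta(pk@P, 18), 0.5)
  expect_lt(abs(pk@Vmax - 40), 0.5)
  expect_identical(pk@conformer, "C3'-endo")
  ## planar input
  expect_false(pseudorotation(rep(0, 5))@defined)
  ## nu2 = Vmax cos P identity holds exactly
  expect_lt(abs(pk@nu[[3]] - pk@Vmax * cos(pk@P * pi / 180)), 0.01)
  ## both P conventions agree
  pk2 <- pseudorotation(endocyclicTorsions(makeRibose(342, 30)))
  expect_lt(ang_delta(pk2@P, 342), 1)
  expect_lt(abs(pk2@PSigned - (-18)), 1)
})

test_that("generator-analysis round trip recovers P and Vmax on a coarse wheel", {
  for (P in seq(0, 342, by = 54)) for (V in c(10, 40)) {
    pk <- pseudorotation(endocyclicTorsions(makeRibose(P, V)))
    expect_lt(ang_delta(pk@P, P), 1)
    expect_lt(abs(pk@Vmax - V), 1)
    ## cosine-law residual stays small
    fit <- pk@Vmax * cos((pk@P + 144 * ((0:4) - 2)) * pi / 180)
    expect_lt(sqrt(mean((pk@nu - fit)^2)), 2)
  }
})

test_that("wheel naming assigns the nearest envelope midpoint", {
  expect_identical(conformerName(c(18, 126, 162)),
                   c("C3'-endo", "C1'-exo", "C2'-endo"))
  expect_identical(conformerName(c(20, 124)), c("C3'-endo", "C1'-exo"))
  expect_identical(wheelSector(18), "C3'-endo")
  expect_match(wheelSector(36), "twist")
})

test_that("chi, gamma, delta are recovered from constructed conformers", {
  lig <- makeConformer(chi = -60, gamma = 75, delta = 180)
  d <- ligandDihedrals(lig)
  expect_lt(ang_delta(d$chi, -60), 0.5)
  expect_lt(ang_delta(d$gamma, 75), 0.5)
  expect_lt(ang_delta(d$delta, 180), 0.5)
  ## missing SD leaves gamma/delta undefined but chi intact
  at <- atoms(lig)
  lig2 <- new("LigandInstance", ligandCode = "SAM", structureId = "X",
              chain = "A", resno = 401L, atoms = at[at$name != "SD", ],
              complete = TRUE)
  d2 <- ligandDihedrals(lig2)
  expect_true(is.na(d2$gamma) && is.na(d2$delta))
  expect_false(is.na(d2$chi))
  ## range contract
  for (chi in c(-140, -60, 0, 80)) {
    v <- ligandDihedrals(makeConformer(chi = chi))$chi
    expect_true(v > -180 && v <= 180)
  }
})

test_that("geometry outputs are invariant under rigid motion and flip under mirroring", {
  lig <- makeConformer(P = 100, Vmax = 35, chi = 40, gamma = -50,
                       delta = 120)
  ## rigid motion
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  at <- atoms(lig)
  xyz <- as.matrix(at[, c("x", "y", "z")]) %*% t(R)
  at[, c("x", "y", "z")] <- sweep(xyz, 2, c(5, -3, 11), "+")
  moved <- new("LigandInstance", ligandCode = "SAM", structureId = "X",
               chain = "A", resno = 401L, atoms = at, complete = TRUE)
  pk0 <- pseudorotation(endocyclicTorsions(lig))
  pk1 <- pseudorotation(endocyclicTorsions(moved))
  expect_lt(ang_delta(pk1@P, pk0@P), 1e-6)
  expect_lt(abs(pk1@Vmax - pk0@Vmax), 1e-6)
  d0 <- ligandDihedrals(lig); d1 <- ligandDihedrals(moved)
  expect_equal(unlist(d1), unlist(d0), tolerance = 1e-6)
  ## mirroring negates dihedrals; negating every nu shifts the cosine
  ## phase by half a turn, i.e. P -> P + 180 (C3'-endo <-> C3'-exo)
  at2 <- atoms(lig)
  at2$z <- -at2$z
  mir <- new("LigandInstance", ligandCode = "SAM", structureId = "X",
             chain = "A", resno = 401L, atoms = at2, complete = TRUE)
  pk2 <- pseudorotation(endocyclicTorsions(mir))
  expect_lt(ang_delta(pk2@P, (pk0@P + 180) %% 360), 1e-6)
  expect_lt(abs(pk2@Vmax - pk0@Vmax), 1e-6)
  d2 <- ligandDihedrals(mir)
  expect_equal(unlist(d2), -unlist(d0), tolerance = 1e-6)
})

test_that("the mean-B reliability threshold is strict at 80", {
  mk <- function(b) makeConformer(bFactor = b)
  expect_false(ligandReliability(mk(50))$flagged)
  two <- makeConformer(bFactor = c(rep(79, 13), rep(81, 13), 80))
  r <- ligandReliability(two)
  expect_equal(r$mean_b, 80)
  expect_false(r$flagged)
  expect_true(ligandReliability(mk(80.2))$flagged)
})

test_that("the per-ligand geometry report row is complete", {
  row <- ligandGeometry(makeConformer(P = 126, Vmax = 40))
  expect_identical(row$conformer, "C1'-exo")
  expect_true(all(c("nu0", "P", "P_signed", "Vmax", "chi", "gamma",
                    "delta", "mean_b", "flagged") %in% names(row)))
})
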