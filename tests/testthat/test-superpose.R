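test_that("kabsch recovers exact rigid motions", {
  m <- makeRibose(18, 40)
  fit0 <- kabsch(m, m)
  expect_equal(fit0$rmsd, 0, tolerance = 1e-9)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-9,
               ignore_attr = TRUE)
  ## 90-degree rotation about z plus translation
  R <- rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 1))
  moved <- sweep(m %*% t(R), 2, c(5, 0, 0), "+")
  fit <- kabsch(moved, m)
  expect_lt(fit$rmsd, 1e-9)
  expect_equal(fit$rotation %*% t(fit$rotation), diag(3),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  expect_error(kabsch(m[1:2, ], m[1:2, ]), "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch(line, line), "collinear")
})

test_that("kabsch rmsd matches the quaternion oracle on random clouds", {
  set.seed(42)
  for (i in 1:20) {
    a <- matrix(rnorm(30), 10, 3)
    b <- matrix(rnorm(30), 10, 3)
    expect_lt(abs(kabsch(a, b)$rmsd - quaternion_rmsd(a, b)), 1e-6)
  }
})

test_that("atom pairing respects atom sets and shared names", {
  sam <- makeConformer(ligandCode = "SAM")
  sah <- makeConformer(ligandCode = "SAH")
  pr <- pairAtoms(sam, sah, "all")
  expect_false("CE" %in% rownames(pr$a))   # SAH lacks the S-methyl
  expect_true("CE" %in% pr$dropped)
  expect_equal(nrow(pairAtoms(sam, sah, "ribose")$a), 5)
  ## incomplete ring on one side
  at <- atoms(sah)
  broken <- new("LigandInstance", ligandCode = "SAH", structureId = "X",
                chain = "A", resno = 1L, atoms = at[at$name != "C2'", ],
                complete = FALSE)
  expect_error(pairAtoms(sam, broken, "ribose"), "pairing error")
})

test_that("rmsd matrices are symmetric, zero-diagonal and honour flags", {
  lig <- makeConformer()
  m <- rmsdMatrix(list(lig, lig, lig), atomSet = "all")
  expect_equal(max(abs(m)), 0, tolerance = 1e-9)
  ligs <- lapply(c(10, 80, 160), function(p)
    makeConformer(P = p, structureId = paste0("S", p)))
  m2 <- rmsdMatrix(ligs, atomSet = "all")
  expect_equal(m2, t(m2), ignore_attr = TRUE)
  expect_equal(unname(diag(m2)), rep(0, 3))
  expect_true(all(m2 >= 0))
  ## flagged ligand excluded by default
  hot <- makeConformer(P = 40, structureId = "HOT", bFactor = 95)
  m3 <- rmsdMatrix(c(ligs, list(hot)), atomSet = "all")
  expect_equal(nrow(m3), 3)
  expect_match(attr(m3, "excluded"), "HOT")
})

test_that("the all-atom fit is optimal relative to a ribose-only fit", {
  specs <- expand.grid(P = c(10, 120, 230), chi = c(-60, -140))
  ligs <- lapply(seq_len(nrow(specs)), function(i)
    makeConformer(P = specs$P[i], chi = specs$chi[i],
                  structureId = paste0("S", i)))
  for (i in 1:(length(ligs) - 1)) for (j in (i + 1):length(ligs)) {
    direct <- superposeLigands(ligs[[i]], ligs[[j]], "all")$rmsd
    via_ribose <- superposeLigands(ligs[[i]], ligs[[j]], "ribose",
                                   measureSet = "all")$rmsd_measured
    expect_lte(direct, via_ribose + 1e-9)
  }
})

test_that("type assignment orders clusters by size and is deterministic", {
  ## two tight groups: intra < 0.5 A, inter > 2 A
  big <- lapply(c(8, 10, 12), function(p)
    makeConformer(P = p, structureId = paste0("A", p)))
  small <- lapply(c(160, 162), function(p)
    makeConformer(P = p, chi = 170, gamma = -170,
                  structureId = paste0("B", p)))
  ligs <- c(big, small)
  m <- rmsdMatrix(ligs, atomSet = "ribose", measureSet = "all")
  ty <- assignTypes(m, threshold = 1.0)
  labs <- typeLabels(ty)
  expect_length(unique(labs), 2)
  expect_true(all(labs[grep("^A", names(labs))] == "Type 1"))
  expect_true(all(labs[grep("^B", names(labs))] == "Type 2"))
  ## threshold beyond the maximum: one Type
  expect_length(unique(typeLabels(assignTypes(m, max(m) + 1))), 1)
  ## threshold zero on distinct conformers: one Type each
  expect_length(unique(typeLabels(assignTypes(m, 0))), length(ligs))
  ## determinism
  expect_identical(typeLabels(assignTypes(m, 1.0)), labs)
})

test_that("the number of Types is non-increasing in the threshold", {
  ligs <- lapply(c(5, 30, 100, 170, 250), function(p)
    makeConformer(P = p, structureId = paste0("S", p)))
  m <- rmsdMatrix(ligs, atomSet = "ribose", measureSet = "all")
  ks <- vapply(c(0, 0.2, 0.5, 1, 2, 5),
               function(h) length(unique(typeLabels(assignTypes(m, h)))),
               0L)
  expect_true(all(diff(ks) <= 0))
})

test_that("masked matrices are rejected by typing with guidance", {
  m <- matrix(c(0, NA, NA, 0), 2, 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(assignTypes(m), "exclude")
})

test_that("target-based comparison mirrors the paper's 3DLC protocol", {
  target <- makeConformer(structureId = "TGT")
  ligs <- lapply(c(10, 20), function(p)
    makeConformer(P = p, structureId = paste0("S", p)))
  r_rib <- rmsdToTarget(ligs, target, "ribose")
  r_all <- rmsdToTarget(ligs, target, "all")
  expect_length(r_rib, 2)
  ## ribose-frame fit is much tighter than the all-atom fit here
  expect_true(all(r_rib <= r_all + 1e-9))
})
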