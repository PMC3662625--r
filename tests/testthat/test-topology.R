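test_that("the packaged catalogs carry the published counts", {
  cat <- ligFoldCatalog()
  expect_equal(nrow(cat), 14)
  expect_false(anyDuplicated(cat$order_string) > 0)
  reg <- foldRegistry()
  expect_equal(nrow(reg), 18)
  expect_equal(sum(reg$is_mtase), 9)
  expect_equal(sum(!reg$is_mtase), 9)
})

test_that("every catalog string maps to its printed LigFold id", {
  cat <- ligFoldCatalog()
  for (i in seq_len(nrow(cat))) {
    hit <- assignLigFold(cat$order_string[i], cat)
    expect_false(hit$novel)
    expect_identical(hit$ligfold, cat$ligfold[i])
    expect_identical(hit$subclass, cat$subclass[i])
  }
})

test_that("a seven-strand Rossmann arrangement linearises to its catalog string", {
  ssa <- perm_to_ssa(c(3, 2, 1, 4, 5, 6, 7))
  ssa$ladders$orientation[6] <- "antiparallel"
  sheet <- buildSheet(ssa)
  expect_equal(sheet@nCore, 7L)
  expect_identical(orderString(sheet), "3214567")
  expect_identical(assignLigFold(sheet)$ligfold, "SAM_DM_Ia")
  ## strand 7 is two-coloured against the parallel majority
  expect_identical(sheet@antiparallel, 7L)
  ## single strand degenerates gracefully
  one <- list(strands = data.frame(chain = "A", start = 10, end = 14,
                                   type = "strand", sheet_id = "A"),
              ladders = data.frame(strand_i = integer(0),
                                   strand_j = integer(0),
                                   orientation = character(0)))
  expect_identical(orderString(buildSheet(one)), "1")
})

test_that("random permutations round-trip through ladder graphs", {
  set.seed(7)
  for (i in 1:50) {
    n <- sample(5:8, 1)
    perm <- sample(n)
    sheet <- buildSheet(perm_to_ssa(perm))
    fwd <- paste(perm, collapse = "")
    rev_ <- paste(rev(perm), collapse = "")
    expect_true(orderString(sheet) %in% c(fwd, rev_))
    ## deterministic: rebuilding gives the same reading
    expect_identical(orderString(buildSheet(perm_to_ssa(perm))),
                     orderString(sheet))
    ## mirror-read input yields the same canonical assignment
    expect_identical(orderString(buildSheet(perm_to_ssa(rev(perm)))),
                     orderString(sheet))
  }
})

test_that("barrels, branches and disconnected sheets are handled", {
  ssa <- perm_to_ssa(c(1, 2, 3, 4, 5))
  ## close the cycle -> barrel
  barrel <- ssa
  barrel$ladders <- rbind(barrel$ladders,
                          data.frame(strand_i = 5, strand_j = 1,
                                     orientation = "parallel"))
  expect_error(buildSheet(barrel), "barrel")
  ## branch
  branch <- ssa
  branch$ladders <- rbind(branch$ladders,
                          data.frame(strand_i = 2, strand_j = 5,
                                     orientation = "parallel"))
  expect_error(buildSheet(branch), "branched|barrel")
  ## disconnected: 4-strand sheet + 2-strand hairpin
  ssa6 <- perm_to_ssa(c(1, 2, 3, 4, 5, 6))
  ssa6$ladders <- ssa6$ladders[-4, ]   # cut between positions 4 and 5
  expect_warning(sheet <- buildSheet(ssa6), "largest")
  expect_equal(sheet@nCore, 4L)
  ## undeclared strand reference
  bad <- ssa
  bad$ladders$strand_j[1] <- 9
  expect_error(buildSheet(bad), "undeclared")
})

test_that("novel topologies report nearest catalog entries", {
  out <- assignLigFold("2134567")
  expect_true(out$novel)
  expect_true(length(out$nearest) >= 1)
  expect_true(out$min_edit_distance >= 1)
})

test_that("dual-domain structures resolve the combined catalog entry", {
  expect_identical(dualDomainScan(list("3214567", "6754123"))$summary,
                   "SAM_DM_Il")
  expect_identical(dualDomainScan(list("6754123", "3214567"))$summary,
                   "SAM_DM_Il")
  one <- dualDomainScan(list("54123"))
  expect_identical(one$summary, "SAM_DM_Id")
  expect_identical(dualDomainScan(list("2134567"))$summary, "NOVEL")
  ## two individually-known sheets without a combined entry
  both <- dualDomainScan(list("54123", "32145"))
  expect_match(both$summary, "SAM_DM_Id")
  expect_match(both$summary, "SAM_DM_Ic")
})

test_that("sidecar TSV and DSSP annotations parse to the same topology", {
  sdir <- withr::local_tempdir()
  strands <- data.frame(chain = "A", start = c(10, 20, 30),
                        end = c(14, 24, 34), type = "strand",
                        sheet_id = "A")
  ladders <- data.frame(strand_i = c(2, 1), strand_j = c(1, 3),
                        orientation = c("parallel", "parallel"))
  sf <- file.path(sdir, "strands.tsv"); lf <- file.path(sdir, "ladders.tsv")
  write.table(strands, sf, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(ladders, lf, sep = "\t", quote = FALSE, row.names = FALSE)
  ssa <- readStrandAnnotation(sf, lf)
  expect_identical(orderString(buildSheet(ssa)), "213")
  ## overlapping strand ranges are rejected
  bad <- strands; bad$start[2] <- 12
  write.table(bad, sf, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readStrandAnnotation(sf, lf), "overlap")

  ## minimal DSSP fixture: three strands laddered 1-2 and 2-3
  dssp <- file.path(sdir, "mini.dssp")
  hdr <- c("==== Secondary Structure Definition by the program DSSP ====",
           "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC")
  row <- function(no, res, ss, lad1, lad2, bp1, bp2) {
    line <- sprintf("%5d%5d A A  %s", no, res, ss)   # ss lands in col 17
    line <- sprintf("%-23s", line)
    paste0(line, lad1, lad2, sprintf("%4d%4d", bp1, bp2), "A")
  }
  lines <- c(hdr,
             row(1, 10, "E", "a", " ", 4, 0),
             row(2, 11, "E", "a", " ", 5, 0),
             row(3, 12, " ", " ", " ", 0, 0),
             row(4, 20, "E", "a", "b", 1, 7),
             row(5, 21, "E", "a", "b", 2, 8),
             row(6, 22, " ", " ", " ", 0, 0),
             row(7, 30, "E", "b", " ", 4, 0),
             row(8, 31, "E", "b", " ", 5, 0))
  writeLines(lines, dssp)
  parsed <- readStrandAnnotation(dssp, format = "dssp")
  expect_equal(nrow(parsed$strands), 3)
  expect_identical(unique(parsed$ladders$orientation), "parallel")
  key <- paste(parsed$ladders$strand_i, parsed$ladders$strand_j)
  expect_setequal(key, c("1 2", "2 3"))
  expect_identical(orderString(buildSheet(parsed)), "123")
})
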