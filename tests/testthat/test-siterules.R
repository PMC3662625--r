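make_aln <- function(rows, rep = names(rows)[1]) {
  FamilyAlignment(rows, representativeId = rep)
}

test_that("column conservation distinguishes strict and conservative", {
  aln <- make_aln(c(REP1 = "DAKD", MEM1 = "DCKE", MEM2 = "DAKD",
                    MEM3 = "DWKE"))
  strict <- conservedColumns(aln, "strict")
  expect_identical(strict$status, c("strict", "not_conserved", "strict",
                                    "not_conserved"))
  cons <- conservedColumns(aln, "conservative")
  expect_identical(cons$status[4], "conservative")   # D/E one group
  expect_identical(cons$status[2], "not_conserved")  # A/C/W mixed
  ## gaps disqualify
  g <- make_aln(c(REP1 = "DD", MEM1 = "D-"))
  expect_identical(conservedColumns(g, "strict")$status[2],
                   "not_conserved")
  ## two identical sequences: everything strict
  s <- make_aln(c(REP1 = "MKLVDW", MEM1 = "MKLVDW"))
  expect_true(all(conservedColumns(s, "strict")$status == "strict"))
})

test_that("site rules intersect contacts with conservation", {
  fam <- makeFamily(4, 50,
    data.frame(pos = c(10, 25, 40), residue = c("D", "G", "K"),
               status = c("strict", "strict", "non_conserved")),
    contactPositions = c(10, 25, 40), seed = 101)
  rule <- buildSiteRule(fam$alignment, fam$contacts, "strict")
  expect_identical(rulePositions(rule)$resno, c(10L, 25L))
  expect_identical(rulePositions(rule)$residue, c("D", "G"))
  ## brute-force audit agrees
  seqs <- as.character(fam$alignment@sequences)
  expect_identical(rulePositions(rule)$resno,
                   sort(audit_conserved(seqs, c(10L, 25L, 40L), "strict")))
  ## unmapped contacts are reported, not fatal
  ctc2 <- rbind(fam$contacts, data.frame(resno = 999L, resname = "X"))
  rule2 <- buildSiteRule(fam$alignment, ctc2, "strict")
  expect_identical(rule2@unmapped, 999L)
  ## no conserved contact columns -> empty rule with warning
  fam0 <- makeFamily(4, 30,
    data.frame(pos = 12, residue = "K", status = "non_conserved"),
    contactPositions = 12, seed = 5)
  expect_warning(r0 <- buildSiteRule(fam0$alignment, fam0$contacts),
                 "empty")
  expect_equal(nrow(rulePositions(r0)), 0)
})

test_that("strict rule positions are a subset of conservative ones", {
  for (seed in c(3, 17, 29)) {
    fam <- makeFamily(5, 60,
      data.frame(pos = c(10, 20, 30, 40),
                 residue = c("D", "I", "G", "K"),
                 status = c("strict", "conservative", "strict",
                            "non_conserved")),
      contactPositions = c(10, 20, 30, 40), seed = seed)
    rs <- buildSiteRule(fam$alignment, fam$contacts, "strict")
    rc <- buildSiteRule(fam$alignment, fam$contacts, "conservative")
    expect_true(all(rulePositions(rs)$resno %in%
                      rulePositions(rc)$resno))
    expect_true(20L %in% rulePositions(rc)$resno)
    expect_false(20L %in% rulePositions(rs)$resno)
    expect_false(40L %in% rulePositions(rc)$resno)
  }
})

test_that("rule propagation maps positions through a global alignment", {
  fam <- makeFamily(4, 50,
    data.frame(pos = c(10, 25), residue = c("D", "G"),
               status = c("strict", "strict")),
    contactPositions = c(10, 25), seed = 23)
  rule <- buildSiteRule(fam$alignment, fam$contacts)
  rep_seq <- gsub("-", "",
                  as.character(fam$alignment@sequences[["REP1"]]))
  ## reflexivity
  self <- propagateRule(rule, fam$alignment, rep_seq)
  expect_true(self$positive)
  expect_identical(self$annotations$query_pos, c(10L, 25L))
  ## N-terminal extension shifts positions by +5
  ext <- propagateRule(rule, fam$alignment, paste0("MKWQV", rep_seq))
  expect_true(ext$positive)
  expect_identical(ext$annotations$query_pos, c(15L, 30L))
  ## a rule-position substitution turns the match negative with diagnostics
  chars <- strsplit(rep_seq, "")[[1]]
  chars[10] <- "A"
  neg <- propagateRule(rule, fam$alignment, paste(chars, collapse = ""))
  expect_false(neg$positive)
  bad <- neg$diagnostics[!neg$diagnostics$ok, ]
  expect_identical(bad$resno, 10L)
  expect_identical(bad$found, "A")
  ## invalid characters rejected
  expect_error(propagateRule(rule, fam$alignment, "MKL1VX"),
               "non-amino-acid")
})

test_that("conservative rules accept in-group substitutions on propagation", {
  fam <- makeFamily(4, 40,
    data.frame(pos = 15, residue = "D", status = "conservative"),
    contactPositions = 15, seed = 31)
  rule <- buildSiteRule(fam$alignment, fam$contacts, "conservative")
  expect_identical(rulePositions(rule)$allowed, "DE")
  rep_seq <- gsub("-", "",
                  as.character(fam$alignment@sequences[["REP1"]]))
  chars <- strsplit(rep_seq, "")[[1]]
  chars[15] <- "E"
  swapped <- propagateRule(rule, fam$alignment, paste(chars, collapse = ""))
  expect_true(swapped$positive)
  chars[15] <- "K"
  out_of_group <- propagateRule(rule, fam$alignment,
                                paste(chars, collapse = ""))
  expect_false(out_of_group$positive)
})

test_that("site rules survive a JSON round trip", {
  fam <- makeFamily(3, 40,
    data.frame(pos = c(8, 20), residue = c("D", "G"),
               status = c("strict", "strict")),
    contactPositions = c(8, 20), seed = 13)
  rule <- buildSiteRule(fam$alignment, fam$contacts)
  f <- withr::local_tempfile(fileext = ".json")
  writeSiteRule(rule, f)
  back <- readSiteRule(f)
  expect_identical(back@familyId, rule@familyId)
  expect_equal(rulePositions(back), rulePositions(rule))
})

test_that("motif I requires the acidic -2 and hydrophobic -3/-4 flanks", {
  hits <- detectMotifs("WVLEAGAGTGLLSS")
  expect_true("I" %in% hits$motif)
  expect_identical(hits$residues[hits$motif == "I"][1], "VLEAGAGTG")
  ## lysine at -2 kills the motif
  none <- detectMotifs("WVLKAGAGTGLLSS")
  expect_false("I" %in% none$motif)
  ## alanine substitutions in the glycine core are tolerated
  ala <- detectMotifs("WVLEAAAGTALLSS")
  expect_true("I" %in% ala$motif)
})

test_that("strand-context motifs are skipped without annotations", {
  expect_message(hits <- detectMotifs("WVLEAGAGTGLLSSDDII"),
                 "skipped")
  expect_setequal(attr(hits, "skipped"),
                  c("II", "III", "IV", "V", "VI"))
})

test_that("strand-context motifs are detected with annotations", {
  ##            1234567890123456789012345678901234567890
  seq <- paste0("WVLEAGAGTG",   # 1-10: motif I region
                "AIVAAEAAAA",   # 11-20: strand II at 14-18, E mid
                "DAAGAAAAAA",   # 21-30: strand III at 21-25, D start, G end?
                "DAVAAAAAAA",   # 31-40: strand IV at 31-35
                "GAVLAAAAAA")   # 41-50: strand V at 41-45
  strands <- data.frame(index = 1:5,
                        start = c(5, 14, 21, 31, 41),
                        end = c(9, 18, 24, 35, 45))
  hits <- detectMotifs(seq, strands)
  expect_true(all(c("I", "II", "IV", "V", "VI") %in% hits$motif))
  ## motif II: E at 16 (middle of 14-18), I/V at 12/13
  m2 <- hits[hits$motif == "II", ][1, ]
  expect_equal(m2$end, 16)
  ## motif III: D at 21
  expect_true("III" %in% hits$motif)
  ## motif IV: D at 31 with V at +2
  m4 <- hits[hits$motif == "IV", ][1, ]
  expect_equal(m4$start, 31)
  ## motif V is a region between strands IV and V, not a residue match
  m5 <- hits[hits$motif == "V", ][1, ]
  expect_equal(m5$start, 36); expect_equal(m5$end, 40)
  ## motif VI: G at 41 with hydrophobic at 43, 44
  m6 <- hits[hits$motif == "VI", ][1, ]
  expect_equal(m6$start, 41)
})
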