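test_that("single-window test accepts exactly two residue types, each twice", {
  expect_identical(windowIsPositive("VVVGGG"), "GV")
  expect_identical(windowIsPositive("SSGGSG"), "GS")
  expect_false(windowIsPositive("AAAAAA"))   # one residue type
  expect_false(windowIsPositive("AAAAAG"))   # second type occurs once
  expect_false(windowIsPositive("AAGGGS"))   # three residue types
  expect_false(windowIsPositive("AAGGXX"))   # X is an ambiguity code
  expect_false(windowIsPositive("AAGG*U"))   # stops / non-standard letters
  expect_false(windowIsPositive("aaggABC"))  # length is free, composition rules
})

test_that("detection unions overlapping positive windows per pair", {
  # the SMN polySG heptamer is one region spanning all of it
  r <- detectRegions(c(SMN = "SSGGSGG"))
  expect_equal(nrow(r), 1L)
  expect_equal(r$start, 1L)
  expect_equal(r$end, 7L)
  expect_equal(r$pair, "GS")
  expect_equal(r$sequence, "SSGGSGG")

  # homorepeats are not polyXY
  expect_equal(nrow(detectRegions(c(p = "AAAAAAAA"))), 0L)

  # two overlapping regions of different pairs stay separate
  r2 <- detectRegions(c(p = "AAAGGGSSS"))
  expect_equal(nrow(r2), 2L)
  expect_equal(r2$start, c(1L, 4L))
  expect_equal(r2$end, c(6L, 9L))
  expect_equal(r2$pair, c("AG", "GS"))

  # shorter-than-window and empty-ish inputs yield nothing
  expect_equal(nrow(detectRegions(c(p = "AGAGA"))), 0L)
  expect_equal(nrow(detectRegions(c(p = "M"))), 0L)
})

test_that("detector matches the window-enumeration oracle on random input", {
  set.seed(421)
  for (i in 1:250) {
    k <- sample(2:20, 1)
    alpha <- sample(STANDARD_AA, k)
    len <- sample(1:500, 1)
    s <- randomSeq(len, alpha)
    got <- detectRegions(c(p = s))
    want <- oracleDetect(s)
    expect_equal(nrow(got), nrow(want), info = s)
    if (nrow(want)) {
      expect_equal(got$start, want$start, info = s)
      expect_equal(got$end, want$end, info = s)
      expect_equal(got$pair, want$pair, info = s)
    }
  }
})

test_that("regions are maximal, pure and deterministic", {
  set.seed(99)
  for (i in 1:40) {
    s <- randomSeq(sample(20:200, 1), c("A", "G", "S", "V"))
    r <- detectRegions(c(p = s))
    if (nrow(r) == 0) next
    for (j in seq_len(nrow(r))) {
      chars <- strsplit(r$sequence[j], "")[[1]]
      tab <- table(chars)
      # exactly the two pair residues, each at least twice, length >= window
      expect_identical(paste(sort(names(tab)), collapse = ""), r$pair[j])
      expect_true(all(tab >= 2))
      expect_gte(r$end[j] - r$start[j] + 1L, 6L)
      # maximality: the boundary windows themselves are positive
      expect_identical(
        windowIsPositive(substr(s, r$start[j], r$start[j] + 5L)), r$pair[j])
      expect_identical(
        windowIsPositive(substr(s, r$end[j] - 5L, r$end[j])), r$pair[j])
    }
    expect_identical(regionsAsDf(detectRegions(c(p = s))), regionsAsDf(r))
  }
})

test_that("close same-pair regions merge across short gaps, others do not", {
  s <- c(p = "GGSSGGASSGGSS")
  r <- detectRegions(s)
  expect_equal(r$start, c(1L, 8L))
  expect_equal(r$end, c(6L, 13L))
  m <- mergeCloseRegions(r, s, mergeGap = 1)
  expect_equal(nrow(m), 1L)
  expect_equal(m$start, 1L)
  expect_equal(m$end, 13L)
  expect_equal(m$sequence, "GGSSGGASSGGSS")
  # merged regions are categorized shuffled (they carry a non-pair residue)
  expect_equal(classifyRegions(m)$category, "shuffled")

  # a 2-residue gap needs mergeGap = 2
  s2 <- c(p = "GGSSGGATSSGGSS")
  r2 <- detectRegions(s2)
  expect_equal(nrow(mergeCloseRegions(r2, s2, 1)), 2L)
  expect_equal(nrow(mergeCloseRegions(r2, s2, 2)), 1L)

  # different pairs never merge
  s3 <- c(p = "AAGGAGTTGGSSGS")
  r3 <- detectRegions(s3)
  expect_equal(nrow(r3), 2L)
  expect_equal(sort(r3$pair), c("AG", "GS"))
  expect_equal(nrow(mergeCloseRegions(r3, s3, 2)), 2L)

  expect_error(mergeCloseRegions(r, s, 0), "mergeGap")
  expect_error(mergeCloseRegions(r, s, 3), "mergeGap")
})

test_that("pair, category and unit filters behave as the search options", {
  regions <- classifyRegions(detectRegions(c(
    a = "VVVGGG", b = "AGAGAGAG", c = "SRSRSR", d = "SSGGSGG")))
  expect_equal(nrow(regions), 4L)

  expect_equal(applyFilters(regions, pair = "GV")$pair, "GV")
  expect_equal(applyFilters(regions, pair = c("V", "G"))$pair, "GV")

  # any X, specific Y = S
  withS <- applyFilters(regions, anyWith = "S")
  expect_setequal(withS$pair, c("RS", "GS"))

  expect_equal(applyFilters(regions, categories = "direpeat")$proteinId,
               c("b", "c"))
  expect_equal(applyFilters(regions, categories = c("joined", "shuffled"))$proteinId,
               c("a", "d"))

  # min units applies to direpeats and drops everything else
  mu <- applyFilters(regions, minUnits = 4)
  expect_equal(mu$proteinId, "b")
  expect_equal(mu$nUnits, 4L)
})

test_that("scanProteins honors ScanParams filters end to end", {
  seqs <- c(p1 = "MAMSSGGSGGGVPEQ", p2 = "KKVVVGGGKKAGAGAGAG")
  all <- scanProteins(seqs)
  expect_equal(nrow(all), 3L)
  only_vg <- scanProteins(seqs, ScanParams(pairFilter = c("G", "V")))
  expect_equal(only_vg$pair, "GV")
  dire <- scanProteins(seqs, ScanParams(categoryFilter = "direpeat"))
  expect_equal(dire$category, "direpeat")
  anyS <- scanProteins(seqs, ScanParams(pairFilter = "S"))
  expect_equal(anyS$pair, "GS")
})

test_that("invalid scan parameters and duplicate ids are rejected", {
  expect_error(ScanParams(window = 3), "window")
  expect_error(ScanParams(mergeGap = 5), "mergeGap")
  expect_error(detectRegions(c(a = "AAGGAA", a = "SSGGSS")), "duplicate")
})
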