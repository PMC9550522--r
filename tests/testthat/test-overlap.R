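test_that("containment requires the complete region inside an interval", {
  iv <- data.frame(start = 1, end = 50)
  expect_true(regionContained(10, 15, iv))
  expect_false(regionContained(10, 15, data.frame(start = 12, end = 50)))
  expect_true(regionContained(10, 15, data.frame(start = 10, end = 15)))
  expect_false(regionContained(10, 15, NULL))
  expect_false(regionContained(10, 15, iv[0, , drop = FALSE]))

  # monotone: enlarging an interval never flips contained -> not contained
  set.seed(3)
  for (i in 1:50) {
    s <- sample(1:80, 1); e <- s + sample(0:19, 1)
    ivs <- data.frame(start = sample(1:90, 1), end = 0)
    ivs$end <- ivs$start + sample(0:30, 1)
    before <- regionContained(s, e, ivs)
    grown <- data.frame(start = max(1, ivs$start - 5), end = ivs$end + 5)
    expect_true(!before || regionContained(s, e, grown))
  }
})

test_that("random placement is uniform, bounded and reproducible", {
  expect_equal(randomPlacement(10, 10), 1L)
  expect_error(randomPlacement(11, 10), "shorter")

  set.seed(42); a <- randomPlacement(6, 100, 50)
  set.seed(42); b <- randomPlacement(6, 100, 50)
  expect_identical(a, b)
  expect_true(all(a >= 1 & a <= 95))

  # chi-square goodness of fit against uniform over the 95 legal starts
  set.seed(101)
  draws <- randomPlacement(6, 100, 10000)
  tab <- tabulate(draws, nbins = 95)
  p <- stats::chisq.test(tab, p = rep(1 / 95, 95))$p.value
  expect_gt(p, 0.01)
})

test_that("Monte-Carlo containment converges to the analytic expectation", {
  # single interval of length m in a protein of length L, region length k:
  # P(contained) = max(0, m - k + 1) / (L - k + 1)
  L <- 100; k <- 6; m <- 30
  iv <- data.frame(start = 35, end = 64)
  set.seed(7)
  starts <- randomPlacement(k, L, 10000)
  mc <- mean(regionContained(starts, starts + k - 1L, iv))
  expect_equal(mc, (m - k + 1) / (L - k + 1), tolerance = 0.05)

  # interval shorter than the region can never contain it
  ivShort <- data.frame(start = 40, end = 43)
  expect_equal(mean(regionContained(starts, starts + k - 1L, ivShort)), 0)
})

test_that("overlap analysis reports observed vs random fractions per pair", {
  # flanks cycle through six residue types so no window outside the planted
  # regions can hold only two
  flank <- function(n) substr(strrep("MKLWYE", ceiling(n / 6) + 1), 1, n)
  proteins <- c(p1 = paste0(flank(20), "AGAGAGAG", flank(72)),
                p2 = paste0(flank(40), "SSGGSGG", flank(53)))
  regions <- scanProteins(proteins)
  expect_equal(nrow(regions), 2L)

  # total coverage: observed and random containment are both 1
  full <- data.frame(proteinId = c("p1", "p2"), start = 1L,
                     end = 100L, kind = "disorder", name = "all",
                     stringsAsFactors = FALSE)
  full <- rbind(full, transform(full, kind = "domain"))
  rep1 <- overlapAnalysis(regions, proteins, full, nRandom = 20, seed = 1)
  expect_true(all(rep1$observedFraction == 1))
  expect_true(all(rep1$randomFraction == 1))

  # empty annotation table: all fractions zero
  none <- full[0, , drop = FALSE]
  rep0 <- overlapAnalysis(regions, proteins, none, nRandom = 5, seed = 1)
  expect_true(all(rep0$observedFraction == 0))
  expect_true(all(rep0$randomFraction == 0))

  # plants inside disorder: observed 1, random near the analytic expectation
  ann <- data.frame(proteinId = c("p1", "p2"), start = c(15L, 35L),
                    end = c(34L, 54L), kind = "disorder",
                    name = c("idr1", "idr2"), stringsAsFactors = FALSE)
  rep2 <- overlapAnalysis(regions, proteins, ann, nRandom = 1000, seed = 5)
  dis <- rep2[rep2$kind == "disorder", ]
  expect_true(all(dis$observedFraction == 1))
  # expectation per protein: (20 - len + 1) / (100 - len + 1)
  expAG <- (20 - 8 + 1) / (100 - 8 + 1)
  expGS <- (20 - 7 + 1) / (100 - 7 + 1)
  expect_equal(dis$randomFraction[dis$pair == "AG"], expAG, tolerance = 0.3)
  expect_equal(dis$randomFraction[dis$pair == "GS"], expGS, tolerance = 0.3)

  # fixed seed -> bit-identical report
  repA <- overlapAnalysis(regions, proteins, ann, nRandom = 10, seed = 9)
  repB <- overlapAnalysis(regions, proteins, ann, nRandom = 10, seed = 9)
  expect_identical(repA, repB)

  # no annotated proteins in common is an error
  annOther <- transform(ann, proteinId = c("zz1", "zz2"))
  expect_error(overlapAnalysis(regions, proteins, annOther, seed = 1),
               "in common")
})

test_that("per-category splitting and pair selection work", {
  fx <- generateFixture(fixtureSpec(
    nProteins = 10, lengthRange = c(120, 200),
    plants = data.frame(pair = rep(c("GV", "RS"), each = 3),
                        category = rep(c("joined", "direpeat"), each = 3)),
    annotationPlan = list(coverPlants = "disorder", pad = 4L,
                          randomDomains = 1L),
    seed = 77))
  rep <- overlapAnalysis(fx$truth, fx$proteins, fx$annotations,
                         nRandom = 20, seed = 2, byCategory = TRUE,
                         pairs = c("GV", "RS"))
  expect_setequal(unique(rep$pair), c("GV", "RS"))
  expect_true(all(rep$category %in% c("direpeat", "joined", "shuffled")))
  planted <- rep[rep$kind == "disorder" &
                 rep$category %in% c("joined", "direpeat"), ]
  expect_true(all(planted$observedFraction == 1))
})
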