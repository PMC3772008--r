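test_that("digestion cuts at every site with the enzyme's offset", {
  expect_equal(fragmentLengths(digestSequence("AAGGCCTT", HaeIII())),
               c(4L, 4L))
  expect_equal(fragmentLengths(digestSequence("AAAATTTT", HaeIII())), 8L)
  # leading zero-length fragment dropped
  expect_equal(fragmentLengths(digestSequence("GATCGATC", Sau3AI())),
               c(4L, 4L))
  expect_equal(fragmentLengths(digestSequence("aaggcctt", HaeIII())),
               c(4L, 4L))
  # N never matches a site position
  expect_equal(fragmentLengths(digestSequence("AAGGCNTT", HaeIII())), 8L)
  expect_error(digestSequence("AAXGG", HaeIII()), "characters")
  expect_error(digestSequence("", HaeIII()), "non-empty")
})

test_that("digestion conserves length and matches a brute-force scanner", {
  set.seed(42)
  for (i in 1:200) {
    n <- sample(20:2000, 1)
    s <- randomDna(n, alphabet = c("A", "C", "G", "T", "N"))
    for (enz in list(HaeIII(), Sau3AI())) {
      fp <- digestSequence(s, enz)
      expect_equal(sum(fragmentLengths(fp)), n)
      expect_equal(fragmentLengths(fp),
                   as.integer(bruteForceDigest(s, enz@site, enz@cutOffset)))
    }
  }
})

test_that("pattern comparison honors tolerance and detectability", {
  p <- function(lens) new("FragmentPattern", enzymeName = "HaeIII",
                          fragmentLengths = as.integer(sort(lens, TRUE)),
                          sequenceLength = as.integer(sum(lens)))
  expect_true(patternEqual(p(c(500, 300, 200)), p(c(500, 300, 200))))
  expect_true(patternEqual(p(c(500, 300, 200)), p(c(510, 300, 200)),
                           toleranceFraction = 0.05))
  expect_false(patternEqual(p(c(500, 300, 200)), p(c(510, 300, 200))))
  expect_false(patternEqual(p(c(500, 300)), p(c(500, 300, 200))))
  # fragments below the detection floor are invisible on gel
  expect_true(patternEqual(p(c(500, 300, 30)), p(c(500, 300)),
                           minDetectableBp = 50L))
  q <- new("FragmentPattern", enzymeName = "Sau3AI",
           fragmentLengths = 500L, sequenceLength = 500L)
  expect_error(patternEqual(p(500), q), "different enzymes")
})

test_that("tolerant pattern equality is reflexive and symmetric", {
  set.seed(7)
  pats <- lapply(1:12, function(i)
    digestSequence(randomDna(800), HaeIII()))
  for (i in 1:12) {
    expect_true(patternEqual(pats[[i]], pats[[i]], 0.05))
    for (j in 1:12)
      expect_equal(patternEqual(pats[[i]], pats[[j]], 0.05),
                   patternEqual(pats[[j]], pats[[i]], 0.05))
  }
})

test_that("two-stage grouping separates by HaeIII then Sau3AI", {
  # identical sequences fall in one group
  g <- groupByArdra(c(a = "AAGGCCTT", b = "AAGGCCTT"))
  expect_equal(length(groupRepresentatives(g)), 1L)
  expect_equal(unname(groupRepresentatives(g)), "a")

  # same HaeIII pattern, different Sau3AI site count: split at stage 2
  s1 <- "AAGGCCTTTTTTTTTT"  # one GGCC, no GATC
  s2 <- "AAGGCCTTTTGATCTT"  # same-length GGCC fragments, one GATC
  expect_equal(fragmentLengths(digestSequence(s1, HaeIII())),
               fragmentLengths(digestSequence(s2, HaeIII())))
  g2 <- groupByArdra(c(x = s1, y = s2))
  expect_equal(length(groupRepresentatives(g2)), 2L)

  # pairwise-distinct HaeIII patterns: n groups, stage 2 a no-op
  set.seed(3)
  seqs <- replicate(8, randomDna(600))
  names(seqs) <- paste0("iso", 1:8)
  pat <- lapply(seqs, function(s) fragmentLengths(digestSequence(s, HaeIII())))
  distinct <- !any(vapply(1:7, function(i) any(vapply((i + 1):8, function(j)
    identical(pat[[i]], pat[[j]]), logical(1))), logical(1)))
  if (distinct)
    expect_equal(length(groupRepresentatives(groupByArdra(seqs))), 8L)

  expect_error(groupByArdra(character(0)), "no sequences")
})

test_that("grouping is invariant to input order at tolerance 0", {
  seqs <- simulateAmplicons(nGroups = 5, copies = 2, length = 900, seed = 9)
  g1 <- groupByArdra(seqs)
  g2 <- groupByArdra(rev(seqs))
  expect_equal(groupAssignments(g1)[sort(names(seqs))],
               groupAssignments(g2)[sort(names(seqs))])
  expect_equal(groupRepresentatives(g1), groupRepresentatives(g2))
})

test_that("FASTA input and grouping CSV output round-trip", {
  seqs <- simulateAmplicons(nGroups = 3, copies = 2, length = 500, seed = 4)
  f <- withr::local_tempfile(fileext = ".fasta")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), f)
  back <- readAmpliconFasta(f)
  expect_equal(back, seqs)
  g <- groupByArdra(back)
  fcsv <- withr::local_tempfile(fileext = ".csv")
  writeArdraGrouping(g, fcsv)
  df <- read.csv(fcsv)
  expect_equal(nrow(df), 6L)
  expect_equal(sum(df$representative), 3L)
})
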