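test_that("p-distance counts mismatches over comparable sites only", {
  s <- randomDna(100)
  expect_equal(pDistance(s, s), 0)
  a <- rep("A", 100); b <- a; b[1:5] <- "C"
  expect_equal(pDistance(a, b), 0.05)
  expect_equal(pDistance("AC-G", "ACTG"), 0)       # gap column excluded
  expect_equal(pDistance("ACNG", "ACTT"), 1 / 3)   # N excluded
  expect_error(pDistance("----", "ACGT"), "no comparable sites")
  expect_error(pDistance("AC", "ACG"), "equal length")
})

test_that("K2P distance matches its closed form and dominates p-distance", {
  a <- c(rep("A", 85), rep("A", 10), rep("C", 5))
  b <- c(rep("A", 85), rep("G", 10), rep("A", 5))  # 10 ts, 5 tv / 100
  expect_equal(k2pDistance(a, b), -0.5 * log(0.75) - 0.25 * log(0.9),
               tolerance = 1e-12)
  expect_equal(k2pDistance(a, a), 0)
  # saturation: Q = 0.5 makes 1 - 2Q = 0
  expect_true(is.na(k2pDistance(c(rep("A", 50), rep("C", 50)),
                                c(rep("A", 50), rep("A", 50)))))
  # correction expands distances: K2P >= p for every defined pair
  set.seed(17)
  for (i in 1:20) {
    x <- strsplit(randomDna(300), "")[[1]]
    y <- x
    mut <- sample(300, sample(5:60, 1))
    y[mut] <- sample(c("A", "C", "G", "T"), length(mut), replace = TRUE)
    k <- k2pDistance(x, y)
    if (!is.na(k)) expect_gte(k, pDistance(x, y) - 1e-12)
  }
})

test_that("pairwise distances agree with the reference implementation", {
  tr <- simulateTree(6, seed = 5, meanBranchLength = 0.04)
  aln <- simulateAlignment(tr, 800, kappa = 2, seed = 5)
  v <- pairwiseDistances(aln, model = "k2p")
  ref <- as.matrix(ape::dist.dna(ape::as.DNAbin(alignmentMatrix(aln) |>
    tolower()), model = "K80", pairwise.deletion = TRUE))
  expect_equal(unname(v), unname(ref[rownames(v), rownames(v)]),
               tolerance = 1e-9)
  vp <- pairwiseDistances(aln, model = "p")
  refp <- as.matrix(ape::dist.dna(ape::as.DNAbin(tolower(alignmentMatrix(aln))),
                                  model = "raw", pairwise.deletion = TRUE))
  expect_equal(unname(vp), unname(refp[rownames(vp), rownames(vp)]),
               tolerance = 1e-9)
})

test_that("phylotype clustering enforces the strict divergence cut", {
  L <- 100
  base <- strsplit(randomDna(L), "")[[1]]
  same <- paste0(base, collapse = "")
  aln <- dnaAlignment(c(s1 = same, s2 = same, s3 = same))
  expect_equal(unname(phylotypes(clusterPhylotypes(aln))), c(1L, 1L, 1L))

  # two sequences at exactly 5% differ: distinct phylotypes
  alt <- base; alt[1:5] <- ifelse(base[1:5] == "A", "C", "A")
  two <- dnaAlignment(c(s1 = same, s2 = paste0(alt, collapse = "")))
  expect_equal(pDistance(same, paste0(alt, collapse = "")), 0.05)
  expect_equal(length(unique(phylotypes(clusterPhylotypes(two)))), 2L)

  # pairwise distances (0.01, 0.01, 0.05): complete linkage gives 2 groups
  sA <- base
  sB <- base; sB[1] <- ifelse(base[1] == "A", "C", "A")   # d(a,b) = 0.01
  sC2 <- base; sC2[96:100] <- ifelse(base[96:100] == "A", "C", "A")
  tri <- dnaAlignment(c(a = paste0(sA, collapse = ""),
                        b = paste0(sB, collapse = ""),
                        c = paste0(sC2, collapse = "")))
  d <- pairwiseDistances(tri)
  expect_equal(sort(d[upper.tri(d)]), c(0.01, 0.05, 0.06))
  got <- phylotypes(clusterPhylotypes(tri))
  expect_equal(length(unique(got)), 2L)
  expect_equal(got[["a"]], got[["b"]])
  # brute force: the only valid maximal partition keeps every within-pair
  # distance < 0.03, so {a,b},{c} is forced
  expect_true(d["a", "b"] < 0.03 && d["a", "c"] >= 0.03 &&
                d["b", "c"] >= 0.03)

  # order invariance
  g1 <- phylotypes(clusterPhylotypes(tri))
  g2 <- phylotypes(clusterPhylotypes(dnaAlignment(
    c(c = paste0(sC2, collapse = ""), a = paste0(sA, collapse = ""),
      b = paste0(sB, collapse = "")))))
  expect_equal(g1[sort(names(g1))], g2[sort(names(g2))])
})

test_that("neighbor joining recovers additive trees exactly", {
  # worked 4-taxon case
  tr <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:1):0);")
  nj <- neighborJoining(additiveMatrix(tr))
  expect_true(sameTopology(tr, nj))
  expect_equal(sort(nj$edge.length), sort(c(1, 2, 3, 1, 1)),
               tolerance = 1e-9)

  # 3 taxa: closed-form star
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  nj3 <- neighborJoining(d3)
  expect_equal(length(nj3$tip.label), 3L)
  expect_equal(sort(nj3$edge.length), c(1, 2, 3), tolerance = 1e-9)

  # random additive trees come back topologically exact, matching ape's NJ
  set.seed(99)
  for (i in 1:20) {
    t0 <- simulateTree(6, seed = i, meanBranchLength = 0.2)
    dm <- additiveMatrix(t0)
    mine <- neighborJoining(dm)
    expect_true(sameTopology(t0, mine))
    expect_true(sameTopology(ape::nj(as.dist(dm)), mine))
    back <- additiveMatrix(mine)
    expect_equal(back[rownames(dm), colnames(dm)], dm, tolerance = 1e-6)
  }
  expect_error(neighborJoining(matrix(0, 2, 2)), "at least 3")
})

test_that("bootstrap supports are deterministic and well-bounded", {
  tr <- ape::read.tree(text = "((A:0.08,B:0.08):0.04,(C:0.08,D:0.08):0.04);")
  aln <- simulateAlignment(tr, 1200, kappa = 2, seed = 3)
  bt1 <- bootstrapSupport(aln, replicates = 50, seed = 10)
  bt2 <- bootstrapSupport(aln, replicates = 50, seed = 10)
  expect_identical(bt1$node.label, bt2$node.label)
  sup <- suppressWarnings(as.integer(bt1$node.label))
  sup <- sup[!is.na(sup)]
  expect_true(all(sup >= 0 & sup <= 100))
  # single replicate: supports are 0 or 100
  bt3 <- bootstrapSupport(aln, replicates = 1, seed = 2)
  s3 <- suppressWarnings(as.integer(bt3$node.label))
  expect_true(all(s3[!is.na(s3)] %in% c(0L, 100L)))
})

test_that("Newick writing round-trips topology, lengths and supports", {
  set.seed(44)
  for (i in 1:5) {
    t0 <- simulateTree(sample(4:12, 1), seed = i)
    back <- readNewickTree(writeNewickTree(t0))
    expect_true(sameTopology(t0, back))
    expect_equal(sort(back$edge.length), sort(t0$edge.length),
                 tolerance = 1e-6)
  }
  two <- readNewickTree("(A:1,B:2);")
  expect_equal(sort(two$tip.label), c("A", "B"))
  expect_error(readNewickTree("((A:1,B:2;"))
  f <- withr::local_tempfile(fileext = ".nwk")
  tr <- simulateTree(5, seed = 2)
  writeNewickTree(tr, f)
  expect_true(sameTopology(tr, readNewickTree(path = f)))
})
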