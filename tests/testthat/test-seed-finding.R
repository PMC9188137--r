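test_that("contiguous matching emits midpoint seeds", {
  s1 <- maskedSeqSet(c(a = "ACGTACGTACGTACG"), "gA")   # 15 bp
  s2 <- maskedSeqSet(c(b = "ACGTACGTACGTACG"), "gB")
  sd <- findContiguousSeeds(s1, s2, 15)
  expect_equal(length(sd), 1)
  expect_equal(unname(sd@positions[1, ]), c(7, 7))     # floor(15/2)

  s1 <- maskedSeqSet(c(a = "AAAA"), "gA")
  s2 <- maskedSeqSet(c(b = "CCCC"), "gB")
  expect_equal(length(findContiguousSeeds(s1, s2, 3)), 0)

  expect_warning(
    findContiguousSeeds(maskedSeqSet(c(a = "ACG"), "gA"),
                        maskedSeqSet(c(b = "ACG"), "gB"), 10),
    "span")
})

test_that("same genome label or mixed weights are rejected", {
  s1 <- maskedSeqSet(c(a = "ACGT"), "gA")
  s2 <- maskedSeqSet(c(b = "ACGT"), "gA")
  expect_error(findContiguousSeeds(s1, s2, 2), "distinct genome labels")
  expect_error(findSpacedSeeds(s1, maskedSeqSet(c(b = "ACGT"), "gB"),
                               c("111", "11")), "equal weight")
})

test_that("spaced matching reproduces the hand-evaluated window", {
  s1 <- maskedSeqSet(c(h1 = "ACGTA"), "gA")
  s2 <- maskedSeqSet(c(m1 = "AGGTA"), "gB")
  sd <- findSpacedSeeds(s1, s2, "10011")   # induced "ATA" on both
  expect_equal(length(sd), 1)
  expect_equal(unname(sd@positions[1, ]), c(2, 2))
})

test_that("hash-based matching equals the brute-force all-window oracle", {
  set.seed(101)
  for (case in list(
    list(bits = "1111", n1 = 900, n2 = 700),           # contiguous, many hits
    list(bits = "110101", n1 = 1200, n2 = 1000),       # spaced
    list(bits = c("11011", "10111"), n1 = 800, n2 = 800))) {  # pattern set
    seqs1 <- randomSeqSet(case$n1, "gA", "x")
    seqs2 <- randomSeqSet(case$n2, "gB", "y")
    got <- findSpacedSeeds(seqs1, seqs2, case$bits, maxPerKmer = Inf)
    exp <- oracleSeedCoords(residues(seqs1)[[1]], residues(seqs2)[[1]],
                            case$bits)
    expect_equal(unname(got@positions[, 1]), exp$pos1)
    expect_equal(unname(got@positions[, 2]), exp$pos2)
  }
})

test_that("masking and ambiguity only remove seeds, never create them", {
  set.seed(33)
  base <- sample(c("A", "C", "G", "T"), 1500, replace = TRUE)
  dirty <- base
  dirty[sample(1500, 100)] <- tolower(dirty[sample(1500, 100)])
  dirty[sample(1500, 10)] <- "n"
  s2chars <- sample(c("A", "C", "G", "T"), 1500, replace = TRUE)
  clean1 <- maskedSeqSet(setNames(paste(base, collapse = ""), "x1"), "gA")
  dirty1 <- maskedSeqSet(setNames(paste(dirty, collapse = ""), "x1"), "gA")
  seqs2 <- maskedSeqSet(setNames(paste(s2chars, collapse = ""), "y1"), "gB")
  keyOf <- function(sd) paste(sd@positions[, 1], sd@positions[, 2])
  full <- findSpacedSeeds(clean1, seqs2, "11011", maxPerKmer = Inf)
  filt <- findSpacedSeeds(dirty1, seqs2, "11011", maxPerKmer = Inf)
  expect_true(all(keyOf(filt) %in% keyOf(full)))
  # and matches the oracle on the dirty input
  exp <- oracleSeedCoords(residues(dirty1)[[1]], residues(seqs2)[[1]], "11011")
  expect_equal(unname(filt@positions[, 1]), exp$pos1)
})

test_that("seeds identical across patterns are de-duplicated", {
  # two patterns of equal span matching the same window pair
  s1 <- maskedSeqSet(c(a = "ACGTACG"), "gA")
  s2 <- maskedSeqSet(c(b = "ACGTACG"), "gB")
  sd <- findSpacedSeeds(s1, s2, c(p1 = "10101", p2 = "11001"),
                        maxPerKmer = Inf)
  df <- as.data.frame(sd)
  expect_equal(anyDuplicated(df[c("pos1", "pos2")]), 0)
  raw <- findSpacedSeeds(s1, s2, c(p1 = "10101", p2 = "11001"),
                         maxPerKmer = Inf, dedup = FALSE)
  expect_gt(length(raw), length(sd))
})

test_that("subsampling returns the full product under the cap", {
  got <- subsamplePairs(c(10, 20), c(1, 2, 3), maxPairs = 10)
  expect_equal(nrow(got), 6)
  expect_setequal(paste(got$a, got$b),
                  paste(rep(c(10, 20), 3), rep(c(1, 2, 3), each = 2)))
})

test_that("subsampling draws exactly maxPairs distinct pairs uniformly", {
  set.seed(2024)
  occ1 <- 1:4; occ2 <- 1:4
  tally <- matrix(0, 4, 4)
  nDraw <- 20000
  sizesOk <- TRUE; distinctOk <- TRUE
  for (i in seq_len(nDraw)) {
    s <- subsamplePairs(occ1, occ2, maxPairs = 10)
    sizesOk <- sizesOk && nrow(s) == 10
    distinctOk <- distinctOk && anyDuplicated(paste(s$a, s$b)) == 0
    tally[cbind(s$a, s$b)] <- tally[cbind(s$a, s$b)] + 1
  }
  expect_true(sizesOk)        # every draw has exactly maxPairs pairs
  expect_true(distinctOk)     # and no pair repeats within a draw
  # each of the 16 pairs kept with probability 10/16
  p <- 10 / 16
  tol <- 5 * sqrt(nDraw * p * (1 - p))
  expect_true(all(abs(tally - nDraw * p) < tol))
})

test_that("random match counts agree with the analytic i.i.d. expectation", {
  # single spaced pattern on 30 kb vs 30 kb, three seeds
  p <- seedPattern("101101010111")          # weight 8, span 12
  exp <- expectedRandomMatches(30000, 30000, 1, patternWeight(p))
  for (sd in 1:3) {
    seqs1 <- randomSeqSet(30000, "gA", "r", seed = 100 + sd)
    seqs2 <- randomSeqSet(30000, "gB", "q", seed = 200 + sd)
    got <- findSpacedSeeds(seqs1, seqs2, patternSet(list(p)),
                           maxPerKmer = Inf)
    expect_lt(abs(length(got) - exp), 5 * sqrt(exp))
  }
})

test_that("expectedRandomMatches follows its closed form", {
  expect_equal(expectedRandomMatches(62.348e6, 56.197e6, 4, 15),
               4 * 62.348e6 * 56.197e6 / 4^15)
  expect_equal(expectedRandomMatches(1e6, 1e6, 4, 10) /
                 expectedRandomMatches(1e6, 1e6, 1, 10), 4)
  expect_equal(expectedRandomMatches(1e6, 1e6, 1, 11) /
                 expectedRandomMatches(1e6, 1e6, 1, 12), 4)
})

test_that("seed finding is deterministic given the rng seed", {
  seqs1 <- randomSeqSet(c(4000, 3000), "gA", "a", seed = 9)
  seqs2 <- randomSeqSet(c(3500, 2500), "gB", "b", seed = 10)
  a <- findSpacedSeeds(seqs1, seqs2, "1011", maxPerKmer = 3, rngSeed = 5)
  b <- findSpacedSeeds(seqs1, seqs2, "1011", maxPerKmer = 3, rngSeed = 5)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("multi-genome candidates require the k-mer in every genome", {
  s1 <- maskedSeqSet(c(a = "AACGTT"), "g1")
  s2 <- maskedSeqSet(c(b = "TACGTA"), "g2")
  s3 <- maskedSeqSet(c(c = "CACGTC"), "g3")
  sd <- findMultiGenomeSeeds(list(s1, s2, s3), "1111")
  df <- as.data.frame(sd)
  # ACGT is the only shared 4-mer, at window start 1 in each -> midpoint 3
  expect_equal(nrow(df), 1)
  expect_equal(c(df$pos1, df$pos2, df$pos3), c(3, 3, 3))
  # s = 2 reduces to pairwise matching
  two <- findMultiGenomeSeeds(list(s1, s2), "1111")
  pair <- findSpacedSeeds(s1, s2, "1111")
  expect_equal(as.data.frame(two)[c("pos1", "pos2")],
               as.data.frame(pair)[c("pos1", "pos2")])
})
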