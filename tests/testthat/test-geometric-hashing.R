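test_that("the geometric map quantizes diagonal offsets with floor toward -Inf", {
  mk <- function(i, j) pairSeeds(i, j)
  expect_equal(geometricMap(mk(13000, 0), 10000)$off1, 1)
  expect_equal(geometricMap(mk(0, 15000), 10000)$off1, -2)
  expect_equal(geometricMap(mk(123456, 123456), 7777)$off1, 0)
  expect_equal(geometricMap(mk(9999, 0), 10000)$off1, 0)
  expect_equal(geometricMap(mk(10000, 0), 10000)$off1, 1)
  expect_equal(geometricMap(mk(0, 1), 10000)$off1, -1)
})

test_that("the multi-genome map generalizes and reduces to the pairwise map", {
  three <- seedSet(matrix(c("a", "b", "c"), 1),
                   matrix(c(50000, 37000, 61000), 1),
                   genomeLabels = c("g1", "g2", "g3"))
  m <- multiGenomeMap(three, 10000)
  expect_equal(c(m$off1, m$off2), c(1, -2))
  # shifting every coordinate by the same delta leaves the key unchanged
  shifted <- seedSet(matrix(c("a", "b", "c"), 1),
                     matrix(c(50000, 37000, 61000) + 12345, 1),
                     genomeLabels = c("g1", "g2", "g3"))
  expect_equal(multiGenomeMap(shifted, 10000), m)
  # s = 2 case equals geometricMap
  pair <- pairSeeds(13000, 0)
  expect_equal(multiGenomeMap(pair, 10000), geometricMap(pair, 10000))
})

test_that("any two members of one tile differ in diagonal by less than F", {
  set.seed(15)
  n <- 3000
  sd <- pairSeeds(sample(0:2e5, n, TRUE), sample(0:2e5, n, TRUE))
  FF <- 10000
  key <- geometricMap(sd, FF)$off1
  d <- sd@positions[, 1] - sd@positions[, 2]
  for (o in unique(key)) {
    dd <- d[key == o]
    expect_lt(max(dd) - min(dd), FF)
  }
})

test_that("chunk assignment follows the worked formulas", {
  params <- ghParams()   # F = 10000, b = 50, h = 400
  # i = 25000, j = 12000: t* = 10000, d = 3000 -> sub-tile 15, chunk 92
  ac <- assignChunk(pairSeeds(25000, 12000), params)
  expect_equal(ac$subTile, 15)
  expect_equal(ac$chunk, 92)
  # d = 0 -> sub-tile 0; d = F - 1 -> sub-tile b - 1
  expect_equal(assignChunk(pairSeeds(10000, 10000), params)$subTile, 0)
  expect_equal(assignChunk(pairSeeds(19999, 10000), params)$subTile, 49)
  expect_equal(assignChunk(pairSeeds(0, 0), params)$chunk, 0)
  # sub-tile index is always within 0..b-1, also on negative diagonals
  set.seed(3)
  sd <- pairSeeds(sample(0:5e4, 500, TRUE), sample(0:5e4, 500, TRUE))
  st <- assignChunk(sd, params)$subTile
  expect_true(all(st >= 0 & st <= 49))
})

test_that("closed-form smax equals the brute-force band scan", {
  params <- ghParams(tileSize = 100, chunkLength = 7)
  set.seed(21)
  for (rep in 1:25) {
    len1 <- sample(50:400, 1); len2 <- sample(50:400, 1)
    off <- sample(-4:3, 1)
    bf <- tryCatch(oracleSmax(len1, len2, off, 100, 7), error = function(e) NA)
    if (is.na(bf)) {
      expect_error(computeSmax(c(len1, len2), off, params), "outside")
    } else {
      expect_equal(computeSmax(c(len1, len2), off, params), bf)
    }
  }
  # multi-genome closed form agrees with the pairwise one at s = 2
  expect_equal(computeSmax(c(300, 200), 1, params),
               oracleSmax(300, 200, 1, 100, 7))
})

test_that("smax endpoints behave as documented", {
  params <- ghParams(tileSize = 10000, chunkLength = 400)
  # 100 kb square, offset 0: best i + j = (99999) + (99999 - 0) constrained
  expect_equal(computeSmax(c(1e5, 1e5), 0, params),
               oracleSmax(1e5, 1e5, 0, 10000, 400))
  # chunk longer than both sequences -> smax 0
  expect_equal(computeSmax(c(50, 60), 0, ghParams(tileSize = 100,
                                                  chunkLength = 1000)), 0)
  # doubling h (roughly) halves smax
  s1 <- computeSmax(c(1e5, 1e5), 0, ghParams(chunkLength = 400))
  s2 <- computeSmax(c(1e5, 1e5), 0, ghParams(chunkLength = 800))
  expect_lte(abs(s1 / 2 - s2), 1)
})

test_that("lambda and tile scores follow the closed forms", {
  params <- ghParams()
  expect_equal(computeLambda(params, 1, c(1, 1)), 80000)    # A = h F / b
  expect_equal(computeLambda(params, 0, c(1e6, 1e6)), 0)
  expect_equal(computeLambda(params, 10, c(1e6, 2e6)) /
                 computeLambda(params, 5, c(1e6, 2e6)), 2)
  expect_error(computeLambda(params, 5, c(0, 1)), "")

  # all candidates in one chunk: score = c / (lambda * b * (smax + 1))
  for (c0 in c(1, 7, 100)) {
    sc <- scoreTile(c0, params, lambda = 0.01, smax = 99)
    expect_equal(sc, c0 / (0.01 * 50 * 100))
  }
  expect_equal(scoreTile(numeric(0), params, 0.01, 99), 0)
  expect_error(scoreTile(5, params, 0, 99), "lambda")

  # splitting c candidates evenly over q chunks divides the p-norm part
  # by q^(1 - 1/p)
  p <- params@pNorm
  for (q in c(2, 5, 10)) {
    single <- scoreTile(100, params, 0.01, 99)
    even <- scoreTile(rep(100 / q, q), params, 0.01, 99)
    expect_equal(even, single / q^(1 - 1 / p))
  }
})

test_that("tile grouping equals per-candidate recomputation of the map", {
  set.seed(8)
  n <- 5000
  ids1 <- sample(c("a1", "a2"), n, TRUE)
  ids2 <- sample(c("b1", "b2"), n, TRUE)
  sd <- seedSet(cbind(ids1, ids2),
                cbind(sample(0:9e4, n, TRUE), sample(0:9e4, n, TRUE)),
                genomeLabels = c("gA", "gB"))
  sd <- dedupSeeds(sd)
  lens <- c(a1 = 1e5, a2 = 1e5, b1 = 1e5, b2 = 1e5)
  res <- runGeometricHashing(sd, lens, ghParams(tauScore = 0))
  # every candidate is in exactly one tile and totals add up
  expect_equal(sum(res$tiles$nMembers), length(sd))
  naive <- geometricMap(sd, 10000)
  naiveCount <- table(paste(naive$seqId1, naive$seqId2, naive$off1))
  gotCount <- setNames(res$tiles$nMembers,
                       paste(res$tiles$seqId1, res$tiles$seqId2,
                             res$tiles$off1))
  expect_equal(gotCount[names(naiveCount)],
               setNames(as.numeric(naiveCount), names(naiveCount)))
})

test_that("tauScore = 0 is the identity filter and output is always a subset", {
  set.seed(12)
  n <- 800
  sd <- dedupSeeds(pairSeeds(sample(0:5e4, n, TRUE), sample(0:5e4, n, TRUE)))
  lens <- c(s1 = 6e4, s2 = 6e4)
  res0 <- runGeometricHashing(sd, lens, ghParams(tauScore = 0))
  expect_equal(as.data.frame(res0$seeds)[c("pos1", "pos2")],
               as.data.frame(sortSeeds(sd))[c("pos1", "pos2")])
  expect_equal(seedStage(res0$seeds), "ghash-pass")
  resT <- runGeometricHashing(sd, lens, ghParams(tauScore = 1))
  keyOf <- function(x) paste(x@positions[, 1], x@positions[, 2])
  expect_true(all(keyOf(resT$seeds) %in% keyOf(sd)))
})

test_that("adding a candidate to a chunk never decreases the tile score", {
  params <- ghParams()
  base <- c(4, 2, 1)
  for (add in 1:3) {
    more <- base; more[add] <- more[add] + 1
    expect_gt(scoreTile(more, params, 0.01, 99),
              scoreTile(base, params, 0.01, 99))
  }
  expect_gt(scoreTile(c(4, 2, 1, 1), params, 0.01, 99),
            scoreTile(c(4, 2, 1), params, 0.01, 99))
})

test_that("clustered candidates outscore scattered ones and thresholding separates them", {
  # tile A: 100 candidates on few chunks of one diagonal; tile B: 1 lone seed
  set.seed(5)
  posA <- 20000 + sort(sample(0:1500, 100))
  sdA <- pairSeeds(posA, posA - 500)             # diag 500 -> off 0
  sdB <- pairSeeds(70000, 95000)                 # off -3
  sd <- dedupSeeds(seedSet(rbind(sdA@seqIds, sdB@seqIds),
                           rbind(sdA@positions, sdB@positions),
                           genomeLabels = c("gA", "gB")))
  lens <- c(s1 = 1e5, s2 = 1e5)
  res <- runGeometricHashing(sd, lens, ghParams(tauScore = 0))
  tl <- res$tiles
  scoreA <- tl$score[tl$off1 == 0]
  scoreB <- tl$score[tl$off1 == -3]
  expect_gt(scoreA, scoreB)
  tau <- sqrt(scoreA * scoreB)
  resT <- runGeometricHashing(sd, lens, ghParams(tauScore = tau))
  expect_equal(length(resT$seeds), 100)
  expect_true(all(resT$seeds@positions[, 1] %in% posA))
})

test_that("multi-genome and pairwise paths agree on identical input at s = 2", {
  set.seed(9)
  n <- 500
  sd <- dedupSeeds(pairSeeds(sample(0:4e4, n, TRUE), sample(0:4e4, n, TRUE)))
  lens <- c(s1 = 5e4, s2 = 5e4)
  params <- ghParams(tauScore = 0.5)
  res <- runGeometricHashing(sd, lens, params)
  # force the generic multi-genome smax path via computeSmax on each tile
  for (r in seq_len(nrow(res$tiles))) {
    expect_equal(computeSmax(c(5e4, 5e4), res$tiles$off1[r], params),
                 res$tiles$smax[r])
  }
})

test_that("two-step filtering restricts pass-2 seeds to selected tiles", {
  set.seed(61)
  # a planted shared block gives dense high-weight matches in one tile
  block <- paste(sample(c("A", "C", "G", "T"), 4000, TRUE), collapse = "")
  flank1 <- paste(sample(c("A", "C", "G", "T"), 12000, TRUE), collapse = "")
  flank2 <- paste(sample(c("A", "C", "G", "T"), 30000, TRUE), collapse = "")
  s1 <- maskedSeqSet(setNames(paste0(flank1, block,
                                     substr(flank2, 1, 8000)), "h1"), "gA")
  s2 <- maskedSeqSet(setNames(paste0(substr(flank2, 8001, 30000), block,
                                     flank1), "m1"), "gB")
  high <- examplePatternSet(19)[[1]]
  low <- examplePatternSet(8)
  params <- ghParams(tauScore = 0)
  res <- twoStepGeometricHashing(s1, s2, high, low, tauPrime = 3,
                                 params = params, rngSeed = 3)
  expect_gt(length(res$seeds), 0)
  # offsets of emitted seeds lie inside the selected (expanded) tile set
  offs <- geometricMap(res$seeds, params@tileSize)$off1
  expect_true(all(offs %in% res$selectedTiles$off1))
  # the block diagonal is 12000 - 22000 = -10000 -> offset -1 selected
  expect_true(-1 %in% res$selectedTiles$off1)
  # weight ordering is enforced
  expect_error(twoStepGeometricHashing(s1, s2, examplePatternSet(8)[[1]],
                                       low, params = params), "exceed")
})

test_that("a vacuous pre-filter makes the two-step equal plain geometric hashing", {
  set.seed(62)
  seqs1 <- randomSeqSet(20000, "gA", "u")
  seqs2 <- randomSeqSet(20000, "gB", "v")
  params <- ghParams(tauScore = 0)
  low <- examplePatternSet(8)
  two <- twoStepGeometricHashing(seqs1, seqs2, examplePatternSet(19)[[1]],
                                 low, tauPrime = 1, params = params,
                                 rngSeed = 4)
  # tauPrime = 1 selects every tile the high pattern hits (plus neighbours);
  # compare against the unrestricted run limited to those same tiles
  plain <- findSpacedSeeds(seqs1, seqs2, low, rngSeed = 4)
  offsPlain <- geometricMap(plain, params@tileSize)$off1
  inSel <- offsPlain %in% two$selectedTiles$off1
  expect_equal(length(two$seeds), sum(inSel))
})
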