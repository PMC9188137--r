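# Geometric hashing of seed candidates: quantize diagonal offsets into
# tiles, score tiles by a normalized p-norm over (sub-tile, chunk)
# candidate counts, threshold, and report the members of passing tiles.

#' Construct geometric hashing parameters
#'
#' @param tileSize Tile size `F` in bp (default 10000, sized for
#'   vertebrate intron-length variation).
#' @param nSubTiles Number of sub-tiles `b` per tile (default 50).
#' @param chunkLength Chunk length `h` in bp along the anti-diagonal
#'   (default 400).
#' @param pNorm Norm exponent `p` (default 6): larger values let the
#'   fullest chunks dominate the tile score.
#' @param tauScore Tile score threshold (default 0 = identity filter;
#'   see [calibrateScoreThreshold()]).
#' @return A [GHParams-class].
#' @export
ghParams <- function(tileSize = 10000, nSubTiles = 50, chunkLength = 400,
                     pNorm = 6, tauScore = 0) {
  new("GHParams", tileSize = as.numeric(tileSize),
      nSubTiles = as.numeric(nSubTiles),
      chunkLength = as.numeric(chunkLength), pNorm = as.numeric(pNorm),
      tauScore = as.numeric(tauScore))
}

setMethod("show", "GHParams", function(object) {
  cat(sprintf(
    "GHParams: F=%g bp, b=%g sub-tiles, h=%g bp chunks, p=%g, tau=%g\n",
    object@tileSize, object@nSubTiles, object@chunkLength, object@pNorm,
    object@tauScore))
})

#' Map seeds to tiles
#'
#' The geometric map sends a pairwise seed `(S1, i, S2, j)` to the tile
#' `(S1, S2, floor((i - j)/F))`; floors are toward minus infinity, so any
#' two seeds of one tile satisfy `|(i - j) - (i' - j')| < F`. For an
#' s-genome seed the key is the s sequence ids plus the `s - 1` floored
#' differences `floor((i_1 - i_g)/F)` against the first (reference)
#' genome.
#'
#' @param x A [SeedSet-class].
#' @param tileSize Tile size `F` in bp.
#' @return data.frame with the `seqId<g>` columns and offset columns
#'   `off1..off<s-1>`, one row per seed.
#' @examples
#' s <- seedSet(matrix(c("s1", "s2"), 1), matrix(c(13000, 0), 1),
#'              genomeLabels = c("gA", "gB"))
#' geometricMap(s, 10000)   # offset 1
#' @export
geometricMap <- function(x, tileSize = 10000) {
  s <- nGenomes(x)
  stopifnot(tileSize > 0, s >= 2)
  out <- as.data.frame(x)[, paste0("seqId", seq_len(s)), drop = FALSE]
  for (g in 2:s) {
    out[[paste0("off", g - 1L)]] <-
      floor((x@positions[, 1] - x@positions[, g]) / tileSize)
  }
  out
}

#' @rdname geometricMap
#' @export
multiGenomeMap <- geometricMap

# internal: add off columns to a seed data.table in place
.addTileCols <- function(dt, s, tileSize) {
  for (g in 2:s) {
    dt[, (paste0("off", g - 1L)) :=
         floor((pos1 - get(paste0("pos", g))) / tileSize)]
  }
  c(paste0("seqId", seq_len(s)), paste0("off", seq_len(s - 1L)))
}

#' Assign seeds to sub-tiles and chunks
#'
#' Within its tile, a pairwise seed with diagonal remainder
#' `d = (i - j) - F * floor((i - j)/F)` falls in sub-tile
#' `floor(d * b / F)` (in `0..b-1`) and in chunk `floor((i + j)/h)` along
#' the anti-diagonal. Multi-genome seeds use the first difference
#' `i_1 - i_2` for the sub-tile and `floor(sum(i_g)/h)` for the chunk.
#'
#' @param x A [SeedSet-class].
#' @param params A [GHParams-class].
#' @return data.frame with columns `subTile` and `chunk`.
#' @export
assignChunk <- function(x, params) {
  stopifnot(nGenomes(x) >= 2)
  FF <- params@tileSize
  diff1 <- x@positions[, 1] - x@positions[, 2]
  d <- diff1 - FF * floor(diff1 / FF)
  data.frame(subTile = floor(d * params@nSubTiles / FF),
             chunk = floor(rowSums(x@positions) / params@chunkLength))
}

#' Maximal chunk index of a tile
#'
#' `smax` is the largest chunk index any admissible position tuple of the
#' tile can reach: the maximum of `floor(sum(i_g)/h)` over positions
#' within the sequence bounds whose differences map to the tile's
#' offsets. Computed in closed form (the objective increases along the
#' diagonal direction, so the optimum pins the reference position at the
#' smallest of the per-genome upper limits).
#'
#' @param seqLens Lengths of the tile's member sequences, in genome
#'   order (length `s`).
#' @param offsets The tile's quantized difference offsets (length
#'   `s - 1`; a single number for pairwise tiles).
#' @param params A [GHParams-class].
#' @return Integer chunk index `smax >= 0`.
#' @export
computeSmax <- function(seqLens, offsets, params) {
  s <- length(seqLens)
  stopifnot(s >= 2, length(offsets) == s - 1)
  FF <- params@tileSize
  uppers <- c(seqLens[1] - 1, seqLens[-1] - 1 + (offsets + 1) * FF - 1)
  lowers <- c(0, offsets * FF)
  i1 <- min(uppers)
  if (i1 < max(lowers))
    stop("tile band lies entirely outside the sequence rectangle")
  total <- i1 + sum(pmin(seqLens[-1] - 1, i1 - offsets * FF))
  floor(total / params@chunkLength)
}

# vectorized pairwise smax over tiles
.smaxPairwise <- function(len1, len2, off, params) {
  FF <- params@tileSize
  i1 <- pmin(len1 - 1, len2 - 1 + (off + 1) * FF - 1)
  lo <- pmax(0, off * FF)
  bad <- i1 < lo
  if (any(bad))
    stop("tile band lies entirely outside the sequence rectangle")
  floor((i1 + pmin(len2 - 1, i1 - off * FF)) / params@chunkLength)
}

#' Expected candidates per chunk under uniform scatter
#'
#' `lambda = A * L / (n1 * n2)` with chunk area `A = h * F / b`: the
#' expected number of the run's `L` seed candidates falling into one
#' chunk if they were scattered evenly over the pairwise alignment space
#' of total size `n1 * n2`. For `s > 2` genomes the chunk volume
#' generalizes to `A = h * F^(s-1) / b` over the product of the genome
#' totals.
#'
#' @param params A [GHParams-class].
#' @param L Total number of observed seed candidates in the run.
#' @param genomeTotals Total bp per genome (length `s >= 2`).
#' @return `lambda` (double).
#' @export
computeLambda <- function(params, L, genomeTotals) {
  stopifnot(length(genomeTotals) >= 2, all(genomeTotals > 0), L >= 0)
  s <- length(genomeTotals)
  A <- params@chunkLength * params@tileSize^(s - 1) / params@nSubTiles
  A * L / prod(genomeTotals)
}

#' Score a tile
#'
#' `Score(t) = (sum_r sum_s n_rs^p)^(1/p) / (lambda * b * (smax + 1))`:
#' the p-norm of the per-(sub-tile, chunk) candidate counts, normalized
#' by `lambda` times the number of chunks of the tile. Candidates that
#' cluster on few chunks score higher than the same number scattered
#' evenly.
#'
#' @param chunkCounts Numeric vector of per-(sub-tile, chunk) counts
#'   (zeros may be omitted; they do not contribute).
#' @param params A [GHParams-class].
#' @param lambda Normalization from [computeLambda()]; must be > 0.
#' @param smax Maximal chunk index from [computeSmax()].
#' @return Score (double, >= 0); 0 for an empty tile.
#' @export
scoreTile <- function(chunkCounts, params, lambda, smax) {
  if (lambda <= 0)
    stop("lambda must be > 0 (normalization undefined)")
  .pnorm(chunkCounts, params@pNorm) /
    (lambda * params@nSubTiles * (smax + 1))
}

# overflow-safe p-norm
.pnorm <- function(v, p) {
  v <- v[v > 0]
  if (!length(v)) return(0)
  m <- max(v)
  m * sum((v / m)^p)^(1 / p)
}

# resolve seqLengths argument: named numeric, MaskedSeqSet, or list of them
.resolveSeqLengths <- function(x) {
  if (is(x, "MaskedSeqSet")) return(seqLengths(x))
  if (is.list(x) && all(vapply(x, is, logical(1), class2 = "MaskedSeqSet")))
    return(do.call(c, lapply(x, seqLengths)))
  if (is.numeric(x) && !is.null(names(x)))
    return(x)
  stop("seqLengths must be a named numeric vector, a MaskedSeqSet, ",
       "or a list of MaskedSeqSet objects")
}

#' Run geometric hashing on seed candidates
#'
#' Groups candidates by tile, computes `lambda` from the total candidate
#' count `L`, scores every tile and returns the union of the members of
#' tiles whose score reaches `params@tauScore`, together with a tile
#' report. With `tauScore = 0` the filter is the identity.
#'
#' @param x A [SeedSet-class] (pairwise or multi-genome).
#' @param seqLengths Named lengths (bp) of every sequence occurring in
#'   `x`; alternatively a [MaskedSeqSet-class] or list of them.
#' @param params A [GHParams-class].
#' @param genomeTotals Total bp per genome for the `lambda`
#'   normalization. Default: per-genome sums of `seqLengths` over the ids
#'   seen in the corresponding coordinate column; pass explicitly when
#'   the run's input contained sequences that produced no candidates.
#' @return List with `seeds` (a [SeedSet-class], stage `"ghash-pass"`)
#'   and `tiles` (data.frame: tile key, member count, `smax`, score,
#'   pass flag).
#' @export
runGeometricHashing <- function(x, seqLengths, params = ghParams(),
                                genomeTotals = NULL) {
  seqLengths <- .resolveSeqLengths(seqLengths)
  s <- nGenomes(x)
  stopifnot(s >= 2)
  allIds <- unique(as.vector(x@seqIds))
  missing <- setdiff(allIds, names(seqLengths))
  if (length(missing))
    stop("seqLengths missing for: ", paste(head(missing, 5), collapse = ", "))
  if (length(x) == 0) {
    out <- x; out@stage <- "ghash-pass"
    return(list(seeds = out, tiles = data.frame()))
  }
  if (is.null(genomeTotals)) {
    genomeTotals <- vapply(seq_len(s), function(g)
      sum(seqLengths[unique(x@seqIds[, g])]), numeric(1))
  }
  L <- length(x)
  lambda <- computeLambda(params, L, genomeTotals)
  dt <- .seedDT(x)
  tileCols <- .addTileCols(dt, s, params@tileSize)
  ac <- assignChunk(x, params)
  dt[, subTile := ac$subTile]
  dt[, chunk := ac$chunk]
  counts <- dt[, .N, by = c(tileCols, "subTile", "chunk")]
  p <- params@pNorm
  tiles <- counts[, .(nMembers = sum(N), pnorm = .pnorm(N, p)),
                  by = tileCols]
  # smax per tile from the member sequences' lengths
  if (s == 2) {
    tiles[, smax := .smaxPairwise(seqLengths[seqId1], seqLengths[seqId2],
                                  off1, params)]
  } else {
    tiles[, smax := vapply(seq_len(.N), function(r) {
      lens <- seqLengths[unlist(.SD[r, paste0("seqId", seq_len(s)),
                                    with = FALSE])]
      offs <- unlist(.SD[r, paste0("off", seq_len(s - 1L)), with = FALSE])
      computeSmax(lens, offs, params)
    }, numeric(1))]
  }
  tiles[, score := pnorm / (lambda * params@nSubTiles * (smax + 1))]
  tiles[, pass := score >= params@tauScore]
  setorderv(tiles, tileCols)
  passing <- tiles[pass == TRUE, tileCols, with = FALSE]
  kept <- dt[passing, on = tileCols, nomatch = NULL]
  out <- sortSeeds(x[sort(kept$idx)])
  out@stage <- "ghash-pass"
  rep <- as.data.frame(tiles[, c(tileCols, "nMembers", "smax", "score",
                                 "pass"), with = FALSE])
  list(seeds = out, tiles = rep)
}

#' Calibrate the tile score threshold on a simulated null
#'
#' Simulates i.i.d. uniform sequence pairs of the same per-genome lengths
#' as the intended input, runs the same seed finding and tile scoring,
#' and returns the smallest threshold at which no null tile passes —
#' the maximum null tile score times a safety `margin`. A single null
#' replicate underestimates the upper tail of the extreme statistic (the
#' maximum per-chunk count of a sparse null typically fluctuates by one,
#' rescaling the maximum score by up to ~1.5), so the default takes the
#' max over `nrep = 3` replicates and multiplies by 1.5.
#'
#' @param lengths1,lengths2 Sequence lengths (bp) of the two genomes'
#'   inputs.
#' @param patterns Pattern set used for seed finding.
#' @param params A [GHParams-class] (its `tauScore` is ignored).
#' @param maxPerKmer Subsampling cap, as in [findSpacedSeeds()].
#' @param nrep Number of null replicates.
#' @param margin Safety factor applied to the maximum null score.
#' @param rngSeed RNG seed for the null simulations.
#' @return Calibrated threshold (double); 0 when no null tile arises.
#' @export
calibrateScoreThreshold <- function(lengths1, lengths2, patterns,
                                    params = ghParams(), maxPerKmer = 10,
                                    nrep = 3, margin = 1.5, rngSeed = NULL) {
  if (!is(patterns, "PatternSet")) patterns <- patternSet(patterns)
  .withSeed(rngSeed, {
    maxScore <- 0
    for (r in seq_len(nrep)) {
      sim <- simulateNegativePairs(lengths1, lengths2,
                                   genomeLabels = c("null1", "null2"))
      cand <- findSpacedSeeds(sim$seqs1, sim$seqs2, patterns,
                              maxPerKmer = maxPerKmer)
      if (length(cand) == 0) next
      res <- runGeometricHashing(
        cand, c(seqLengths(sim$seqs1), seqLengths(sim$seqs2)),
        params, genomeTotals = c(sum(lengths1), sum(lengths2)))
      if (nrow(res$tiles))
        maxScore <- max(maxScore, res$tiles$score)
    }
    maxScore * margin
  })
}

#' Two-step (coarse-to-fine) geometric hashing
#'
#' Pass 1 finds candidates with a single high-weight pattern (weight
#' `k' > k`; specific but insensitive), maps them to tiles, and selects
#' the tile set `T'` of tiles holding at least `tauPrime` candidates,
#' expanded by the offset neighbours `t - 1` and `t + 1` of each selected
#' tile. Pass 2 runs normal spaced-seed finding with the sensitive
#' low-weight pattern set, discards candidates whose tile is not in
#' `T'`, and applies the usual tile scoring and threshold.
#'
#' @inheritParams findSpacedSeeds
#' @param highPattern A [SeedPattern-class] of weight `k'`.
#' @param tauPrime Minimum pass-1 candidate count for a tile to enter
#'   `T'` (default 3).
#' @param lowPatterns [PatternSet-class] of weight `k < k'`.
#' @param params A [GHParams-class] (including the pass-2 score
#'   threshold).
#' @return List with `seeds`, `tiles` (as [runGeometricHashing()]) and
#'   `selectedTiles` (the expanded `T'`).
#' @export
twoStepGeometricHashing <- function(seqs1, seqs2, highPattern,
                                    lowPatterns, tauPrime = 3,
                                    params = ghParams(), maxPerKmer = 10,
                                    maskFilter = TRUE, rngSeed = NULL) {
  if (is.character(highPattern)) highPattern <- seedPattern(highPattern)
  if (is(highPattern, "PatternSet")) {
    stopifnot(length(highPattern) == 1)
    highPattern <- highPattern[[1]]
  }
  if (!is(lowPatterns, "PatternSet")) lowPatterns <- patternSet(lowPatterns)
  if (highPattern@weight <= patternWeight(lowPatterns))
    stop("the first-pass weight k' (", highPattern@weight,
         ") must exceed the second-pass weight k (",
         patternWeight(lowPatterns), ")")
  stopifnot(tauPrime >= 1)
  seqLens <- c(seqLengths(seqs1), seqLengths(seqs2))
  pass1 <- findSpacedSeeds(seqs1, seqs2, patternSet(list(highPattern)),
                           maxPerKmer = maxPerKmer,
                           maskFilter = maskFilter, rngSeed = rngSeed)
  keyCols <- c("seqId1", "seqId2", "off1")
  selected <- data.table(seqId1 = character(0), seqId2 = character(0),
                         off1 = numeric(0))
  if (length(pass1) > 0) {
    t1 <- as.data.table(geometricMap(pass1, params@tileSize))
    raw <- t1[, .N, by = keyCols][N >= tauPrime]
    if (nrow(raw)) {
      selected <- rbindlist(lapply(c(-1, 0, 1), function(dlt) {
        nb <- copy(raw[, keyCols, with = FALSE]); nb[, off1 := off1 + dlt]; nb
      }))
      selected <- unique(selected)
      setorderv(selected, keyCols)
    }
  }
  pass2 <- findSpacedSeeds(seqs1, seqs2, lowPatterns,
                           maxPerKmer = maxPerKmer,
                           maskFilter = maskFilter, rngSeed = rngSeed)
  if (length(pass2) > 0 && nrow(selected) > 0) {
    t2 <- as.data.table(geometricMap(pass2, params@tileSize))
    t2[, idx := .I]
    keepIdx <- t2[selected, on = keyCols, nomatch = NULL]$idx
    pass2 <- pass2[sort(keepIdx)]
  } else if (nrow(selected) == 0) {
    pass2 <- pass2[integer(0)]
  }
  res <- runGeometricHashing(pass2, seqLens, params,
                             genomeTotals = c(sum(seqLengths(seqs1)),
                                              sum(seqLengths(seqs2))))
  res$selectedTiles <- as.data.frame(selected)
  res
}
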