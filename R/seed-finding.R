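# Seed candidate generation: exact contiguous k-mer matching and (multiple)
# spaced-seed matching over a primary hash of induced k-mers, with the
# per-k-mer subsampling cap and repeat-mask/ambiguity filtering.

# evaluate expr with a locally-set RNG seed, restoring the caller's state
.withSeed <- function(rngSeed, expr) {
  if (is.null(rngSeed)) return(expr)
  hasSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hasSeed) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (hasSeed) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(rngSeed)
  expr
}

.genomeLabelOf <- function(seqs, what) {
  g <- unique(unname(genomeLabels(seqs)))
  if (length(g) != 1)
    stop(what, " must contain sequences of a single genome label, found: ",
         paste(g, collapse = ", "))
  g
}

# occurrence table of one pattern over all sequences of a set:
# data.table(kmer = packed code, seqIdx, pos = 0-based window start)
.occurrenceDT <- function(seqs, pattern, maskFilter = TRUE) {
  res <- residues(seqs)
  out <- vector("list", length(res))
  for (i in seq_along(res)) {
    codes <- .windowCodes(res[[i]], pattern, maskFilter = maskFilter)
    valid <- which(!is.na(codes))
    out[[i]] <- data.table(kmer = codes[valid], seqIdx = i, pos = valid - 1L)
  }
  rbindlist(out)
}

#' Subsample the seed-candidate pairs of one k-mer
#'
#' If a k-mer occurs at positions `occ1` in genome 1 and `occ2` in genome
#' 2, it proposes `|occ1| * |occ2|` candidate position pairs. When that
#' product exceeds `maxPairs`, a uniform random subsample of exactly
#' `maxPairs` distinct pairs is drawn (without replacement, without
#' materializing the product); otherwise the full Cartesian product is
#' returned. The default cap of 10 limits the noise contributed by
#' repetitive k-mers; weight-12 runs conventionally relax it to 100.
#'
#' @param occ1,occ2 Position vectors (any numeric values).
#' @param maxPairs Cap (>= 1), default 10.
#' @return data.frame with columns `a` (from `occ1`) and `b` (from
#'   `occ2`).
#' @export
subsamplePairs <- function(occ1, occ2, maxPairs = 10) {
  stopifnot(maxPairs >= 1)
  n1 <- length(occ1); n2 <- length(occ2)
  if (n1 == 0 || n2 == 0)
    return(data.frame(a = numeric(0), b = numeric(0)))
  total <- as.numeric(n1) * n2
  if (total <= maxPairs) {
    ia <- rep(seq_len(n1), times = n2)
    ib <- rep(seq_len(n2), each = n1)
  } else {
    idx <- sample(total, maxPairs)
    ia <- ((idx - 1) %/% n2) + 1
    ib <- ((idx - 1) %% n2) + 1
  }
  data.frame(a = occ1[ia], b = occ2[ib])
}

# uniform subsample of tuples from the Cartesian product of s occurrence
# lists (multi-genome generalization of subsamplePairs); returns a matrix
# with one column per genome
.subsampleTuples <- function(occList, maxTuples) {
  ns <- lengths(occList)
  if (any(ns == 0)) return(matrix(numeric(0), 0, length(occList)))
  total <- prod(as.numeric(ns))
  s <- length(occList)
  if (total <= maxTuples) {
    grid <- as.matrix(expand.grid(lapply(ns, seq_len), KEEP.OUT.ATTRS = FALSE))
  } else {
    idx <- sample(total, maxTuples) - 1
    grid <- matrix(0, length(idx), s)
    for (g in seq_len(s)) {        # mixed-radix decode
      grid[, g] <- (idx %% ns[g]) + 1
      idx <- idx %/% ns[g]
    }
  }
  out <- matrix(0, nrow(grid), s)
  for (g in seq_len(s)) out[, g] <- occList[[g]][grid[, g]]
  out
}

# all matching position pairs of one pattern between two occurrence
# tables, with the per-k-mer cap applied across the Cartesian product
.matchOccurrences <- function(dt1, dt2, maxPerKmer) {
  empty <- data.table(seqIdx1 = integer(0), pos1 = integer(0),
                      seqIdx2 = integer(0), pos2 = integer(0))
  if (!nrow(dt1) || !nrow(dt2)) return(empty)
  c1 <- dt1[, .N, by = kmer]
  c2 <- dt2[, .N, by = kmer]
  cc <- c1[c2, on = "kmer", nomatch = NULL]
  setnames(cc, c("N", "i.N"), c("N1", "N2"))
  if (!nrow(cc)) return(empty)
  lightK <- cc[N1 * N2 <= maxPerKmer, kmer]
  heavyK <- sort(cc[N1 * N2 > maxPerKmer, kmer])
  parts <- list(empty)
  if (length(lightK)) {
    d1 <- dt1[kmer %in% lightK]
    d2 <- dt2[kmer %in% lightK]
    parts[[length(parts) + 1L]] <-
      d1[d2, on = "kmer", allow.cartesian = TRUE, nomatch = NULL,
         .(seqIdx1 = x.seqIdx, pos1 = x.pos,
           seqIdx2 = i.seqIdx, pos2 = i.pos)]
  }
  if (length(heavyK)) {
    o1 <- dt1[kmer %in% heavyK]; setkey(o1, kmer)
    o2 <- dt2[kmer %in% heavyK]; setkey(o2, kmer)
    for (kv in heavyK) {
      r1 <- o1[.(kv)]; r2 <- o2[.(kv)]
      pick <- subsamplePairs(seq_len(nrow(r1)), seq_len(nrow(r2)),
                             maxPerKmer)
      parts[[length(parts) + 1L]] <-
        data.table(seqIdx1 = r1$seqIdx[pick$a], pos1 = r1$pos[pick$a],
                   seqIdx2 = r2$seqIdx[pick$b], pos2 = r2$pos[pick$b])
    }
  }
  rbindlist(parts)
}

#' Find spaced-seed candidates between two genomes
#'
#' For each pattern, induced k-mers of genome 1 are indexed and genome 2
#' is streamed against the index; a match of pattern `p` at window starts
#' `(a, b)` yields the midpoint seed `(a + floor(span/2), b +
#' floor(span/2))` in 0-based coordinates. Seeds identical in all
#' coordinates that arise from different patterns are de-duplicated; the
#' per-k-mer subsampling cap is applied per (pattern, k-mer). Output is
#' canonically sorted, hence independent of hash iteration order.
#'
#' @param seqs1,seqs2 [MaskedSeqSet-class] objects with distinct genome
#'   labels (all sequences of a set share one label).
#' @param patterns A [PatternSet-class], a single [SeedPattern-class], or
#'   a character vector of binary pattern strings.
#' @param maxPerKmer Per-k-mer candidate cap (default 10); `Inf` disables
#'   subsampling.
#' @param maskFilter Exclude windows whose match positions fall in
#'   softmasked sequence.
#' @param rngSeed Seed for the subsampling RNG (reproducibility); `NULL`
#'   uses the current RNG state.
#' @param dedup De-duplicate identical coordinates across patterns.
#' @return A [SeedSet-class] of stage `"candidate"`.
#' @examples
#' s1 <- maskedSeqSet(c(h1 = "ACGTA"), "gA")
#' s2 <- maskedSeqSet(c(m1 = "AGGTA"), "gB")
#' findSpacedSeeds(s1, s2, "10011")   # one seed at (2, 2)
#' @export
findSpacedSeeds <- function(seqs1, seqs2, patterns, maxPerKmer = 10,
                            maskFilter = TRUE, rngSeed = NULL,
                            dedup = TRUE) {
  if (!is(patterns, "PatternSet")) patterns <- patternSet(patterns)
  g1 <- .genomeLabelOf(seqs1, "seqs1")
  g2 <- .genomeLabelOf(seqs2, "seqs2")
  if (g1 == g2)
    stop("seqs1 and seqs2 must come from distinct genome labels, both are '",
         g1, "'")
  ids1 <- seqIds(seqs1); ids2 <- seqIds(seqs2)
  maxSpan <- patternSpan(patterns)
  if (maxSpan > max(c(seqLengths(seqs1), seqLengths(seqs2)))) {
    warning("pattern span ", maxSpan, " exceeds every sequence length; ",
            "no windows to match")
  }
  .withSeed(rngSeed, {
    parts <- vector("list", length(patterns))
    for (pi in seq_along(patterns@patterns)) {
      p <- patterns[[pi]]
      dt1 <- .occurrenceDT(seqs1, p, maskFilter = maskFilter)
      dt2 <- .occurrenceDT(seqs2, p, maskFilter = maskFilter)
      m <- .matchOccurrences(dt1, dt2, maxPerKmer)
      mid <- p@span %/% 2
      parts[[pi]] <- data.table(
        seqId1 = ids1[m$seqIdx1], pos1 = m$pos1 + mid,
        seqId2 = ids2[m$seqIdx2], pos2 = m$pos2 + mid,
        pattern = p@id)
    }
    dt <- rbindlist(parts)
    out <- .seedsFromDT(dt, genomeLabels = c(g1, g2), stage = "candidate")
    if (dedup) dedupSeeds(out) else sortSeeds(out)
  })
}

#' Find exact contiguous k-mer seeds
#'
#' The baseline method: an exact contiguous match of length `k` at window
#' starts `(a, b)` (after mask/ambiguity filtering) yields the midpoint
#' seed `(a + floor(k/2), b + floor(k/2))`. Equivalent to
#' [findSpacedSeeds()] with the contiguous pattern of weight `k`.
#'
#' @inheritParams findSpacedSeeds
#' @param k Match length (weight), `1 <= k <= 26`.
#' @return A [SeedSet-class].
#' @export
findContiguousSeeds <- function(seqs1, seqs2, k, maxPerKmer = 10,
                                maskFilter = TRUE, rngSeed = NULL) {
  stopifnot(k >= 1)
  p <- seedPattern(strrep("1", k), id = paste0("contig", k))
  findSpacedSeeds(seqs1, seqs2, patternSet(list(p)), maxPerKmer = maxPerKmer,
                  maskFilter = maskFilter, rngSeed = rngSeed)
}

#' Find multi-genome seed candidates
#'
#' Generalization to `s >= 2` genomes: a candidate requires the identical
#' induced k-mer in every genome. Per-genome occurrence lists of each
#' shared k-mer are intersected and their Cartesian product emitted, with
#' the same per-(pattern, k-mer) subsampling cap.
#'
#' @param seqsList List of [MaskedSeqSet-class] objects, one per genome,
#'   with pairwise distinct genome labels.
#' @inheritParams findSpacedSeeds
#' @return A [SeedSet-class] with one coordinate column per genome.
#' @export
findMultiGenomeSeeds <- function(seqsList, patterns, maxPerKmer = 10,
                                 maskFilter = TRUE, rngSeed = NULL,
                                 dedup = TRUE) {
  stopifnot(length(seqsList) >= 2)
  if (!is(patterns, "PatternSet")) patterns <- patternSet(patterns)
  labels <- vapply(seq_along(seqsList), function(g)
    .genomeLabelOf(seqsList[[g]], paste0("seqsList[[", g, "]]")),
    character(1))
  if (anyDuplicated(labels))
    stop("genome labels must be pairwise distinct")
  s <- length(seqsList)
  idsByG <- lapply(seqsList, seqIds)
  .withSeed(rngSeed, {
    parts <- list()
    for (pi in seq_along(patterns@patterns)) {
      p <- patterns[[pi]]
      dts <- lapply(seqsList, .occurrenceDT, pattern = p,
                    maskFilter = maskFilter)
      shared <- Reduce(intersect, lapply(dts, function(d) unique(d$kmer)))
      if (!length(shared)) next
      shared <- sort(shared)
      occ <- lapply(dts, function(d) {
        d <- d[kmer %in% shared]; setkey(d, kmer); d
      })
      mid <- p@span %/% 2
      for (kv in shared) {
        rows <- lapply(occ, function(d) d[.(kv)])
        tup <- .subsampleTuples(lapply(rows, function(r) seq_len(nrow(r))),
                                maxPerKmer)
        if (!nrow(tup)) next
        dt <- data.table(idx = seq_len(nrow(tup)))
        for (g in seq_len(s)) {
          r <- rows[[g]]
          dt[, (paste0("seqId", g)) := idsByG[[g]][r$seqIdx[tup[, g]]]]
          dt[, (paste0("pos", g)) := r$pos[tup[, g]] + mid]
        }
        dt[, pattern := p@id]
        parts[[length(parts) + 1L]] <- dt
      }
    }
    dt <- if (length(parts)) rbindlist(parts) else
      data.table()
    out <- .seedsFromDT(dt, genomeLabels = labels, stage = "candidate")
    if (dedup) dedupSeeds(out) else sortSeeds(out)
  })
}

#' Expected random match count under the i.i.d. uniform model
#'
#' For independent uniformly-random DNA of total lengths `n1` and `n2`
#' compared with `m` patterns of weight `k`, the expected number of
#' matching position pairs is `m * n1 * n2 / 4^k` (boundary effects of the
#' pattern span ignored). Serves as the analytic oracle for calibration
#' tests of the matching engine.
#'
#' @param n1,n2 Total bp per genome.
#' @param m Number of patterns.
#' @param k Pattern weight.
#' @return Expected count (double).
#' @export
expectedRandomMatches <- function(n1, n2, m, k) {
  stopifnot(n1 > 0, n2 > 0, m > 0, k > 0)
  m * n1 * n2 / 4^k
}
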