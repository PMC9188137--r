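# Fixture builders and independent brute-force oracles used across tests.

randomSeqSet <- function(lengths, genome, prefix = "s", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  seqs <- vapply(lengths, function(n)
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""),
    character(1))
  names(seqs) <- paste0(prefix, seq_along(seqs))
  maskedSeqSet(seqs, genome)
}

# character-level induced k-mer: an independent implementation of the
# pattern application, used as the oracle for the packed-code path
oracleInduce <- function(s, bits, start, maskFilter = TRUE) {
  pos <- which(strsplit(bits, "")[[1]] == "1")
  ch <- strsplit(s, "")[[1]][start + pos]
  if (maskFilter && any(ch %in% letters)) return(NA_character_)
  up <- toupper(ch)
  if (any(!up %in% c("A", "C", "G", "T"))) return(NA_character_)
  paste(up, collapse = "")
}

# all matching window-start pairs of one pattern between two single
# sequences, by exhaustive all-window comparison (no hashing, no cap)
oracleMatches <- function(s1, s2, bits, maskFilter = TRUE) {
  span <- nchar(bits)
  n1 <- nchar(s1) - span + 1
  n2 <- nchar(s2) - span + 1
  if (n1 < 1 || n2 < 1)
    return(data.frame(a = integer(0), b = integer(0)))
  k1 <- vapply(0:(n1 - 1), function(a) oracleInduce(s1, bits, a, maskFilter),
               character(1))
  k2 <- vapply(0:(n2 - 1), function(b) oracleInduce(s2, bits, b, maskFilter),
               character(1))
  hit <- which(outer(k1, k2, `==`), arr.ind = TRUE)  # NA == NA is NA -> dropped
  data.frame(a = hit[, 1] - 1L, b = hit[, 2] - 1L)
}

# midpoint seed coordinates from oracle matches, de-duplicated across
# patterns, canonically sorted
oracleSeedCoords <- function(s1, s2, bitsVec, maskFilter = TRUE) {
  out <- list()
  for (bits in bitsVec) {
    m <- oracleMatches(s1, s2, bits, maskFilter)
    mid <- nchar(bits) %/% 2
    out[[length(out) + 1L]] <- data.frame(pos1 = m$a + mid, pos2 = m$b + mid)
  }
  df <- unique(do.call(rbind, out))
  df[order(df$pos1, df$pos2), , drop = FALSE]
}

# O(n^2) all-pairs neighbouring-matches check on one sequence pair
oracleM4 <- function(pos1, pos2, D, tau, span, countSelf = TRUE) {
  n <- length(pos1)
  keep <- logical(n)
  for (i in seq_len(n)) {
    cnt <- if (countSelf) 1L else 0L
    for (j in seq_len(n)) {
      if (j == i) next
      if (pos1[i] - pos2[i] != pos1[j] - pos2[j]) next
      di <- abs(pos1[i] - pos1[j])
      if (di <= D / 2 && di >= span) cnt <- cnt + 1L
    }
    keep[i] <- cnt >= tau
  }
  keep
}

# brute-force smax: scan all admissible (i, j) pairs of a tile band
oracleSmax <- function(len1, len2, off, tileSize, chunkLength) {
  best <- -Inf
  for (i in 0:(len1 - 1)) {
    lo <- i - (off + 1) * tileSize + 1
    hi <- i - off * tileSize
    jmax <- min(len2 - 1, hi)
    if (jmax >= max(0, lo)) best <- max(best, i + jmax)
  }
  if (!is.finite(best)) stop("empty band")
  floor(best / chunkLength)
}

pairSeeds <- function(pos1, pos2, seq1 = "s1", seq2 = "s2",
                      labels = c("gA", "gB")) {
  seedSet(cbind(rep_len(seq1, length(pos1)), rep_len(seq2, length(pos1))),
          cbind(pos1, pos2), genomeLabels = labels)
}
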