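# Neighbouring-matches filter: a candidate seed survives only if enough
# non-overlapping seeds lie on the same alignment diagonal within a
# window of length D centered on it.

#' Build a diagonal index over pairwise seed candidates
#'
#' Groups pairwise candidates by (sequence pair, diagonal `i - j`) with
#' first-genome positions sorted increasingly. Mostly useful for
#' inspection; [filterNeighbouringSeeds()] builds it internally.
#'
#' @param x A pairwise [SeedSet-class].
#' @return data.frame with columns `seqId1`, `seqId2`, `diag` and a list
#'   column `positions` of sorted first-genome positions.
#' @export
buildDiagonalIndex <- function(x) {
  if (nGenomes(x) != 2)
    stop("the neighbouring-matches filter is defined for pairwise seeds only")
  dt <- .seedDT(x)
  dt[, diag := pos1 - pos2]
  idx <- dt[, .(positions = list(sort(pos1))), by = .(seqId1, seqId2, diag)]
  setorder(idx, seqId1, seqId2, diag)
  as.data.frame(idx)
}

# neighbour counts for one sorted position vector: for each position, the
# number of other positions p' with lowDist <= |p - p'| <= highDist
.diagNeighbourCounts <- function(pos, D, minSep) {
  p <- sort(pos)
  half <- D / 2
  nWin <- findInterval(p + half, p) - findInterval(p - half - 1e-9, p)
  # positions closer than minSep (including self)
  near <- findInterval(p + min(half, minSep - 1) + 1e-9, p) -
          findInterval(p - min(half, minSep - 1) - 1e-9, p)
  cnt <- pmax(nWin - near, 0L)
  cnt[order(order(pos))]          # back to input order
}

#' Filter seeds by neighbouring matches on the same diagonal
#'
#' A candidate `(i, j)` passes iff the total number of seeds `(i', j')` of
#' the same sequence pair with `i' - j' = i - j` and `|i - i'| <= D/2`
#' reaches `tau`, where two counted matches must not overlap:
#' neighbours with `|i - i'| < span` are not counted. By default the
#' candidate itself contributes 1 to the total, so `tau = 2` requires at
#' least one valid neighbour and `tau = 1` is the identity filter; set
#' `countSelf = FALSE` to require `tau` true neighbours instead.
#'
#' @param x A pairwise [SeedSet-class].
#' @param D Search window in bp (default 1000).
#' @param tau Count threshold (default 2).
#' @param span Non-overlap distance in bp: the (maximum) span of the
#'   pattern set that produced the candidates.
#' @param countSelf Whether the candidate itself counts toward `tau`.
#' @return The surviving seeds, canonically ordered, stage `"m4-pass"`.
#' @export
filterNeighbouringSeeds <- function(x, D = 1000, tau = 2, span,
                                    countSelf = TRUE) {
  if (nGenomes(x) != 2)
    stop("the neighbouring-matches filter is defined for pairwise seeds only")
  stopifnot(D >= 0, tau >= 1, span >= 1)
  if (length(x) == 0) {
    out <- x; out@stage <- "m4-pass"; return(out)
  }
  dt <- .seedDT(x)
  dt[, diag := pos1 - pos2]
  dt[, cnt := .diagNeighbourCounts(pos1, D = D, minSep = span),
     by = .(seqId1, seqId2, diag)]
  need <- if (countSelf) tau - 1L else tau
  keepIdx <- dt$idx[dt$cnt >= need]
  out <- sortSeeds(x[keepIdx])
  out@stage <- "m4-pass"
  out
}
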