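#' MaskedSeqSet: softmasked DNA sequences with genome labels
#'
#' A collection of DNA sequences in which lowercase residues mark
#' softmasked (repeat-derived) positions and non-ACGT letters (e.g. `n`,
#' IUPAC ambiguity codes) mark ambiguous positions. Case is preserved
#' internally; every position is classifiable as (masked|unmasked) x
#' (unambiguous|ambiguous). Each sequence carries the label of the genome
#' or assembly it belongs to; seed finding only pairs sequences from
#' distinct genome labels.
#'
#' @slot seqs A [Biostrings::BStringSet] holding the residues, named by
#'   sequence id. `BStringSet` (not `DNAStringSet`) so softmask case
#'   survives round trips.
#' @slot genome Character vector, one genome label per sequence.
#' @export
setClass("MaskedSeqSet",
  representation(seqs = "BStringSet", genome = "character"))

setValidity("MaskedSeqSet", function(object) {
  msg <- NULL
  n <- length(object@seqs)
  if (length(object@genome) != n)
    msg <- c(msg, "genome labels must match number of sequences")
  ids <- names(object@seqs)
  if (n > 0 && (is.null(ids) || anyNA(ids) || any(!nzchar(ids))))
    msg <- c(msg, "all sequences must be named with non-empty ids")
  if (n > 0 && anyDuplicated(ids))
    msg <- c(msg, "sequence ids must be unique")
  if (is.null(msg)) TRUE else msg
})

#' SeedPattern: a spaced-seed pattern
#'
#' A binary match/don't-care pattern. The number of 1s is the weight `k`,
#' the total length the span. Match positions are stored 1-based (the
#' position of the s-th 1), mirroring the usual notation; helper code
#' converts to 0-based offsets where needed. Leading or trailing 0s carry
#' no information and are rejected.
#'
#' @slot bits Binary string over \{0,1\}.
#' @slot weight Integer, number of match positions.
#' @slot span Integer, pattern length.
#' @slot matchPos Integer vector of length `weight`: 1-based positions of
#'   the 1s, strictly increasing.
#' @slot id Short label.
#' @export
setClass("SeedPattern",
  representation(bits = "character", weight = "integer", span = "integer",
                 matchPos = "integer", id = "character"))

setValidity("SeedPattern", function(object) {
  msg <- NULL
  b <- object@bits
  if (length(b) != 1 || !nzchar(b) || grepl("[^01]", b))
    return("bits must be a nonempty string over {0,1}")
  if (substr(b, 1, 1) != "1" || substr(b, nchar(b), nchar(b)) != "1")
    msg <- c(msg, "pattern must begin and end with a match position (1)")
  ones <- which(strsplit(b, "")[[1]] == "1")
  if (object@weight != length(ones))
    msg <- c(msg, "weight must equal the number of 1s")
  if (object@span != nchar(b))
    msg <- c(msg, "span must equal the pattern length")
  if (!identical(object@matchPos, as.integer(ones)))
    msg <- c(msg, "matchPos must list the 1-based positions of the 1s")
  if (length(object@id) != 1 || !nzchar(object@id))
    msg <- c(msg, "id must be a single nonempty string")
  if (is.null(msg)) TRUE else msg
})

#' PatternSet: a set of spaced-seed patterns of equal weight
#'
#' Multiple spaced-seed patterns are matched jointly: a position pair is a
#' candidate if any pattern in the set matches there. All patterns must
#' share the same weight; ids must be unique.
#'
#' @slot patterns List of [SeedPattern-class] objects.
#' @export
setClass("PatternSet", representation(patterns = "list"))

setValidity("PatternSet", function(object) {
  ps <- object@patterns
  if (length(ps) < 1) return("a PatternSet needs at least one pattern")
  if (!all(vapply(ps, is, logical(1), class2 = "SeedPattern")))
    return("all elements must be SeedPattern objects")
  ws <- vapply(ps, function(p) p@weight, integer(1))
  if (length(unique(ws)) != 1)
    return("all patterns in a set must have equal weight")
  ids <- vapply(ps, function(p) p@id, character(1))
  if (anyDuplicated(ids)) return("pattern ids must be unique")
  TRUE
})

#' SeedSet: alignment seed candidates
#'
#' A set of seeds, each a tuple of (sequence id, position) coordinates, one
#' per genome: two for pairwise seeds, `s` for multi-genome seeds.
#' Positions are 0-based. Column `g` of the coordinate matrices belongs to
#' genome `genomeLabels[g]`; within one seed the genome labels are
#' pairwise distinct by construction. Each seed optionally records the
#' pattern that produced it; the whole set carries a stage tag
#' (`"candidate"`, `"m4-pass"` or `"ghash-pass"`).
#'
#' @slot seqIds Character matrix, n seeds x s genomes.
#' @slot positions Numeric matrix (integral values), n x s, 0-based.
#' @slot genomeLabels Character vector of length s.
#' @slot pattern Character vector of length n (NA where not applicable).
#' @slot stage Single stage tag.
#' @export
setClass("SeedSet",
  representation(seqIds = "matrix", positions = "matrix",
                 genomeLabels = "character", pattern = "character",
                 stage = "character"))

setValidity("SeedSet", function(object) {
  msg <- NULL
  n <- nrow(object@seqIds); s <- ncol(object@seqIds)
  if (!is.character(object@seqIds)) msg <- c(msg, "seqIds must be character")
  if (!is.numeric(object@positions)) msg <- c(msg, "positions must be numeric")
  if (!all(dim(object@positions) == c(n, s)))
    msg <- c(msg, "seqIds and positions must have identical dimensions")
  if (length(object@genomeLabels) != s)
    msg <- c(msg, "need one genome label per coordinate column")
  if (s > 0 && anyDuplicated(object@genomeLabels))
    msg <- c(msg, "genome labels of the coordinate columns must be distinct")
  if (length(object@pattern) != n)
    msg <- c(msg, "pattern must have one entry per seed")
  if (length(object@stage) != 1)
    msg <- c(msg, "stage must be a single tag")
  if (n > 0 && any(object@positions < 0, na.rm = TRUE))
    msg <- c(msg, "positions must be >= 0 (0-based)")
  if (is.null(msg)) TRUE else msg
})

#' GeneAnnot: CDS intervals and homologous sequence pairs
#'
#' Gene annotations driving sensitivity evaluation: CDS intervals per
#' sequence (internal 0-based half-open coordinates) and the symmetric
#' homology relation between sequences of the two genomes.
#'
#' @slot cds data.frame with columns `seqId`, `start`, `end` (0-based
#'   half-open, `start < end`).
#' @slot pairs data.frame with columns `seqId1`, `seqId2`: homologous
#'   sequence pairs. The relation is treated as symmetric.
#' @export
setClass("GeneAnnot", representation(cds = "data.frame", pairs = "data.frame"))

setValidity("GeneAnnot", function(object) {
  msg <- NULL
  cds <- object@cds
  if (!all(c("seqId", "start", "end") %in% names(cds)))
    msg <- c(msg, "cds needs columns seqId, start, end")
  else if (nrow(cds) > 0 && any(cds$start >= cds$end))
    msg <- c(msg, "cds intervals must satisfy start < end (half-open)")
  if (!all(c("seqId1", "seqId2") %in% names(object@pairs)))
    msg <- c(msg, "pairs needs columns seqId1, seqId2")
  if (is.null(msg)) TRUE else msg
})

#' GHParams: geometric hashing parameters
#'
#' Tile geometry and scoring parameters for geometric hashing. A tile is a
#' diagonal stripe of width `F` bp in the pairwise alignment space; it is
#' split into `b` sub-tiles of width `F/b` by within-tile diagonal and into
#' chunks of length `h` bp along the anti-diagonal `i + j`. Tile scores are
#' the p-norm (exponent `pNorm`) of the per-(sub-tile, chunk) candidate
#' counts divided by `lambda * b * (smax + 1)`, where `lambda` is the
#' expected number of candidates per chunk under uniform scatter. Tiles
#' with score >= `tauScore` pass.
#'
#' @slot tileSize Tile size F in bp (default 10000).
#' @slot nSubTiles Number of sub-tiles b (default 50).
#' @slot chunkLength Chunk length h in bp (default 400).
#' @slot pNorm Norm exponent p (default 6).
#' @slot tauScore Score threshold tau (>= 0).
#' @export
setClass("GHParams",
  representation(tileSize = "numeric", nSubTiles = "numeric",
                 chunkLength = "numeric", pNorm = "numeric",
                 tauScore = "numeric"))

setValidity("GHParams", function(object) {
  msg <- NULL
  if (object@tileSize <= 0) msg <- c(msg, "tileSize must be > 0")
  if (object@nSubTiles < 1) msg <- c(msg, "nSubTiles must be >= 1")
  if (object@chunkLength < 1) msg <- c(msg, "chunkLength must be >= 1")
  if (object@pNorm < 1) msg <- c(msg, "pNorm must be >= 1")
  if (object@tauScore < 0) msg <- c(msg, "tauScore must be >= 0")
  if (is.null(msg)) TRUE else msg
})
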