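#' Construct a MaskedSeqSet
#'
#' @param seqs Named character vector of residues, or a
#'   [Biostrings::BStringSet]. Lowercase = softmasked; non-ACGT letters are
#'   ambiguous.
#' @param genome Genome label(s): a single string (recycled) or one label
#'   per sequence.
#' @return A [MaskedSeqSet-class].
#' @examples
#' maskedSeqSet(c(s1 = "ACgtN"), genome = "gA")
#' @export
maskedSeqSet <- function(seqs, genome) {
  if (is.character(seqs)) seqs <- BStringSet(seqs)
  if (!is(seqs, "BStringSet")) seqs <- BStringSet(seqs)
  n <- length(seqs)
  if (length(genome) == 1) genome <- rep(genome, n)
  new("MaskedSeqSet", seqs = seqs, genome = as.character(genome))
}

#' @describeIn maskedSeqSet Sequence ids.
#' @param x A `MaskedSeqSet`.
#' @export
setMethod("seqIds", "MaskedSeqSet", function(x) names(x@seqs))

#' @describeIn maskedSeqSet Genome label per sequence.
#' @export
setMethod("genomeLabels", "MaskedSeqSet", function(x)
  setNames(x@genome, names(x@seqs)))

#' @describeIn maskedSeqSet Sequence lengths in bp, named by id.
#' @export
setMethod("seqLengths", "MaskedSeqSet", function(x)
  setNames(width(x@seqs), names(x@seqs)))

#' @describeIn maskedSeqSet Residues as a named character vector (case
#'   preserved).
#' @export
setMethod("residues", "MaskedSeqSet", function(x)
  setNames(as.character(x@seqs), names(x@seqs)))

setMethod("length", "MaskedSeqSet", function(x) length(x@seqs))

setMethod("show", "MaskedSeqSet", function(object) {
  n <- length(object)
  cat("MaskedSeqSet with", n, "sequence(s),",
      sum(as.numeric(width(object@seqs))), "bp total\n")
  if (n > 0) {
    k <- min(n, 5L)
    for (i in seq_len(k)) {
      cat(sprintf("  %s [%s] %d bp\n", names(object@seqs)[i],
                  object@genome[i], width(object@seqs)[i]))
    }
    if (n > k) cat("  ...", n - k, "more\n")
  }
})

setMethod("[", "MaskedSeqSet", function(x, i, j, ..., drop = TRUE) {
  new("MaskedSeqSet", seqs = x@seqs[i], genome = x@genome[i])
})

#' Combine MaskedSeqSet objects
#' @param x,... `MaskedSeqSet` objects.
#' @export
setMethod("c", "MaskedSeqSet", function(x, ...) {
  rest <- list(...)
  seqs <- do.call(c, c(list(x@seqs), lapply(rest, function(y) y@seqs)))
  genome <- c(x@genome, unlist(lapply(rest, function(y) y@genome)))
  new("MaskedSeqSet", seqs = seqs, genome = genome)
})

# ---- per-position classification ------------------------------------------

# lookup tables over raw byte codes
.baseCodeLUT <- local({
  lut <- rep(NA_integer_, 256)
  lut[utf8ToInt("A") + 1L] <- 0L; lut[utf8ToInt("a") + 1L] <- 0L
  lut[utf8ToInt("C") + 1L] <- 1L; lut[utf8ToInt("c") + 1L] <- 1L
  lut[utf8ToInt("G") + 1L] <- 2L; lut[utf8ToInt("g") + 1L] <- 2L
  lut[utf8ToInt("T") + 1L] <- 3L; lut[utf8ToInt("t") + 1L] <- 3L
  lut
})

.maskLUT <- local({
  lut <- rep(FALSE, 256)
  lut[utf8ToInt("a"):utf8ToInt("z") + 1L] <- TRUE  # lowercase = softmasked
  lut
})

# 2-bit base codes (0..3) with NA at ambiguous positions; optionally NA at
# masked positions too (so summation over match offsets propagates the flag)
.encodeResidues <- function(s, maskToNA = FALSE) {
  bytes <- as.integer(charToRaw(s))
  code <- .baseCodeLUT[bytes + 1L]
  if (maskToNA) code[.maskLUT[bytes + 1L]] <- NA_integer_
  code
}

.maskedFlags <- function(s) .maskLUT[as.integer(charToRaw(s)) + 1L]

#' @describeIn maskedSeqSet 0-based positions of softmasked residues of
#'   sequence `id`.
#' @param id Sequence id.
#' @export
setMethod("maskedPositions", "MaskedSeqSet", function(x, id) {
  which(.maskedFlags(as.character(x@seqs[[id]]))) - 1L
})

#' @describeIn maskedSeqSet 0-based positions of ambiguous (non-ACGT)
#'   residues of sequence `id`.
#' @export
setMethod("ambiguousPositions", "MaskedSeqSet", function(x, id) {
  which(is.na(.encodeResidues(as.character(x@seqs[[id]])))) - 1L
})
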