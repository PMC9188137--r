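#' Parse a spaced-seed pattern
#'
#' A pattern is a binary string over \{0,1\}: 1 = match position, 0 =
#' don't-care. The number of 1s is its weight `k`, its length the span
#' `l`; the contiguous pattern of weight `k` is `"1...1"` with `k = l`.
#' Leading or trailing 0s are rejected.
#'
#' @param bits Binary string.
#' @param id Optional label (defaults to the bits themselves).
#' @return A [SeedPattern-class].
#' @examples
#' p <- seedPattern("1101")         # weight 3, span 4, match positions 1,2,4
#' patternWeight(p)
#' @export
seedPattern <- function(bits, id = NULL) {
  bits <- as.character(bits)
  if (length(bits) != 1 || !nzchar(bits))
    stop("pattern must be a single nonempty string")
  if (grepl("[^01]", bits))
    stop("pattern may only contain 0 and 1: ", bits)
  if (substr(bits, 1, 1) != "1" || substr(bits, nchar(bits), nchar(bits)) != "1")
    stop("pattern must begin and end with 1 (leading/trailing 0s are ",
         "meaningless): ", bits)
  ones <- which(strsplit(bits, "")[[1]] == "1")
  if (is.null(id)) id <- bits
  new("SeedPattern", bits = bits, weight = length(ones),
      span = nchar(bits), matchPos = as.integer(ones), id = as.character(id))
}

#' @describeIn seedPattern Weight (number of match positions).
#' @param x A `SeedPattern`.
#' @export
setMethod("patternWeight", "SeedPattern", function(x) x@weight)

#' @describeIn seedPattern Span (pattern length).
#' @export
setMethod("patternSpan", "SeedPattern", function(x) x@span)

#' @describeIn seedPattern 1-based positions of the match positions.
#' @export
setMethod("matchPositions", "SeedPattern", function(x) x@matchPos)

setMethod("show", "SeedPattern", function(object) {
  cat(sprintf("SeedPattern '%s': %s (weight %d, span %d)\n",
              object@id, object@bits, object@weight, object@span))
})

#' Construct a pattern set
#'
#' @param patterns A list of [SeedPattern-class] objects, or a character
#'   vector of binary strings (optionally named: names become ids).
#' @return A [PatternSet-class]; all patterns must share one weight.
#' @export
patternSet <- function(patterns) {
  if (is.character(patterns)) {
    ids <- names(patterns)
    patterns <- lapply(seq_along(patterns), function(i)
      seedPattern(patterns[i],
                  id = if (!is.null(ids) && nzchar(ids[i])) ids[i] else NULL))
  }
  if (is(patterns, "SeedPattern")) patterns <- list(patterns)
  new("PatternSet", patterns = patterns)
}

setMethod("length", "PatternSet", function(x) length(x@patterns))

#' @describeIn patternSet Pattern ids.
#' @param x A `PatternSet`.
#' @export
setMethod("patternIds", "PatternSet", function(x)
  vapply(x@patterns, function(p) p@id, character(1)))

#' @describeIn patternSet Common weight of the set.
#' @export
setMethod("patternWeight", "PatternSet", function(x) x@patterns[[1]]@weight)

#' @describeIn patternSet Maximum span in the set.
#' @export
setMethod("patternSpan", "PatternSet", function(x)
  max(vapply(x@patterns, function(p) p@span, integer(1))))

setMethod("show", "PatternSet", function(object) {
  cat(sprintf("PatternSet: %d pattern(s) of weight %d\n",
              length(object), patternWeight(object)))
  for (p in object@patterns)
    cat(sprintf("  %s\t%s\n", p@id, p@bits))
})

setMethod("[[", "PatternSet", function(x, i) x@patterns[[i]])

#' Read a pattern set from a config file
#'
#' One pattern per line, either `id<TAB>bits` or bare `bits`; `#` comments
#' and blank lines are ignored.
#' @param path File path.
#' @return A [PatternSet-class].
#' @export
readPatternSet <- function(path) {
  if (!file.exists(path)) stop("pattern file not found: ", path)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  if (!length(lines)) stop("no patterns in ", path)
  parts <- strsplit(lines, "[\t ]+")
  pats <- lapply(parts, function(p) {
    if (length(p) >= 2) seedPattern(p[2], id = p[1]) else seedPattern(p[1])
  })
  patternSet(pats)
}

#' Bundled example pattern sets
#'
#' Returns a pattern set shipped with the package: four patterns each of
#' weight 15, 14 or 8, or the single weight-19 pattern used as the coarse
#' pass of the two-step filter.
#' @param weight One of 15, 14, 8, 19.
#' @export
examplePatternSet <- function(weight = 15) {
  file <- switch(as.character(weight),
                 "15" = "patterns_w15.txt", "14" = "patterns_w14.txt",
                 "8" = "patterns_w8.txt", "19" = "pattern_w19.txt",
                 stop("no bundled pattern set of weight ", weight))
  readPatternSet(system.file("extdata", file, package = "geoseed",
                             mustWork = TRUE))
}

#' Induce the k-mer of a spaced-seed pattern at one window
#'
#' Concatenates the residues of `seq` at the pattern's match positions for
#' the window starting at 0-based position `start`. Returns
#' `NA_character_` if any selected residue is ambiguous (non-ACGT, e.g.
#' `n`), or — when `maskFilter` is `TRUE` — softmasked. Only the match
#' positions are tested; don't-care positions may be masked or ambiguous.
#'
#' @param seq A [MaskedSeqSet-class] of length 1, or a single residue
#'   string.
#' @param pattern A [SeedPattern-class].
#' @param start 0-based window start; must satisfy
#'   `0 <= start <= length(seq) - span`.
#' @param maskFilter Reject windows with softmasked match positions.
#' @return Uppercase k-mer string, or `NA_character_`.
#' @examples
#' induceKmer("ACGT", seedPattern("101"), 0)   # "AG"
#' @export
induceKmer <- function(seq, pattern, start, maskFilter = TRUE) {
  s <- .singleResidues(seq)
  n <- nchar(s)
  if (start < 0 || start > n - pattern@span)
    stop("window start ", start, " out of range for span ", pattern@span,
         " and sequence length ", n)
  idx <- start + pattern@matchPos           # 1-based residue indices
  chars <- strsplit(s, "")[[1]][idx]
  code <- .baseCodeLUT[as.integer(charToRaw(paste(chars, collapse = ""))) + 1L]
  if (anyNA(code)) return(NA_character_)
  if (maskFilter && any(.maskLUT[as.integer(charToRaw(
        paste(chars, collapse = ""))) + 1L]))
    return(NA_character_)
  toupper(paste(chars, collapse = ""))
}

.singleResidues <- function(seq) {
  if (is(seq, "MaskedSeqSet")) {
    stopifnot(length(seq) == 1)
    residues(seq)[[1]]
  } else if (is.character(seq) && length(seq) == 1) seq
  else stop("expected a single sequence")
}

#' Enumerate all induced k-mers of a sequence
#'
#' Bulk form of [induceKmer()]: yields every valid window start in
#' increasing order, skipping windows rejected by the ambiguity or mask
#' filter (ambiguous match positions always reject a window; softmasked
#' ones only when `maskFilter` is on). The number of skipped windows is
#' attached as attribute `skipped`.
#'
#' @inheritParams induceKmer
#' @return data.frame with columns `start` (0-based) and `kmer`, attribute
#'   `skipped`.
#' @export
enumerateKmers <- function(seq, pattern, maskFilter = TRUE) {
  s <- .singleResidues(seq)
  codes <- .windowCodes(s, pattern, maskFilter = maskFilter)
  valid <- which(!is.na(codes))
  out <- data.frame(start = valid - 1L,
                    kmer = .decodeKmer(codes[valid], pattern@weight),
                    stringsAsFactors = FALSE)
  attr(out, "skipped") <- length(codes) - length(valid)
  out
}

# ---- 2-bit packed window codes --------------------------------------------

# Numeric (double) codes are exact integers up to 2^53; weight w uses 2w
# bits, so w <= 26 is enforced.
.maxPackWeight <- 26L

# Vector of packed k-mer codes for every window start of `s` (1-based
# window index; value NA where the window is rejected because a match
# position is ambiguous or — with maskFilter — softmasked).
.windowCodes <- function(s, pattern, maskFilter = TRUE) {
  w <- pattern@weight
  if (w > .maxPackWeight)
    stop("pattern weight ", w, " exceeds the supported maximum of ",
         .maxPackWeight)
  n <- nchar(s)
  nWin <- n - pattern@span + 1L
  if (nWin < 1) return(numeric(0))
  codeN <- as.numeric(.encodeResidues(s, maskToNA = maskFilter))
  acc <- numeric(nWin)
  mult <- 4^((w - 1L):0)
  off <- pattern@matchPos - 1L          # 0-based offsets
  for (si in seq_len(w)) {
    acc <- acc + codeN[(1L + off[si]):(nWin + off[si])] * mult[si]
  }
  acc
}

.kmerAlphabet <- c("A", "C", "G", "T")

# decode packed codes back to strings (small vectors only; for interface
# and testing — the matching pipeline stays packed)
.decodeKmer <- function(codes, w) {
  if (!length(codes)) return(character(0))
  out <- matrix("", nrow = length(codes), ncol = w)
  rem <- codes
  for (si in w:1) {
    out[, si] <- .kmerAlphabet[(rem %% 4) + 1]
    rem <- rem %/% 4
  }
  apply(out, 1, paste, collapse = "")
}
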