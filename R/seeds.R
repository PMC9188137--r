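#' Construct a SeedSet
#'
#' @param seqIds Character matrix (n seeds x s genomes) of sequence ids,
#'   or a vector for a single seed.
#' @param positions Numeric matrix of 0-based positions, same shape.
#' @param genomeLabels Genome label per coordinate column.
#' @param pattern Optional pattern id per seed (recycled).
#' @param stage Stage tag: `"candidate"`, `"m4-pass"` or `"ghash-pass"`.
#' @return A [SeedSet-class].
#' @examples
#' seedSet(matrix(c("s1", "s2"), 1), matrix(c(100, 200), 1),
#'         genomeLabels = c("gA", "gB"))
#' @export
seedSet <- function(seqIds, positions, genomeLabels,
                    pattern = NA_character_, stage = "candidate") {
  if (!is.matrix(seqIds)) seqIds <- matrix(seqIds, nrow = 1)
  if (!is.matrix(positions)) positions <- matrix(positions, nrow = 1)
  storage.mode(seqIds) <- "character"
  storage.mode(positions) <- "double"
  n <- nrow(seqIds)
  pattern <- rep_len(as.character(pattern), n)
  new("SeedSet", seqIds = seqIds, positions = positions,
      genomeLabels = as.character(genomeLabels), pattern = pattern,
      stage = stage)
}

# empty set with a given dimensionality
.emptySeedSet <- function(genomeLabels, stage = "candidate") {
  s <- length(genomeLabels)
  seedSet(matrix(character(0), 0, s), matrix(numeric(0), 0, s),
          genomeLabels = genomeLabels, pattern = character(0), stage = stage)
}

setMethod("length", "SeedSet", function(x) nrow(x@seqIds))

#' @describeIn seedSet Number of genomes per seed (2 = pairwise).
#' @param x A `SeedSet`.
#' @export
setMethod("nGenomes", "SeedSet", function(x) ncol(x@seqIds))

#' @describeIn seedSet Genome label per coordinate column.
#' @export
setMethod("genomeLabels", "SeedSet", function(x) x@genomeLabels)

#' @describeIn seedSet Stage tag of the set.
#' @export
setMethod("seedStage", "SeedSet", function(x) x@stage)

setMethod("show", "SeedSet", function(object) {
  cat(sprintf("SeedSet: %d seed(s) across %d genome(s) [stage: %s]\n",
              length(object), nGenomes(object), object@stage))
  if (length(object) > 0) {
    print(utils::head(as.data.frame(object), 5))
    if (length(object) > 5) cat("  ...", length(object) - 5, "more\n")
  }
})

setMethod("[", "SeedSet", function(x, i, j, ..., drop = TRUE) {
  new("SeedSet", seqIds = x@seqIds[i, , drop = FALSE],
      positions = x@positions[i, , drop = FALSE],
      genomeLabels = x@genomeLabels, pattern = x@pattern[i],
      stage = x@stage)
})

#' Coerce a SeedSet to a data.frame
#'
#' Columns `seqId1`, `pos1`, ..., `seqId<s>`, `pos<s>`, `pattern`, `stage`.
#' @param x A [SeedSet-class].
#' @param ... Unused.
#' @exportS3Method base::as.data.frame
#' @export
as.data.frame.SeedSet <- function(x, ...) {
  s <- nGenomes(x)
  out <- list()
  for (g in seq_len(s)) {
    out[[paste0("seqId", g)]] <- x@seqIds[, g]
    out[[paste0("pos", g)]] <- x@positions[, g]
  }
  out$pattern <- x@pattern
  out$stage <- rep(x@stage, length(x))
  as.data.frame(out, stringsAsFactors = FALSE)
}

setMethod("as.data.frame", "SeedSet", as.data.frame.SeedSet)

# internal: data.table with seqId<g>/pos<g> columns
.seedDT <- function(x) {
  s <- nGenomes(x)
  dt <- data.table(idx = seq_len(length(x)))
  for (g in seq_len(s)) {
    dt[, (paste0("seqId", g)) := x@seqIds[, g]]
    dt[, (paste0("pos", g)) := x@positions[, g]]
  }
  dt[, pattern := x@pattern]
  dt
}

.seedsFromDT <- function(dt, genomeLabels, stage = "candidate") {
  s <- length(genomeLabels)
  n <- nrow(dt)
  seqIds <- matrix(character(0), n, s)
  positions <- matrix(numeric(0), n, s)
  if (n > 0) {
    seqIds <- do.call(cbind, lapply(seq_len(s), function(g)
      as.character(dt[[paste0("seqId", g)]])))
    positions <- do.call(cbind, lapply(seq_len(s), function(g)
      as.numeric(dt[[paste0("pos", g)]])))
  }
  pat <- if ("pattern" %in% names(dt) && n > 0) as.character(dt$pattern)
         else rep(NA_character_, n)
  seedSet(seqIds, positions, genomeLabels, pattern = pat, stage = stage)
}

#' Canonically sort a SeedSet
#'
#' Orders seeds by sequence ids and positions of all coordinate columns so
#' results are independent of hash iteration order.
#' @param x A [SeedSet-class].
#' @return The sorted `SeedSet`.
#' @export
sortSeeds <- function(x) {
  if (length(x) < 2) return(x)
  cols <- as.list(as.data.frame(x)[
    , unlist(lapply(seq_len(nGenomes(x)),
                    function(g) paste0(c("seqId", "pos"), g))),
    drop = FALSE])
  ord <- do.call(order, cols)
  x[ord]
}

#' De-duplicate seeds on coordinates
#'
#' Seeds identical in all (sequence id, position) coordinates are collapsed
#' to one, keeping the first pattern id encountered. Output is canonically
#' sorted.
#' @param x A [SeedSet-class].
#' @export
dedupSeeds <- function(x) {
  if (length(x) < 2) return(sortSeeds(x))
  df <- as.data.frame(x)
  key <- do.call(paste, c(df[grep("^(seqId|pos)", names(df))], sep = "\r"))
  sortSeeds(x[!duplicated(key)])
}
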